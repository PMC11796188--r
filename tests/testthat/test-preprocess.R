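test_that("missingness filter keeps exactly the features at or under threshold", {
  m <- matrix(runif(10 * 6) + 0.5, 10, 6)
  m[1:3, 2] <- NA          # 3 missing
  m[1:5, 5] <- NA          # 5 missing
  ft <- make_feature_table(m)
  out <- filter_features(ft, max_missing = 3)
  expect_identical(setdiff(names(out), "sample_id"),
                   c("f01", "f02", "f03", "f04", "f06"))
  rep <- attr(out, "removal_report")
  expect_identical(rep$feature_id, "f05")
  expect_identical(rep$n_missing, 5)

  # fully observed matrix passes through untouched (modulo the report attr)
  full <- make_feature_table(matrix(1:20, 4, 5))
  kept <- filter_features(full, max_missing = 0)
  attr(kept, "removal_report") <- NULL
  expect_equal(as.data.frame(kept), as.data.frame(full))

  # fractional threshold variant
  out_frac <- filter_features(ft, max_missing = 3 / 10, fraction = TRUE)
  expect_identical(names(out_frac), names(out))
  expect_error(filter_features(ft[0, ], 3), "empty")
})

test_that("kNN imputation averages the nearest features and only fills gaps", {
  # identical neighbours: a feature duplicated k times pins the imputed value
  base <- rnorm(8, 10)
  m <- cbind(f1 = base, f2 = base, f3 = base, f4 = rnorm(8, 50))
  m[3, 1] <- NA
  out <- fm <- as.matrix(knn_impute(make_feature_table(m), k = 2)[-1])
  expect_equal(out[3, 1], base[3], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(out[-3, 1], base[-3], ignore_attr = TRUE)

  # complete matrix: idempotent
  full <- make_feature_table(matrix(rnorm(30), 6, 5))
  expect_identical(knn_impute(full, k = 3), full)

  # 6-feature x 5-sample fixture against the brute-force oracle
  set.seed(21)
  m2 <- matrix(rnorm(30, 5), 5, 6)
  m2[2, 4] <- NA
  got <- as.matrix(knn_impute(make_feature_table(m2), k = 2)[-1])
  want <- oracle_knn_impute(m2, k = 2)
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)

  # no usable neighbour: the whole sample row is missing
  m3 <- matrix(rnorm(20), 4, 5)
  m3[1, ] <- NA
  expect_error(knn_impute(make_feature_table(m3), k = 2), "neighbour")
})

test_that("kNN matches the exhaustive oracle across random masked matrices", {
  set.seed(77)
  for (rep in 1:12) {
    nr <- sample(5:20, 1); nc <- sample(5:20, 1)
    m <- matrix(rnorm(nr * nc, 8, 2), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.08, nr, nc)
    # keep at least 3 observed cells per row and column so neighbours exist
    mask[rowSums(!mask) < 3, ] <- FALSE
    m[mask] <- NA
    k <- sample(2:4, 1)
    got <- as.matrix(knn_impute(make_feature_table(m), k = k)[-1])
    want <- oracle_knn_impute(m, k = k)
    expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("filter then impute never alters an observed value", {
  set.seed(5)
  m <- matrix(10^rnorm(40 * 25, 3), 40, 25,
              dimnames = list(NULL, sprintf("f%02d", 1:25)))
  m[runif(length(m)) < 0.05] <- NA
  ft <- make_feature_table(m)
  out <- knn_impute(filter_features(ft, max_missing = 10), k = 5)
  keep <- intersect(names(out), colnames(m))
  m_obs <- m[, keep]
  got <- as.matrix(out[keep])
  idx <- !is.na(m_obs)
  expect_identical(got[idx], m_obs[idx])
  expect_false(anyNA(got))
})

test_that("log10_standardize applies the exact analysis transform", {
  ft <- make_feature_table(cbind(f1 = c(10, 100, 1000)))
  out <- log10_standardize(ft)
  expect_equal(out$f1, c(-1, 0, 1))  # log10 -> (1,2,3), sample SD 1

  set.seed(3)
  any_ft <- make_feature_table(matrix(rexp(200) + 0.1, 20, 10))
  g <- as.matrix(log10_standardize(any_ft)[-1])
  expect_equal(apply(g, 2, sd), rep(1, 10), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(colMeans(g), rep(0, 10), ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(log10_standardize(make_feature_table(cbind(f1 = c(5, 5, 5)))),
               "zero-variance")
  expect_error(log10_standardize(make_feature_table(cbind(f1 = c(1, -2, 3)))),
               "non-positive")
})

test_that("log10_standardize inverts the generator's construction", {
  st <- simulate_cohort(sim_config(n_samples = 50, n_features = 12,
                                   missing_rate = 0, n_batches = 1,
                                   batch_shift_sd = 0, batch_scale_sd = 0,
                                   seed = 17))
  grid <- as.matrix(log10_standardize(st$features_raw)[, -(1:2)])
  expect_equal(grid, st$truth$latent_standardized,
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("density arithmetic and invalid-record flagging are correct", {
  out <- derive_density(tibble::tibble(dense_volume = 100, total_volume = 1000))
  expect_equal(out$vpd, 0.10)
  expect_equal(out$nondense_volume, 900)
  expect_equal(out$log10_vpd, -1)

  # boundary: DV == total keeps the record but log10 NDV is undefined
  b <- derive_density(tibble::tibble(dense_volume = 50, total_volume = 50))
  expect_equal(b$vpd, 1)
  expect_equal(b$nondense_volume, 0)
  expect_true(is.na(b$log10_ndv))

  # 705 records, 5 unusable -> 700 analyzable
  set.seed(6)
  d <- tibble::tibble(dense_volume = runif(705, 20, 200),
                      total_volume = runif(705, 300, 1500))
  d$dense_volume[c(1, 100, 300)] <- -1            # non-positive
  d$dense_volume[c(400, 650)] <- d$total_volume[c(400, 650)] * 1.5  # DV > total
  out <- derive_density(d)
  expect_identical(nrow(out), 700L)
  expect_identical(nrow(attr(out, "invalid_report")), 5L)
  expect_equal(out$nondense_volume, out$total_volume - out$dense_volume,
               tolerance = 1e-9)
  expect_equal(out$vpd, out$dense_volume / out$total_volume, tolerance = 1e-9)
})

test_that("chained-equation imputation fills covariates sensibly", {
  co <- make_cohort(80, seed = 31)
  expect_identical(impute_covariates(co), co)   # complete: unchanged

  # deterministic limit: BMI18 = 1.2 * BMI10 exactly, one missing BMI18
  co2 <- co
  co2$bmi18 <- 1.2 * co2$bmi10
  co2$bmi18[7] <- NA
  done <- impute_covariates(co2, n_iterations = 10, seed = 2)
  expect_equal(done$bmi18[7], 1.2 * co2$bmi10[7], tolerance = 1e-6)

  # mixed missingness incl. categorical, seeded reproducibility
  co3 <- co
  co3$bmi10[1:5] <- NA
  co3$race[3:6] <- NA
  co3$family_history[10:12] <- NA
  a <- impute_covariates(co3, seed = 99)
  b <- impute_covariates(co3, seed = 99)
  expect_identical(a, b)
  expect_false(anyNA(a))
  # observed entries untouched
  expect_identical(a$bmi10[-(1:5)], co3$bmi10[-(1:5)])

  co4 <- co
  co4$age <- NA_real_
  expect_error(impute_covariates(co4), "no observed values")
})
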