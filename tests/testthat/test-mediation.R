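test_that("total-effect fit is exact on deterministic input", {
  x <- rnorm(40, 20, 3)
  fit <- estimate_total_effect(2 * x, x)
  expect_equal(fit$gamma_star, 2, tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("the total effect converges to the generator identity", {
  cfg <- sim_config(n_samples = 5000, n_features = 6, n_true_mediators = 3,
                    alpha_effects = c(0.2, -0.15, 0.1),
                    beta_effects = c(0.3, 0.25, -0.2), gamma_direct = -0.05,
                    missing_rate = 0, n_batches = 1, batch_shift_sd = 0,
                    batch_scale_sd = 0, seed = 23)
  st <- simulate_cohort(cfg)
  Z <- mediomics:::covariate_matrix(st$cohort,
                                    c("age", "race", "family_history", "age_menarche"))
  fit <- estimate_total_effect(st$density$log10_vpd, st$cohort$bmi10, Z)
  expect_lt(abs(fit$gamma_star - st$truth$implied_total_effect),
            3 * fit$std_error)
})

test_that("screening budget, ranking and tie-breaking follow the rules", {
  # default d = ceiling(2n / ln n); n = 700 -> 214
  expect_identical(ceiling(2 * 700 / log(700)), 214)
  set.seed(31)
  n <- 700
  m <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, sprintf("f%02d", 1:20)))
  y <- rnorm(n); x <- rnorm(n)
  sr <- screen_mediators(m, y, x)
  expect_identical(sr$d, 214L)
  expect_identical(nrow(sr$kept), 20L)  # p <= d: everything kept

  # a feature collinear with the outcome must rank first, and every kept
  # statistic must match an exhaustive per-feature OLS oracle
  m[, 3] <- y + rnorm(n, sd = 1e-6)
  sr2 <- screen_mediators(m, y, x, d = 5)
  oracle_t <- vapply(seq_len(ncol(m)), function(j) {
    summary(lm(y ~ m[, j] + x))$coefficients[2, "t value"]
  }, numeric(1))
  expect_identical(sr2$kept$feature_id[which.max(sr2$kept$statistic)], "f03")
  ord <- order(-abs(oracle_t))[1:5]
  expect_setequal(sr2$kept$feature_id, sprintf("f%02d", sort(ord)))
  # exact agreement off the near-collinear column; that one only to ~1e-4
  # relative (the partial-correlation route loses precision as |rho| -> 1)
  expect_equal(sr2$statistic_all[-3], abs(oracle_t)[-3], ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(sr2$statistic_all[[3]], abs(oracle_t)[3], tolerance = 1e-3)
  expect_error(screen_mediators(m, y, x, d = 0), "d must be")
})

test_that("screening keeps every mediator above the d-th largest |t|", {
  set.seed(32)
  for (rep in 1:5) {
    n <- 150; p <- sample(20:50, 1)
    m <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%03d", 1:p)))
    y <- rnorm(n) + m[, 1] * 0.5
    x <- rnorm(n)
    d <- sample(5:15, 1)
    sr <- screen_mediators(m, y, x, d = d)
    tall <- sort(sr$statistic_all, decreasing = TRUE)
    expect_true(all(sr$statistic_all[sr$kept$feature_id] >= tall[d] - 1e-12))
    expect_identical(nrow(sr$kept), as.integer(d))
  }
})

test_that("MCP at lambda = 0 equals OLS and the univariate solution is closed form", {
  set.seed(33)
  n <- 200
  M <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, sprintf("m%d", 1:6)))
  x <- rnorm(n)
  y <- M %*% c(0.4, -0.3, 0, 0, 0.2, 0) + 0.5 * x + rnorm(n)
  fit0 <- mcp_fit(M, y, x, lambda = 0, tol = 1e-12)
  ols <- coef(lm(y ~ M + x))
  expect_equal(unname(fit0$beta_penalized), unname(ols[2:7]), tolerance = 1e-8)
  expect_identical(fit0$support, colnames(M))

  # orthonormal single predictor: z = 0.5, lambda = 0.2, gamma = 3 -> 0.45
  u <- rnorm(500)
  u <- (u - mean(u)) / sqrt(sum((u - mean(u))^2) / 500)   # x'x/n = 1
  yy <- 0.5 * u
  xv <- residuals(lm(rnorm(500) ~ u))           # exposure orthogonal to u
  fit1 <- mcp_fit(cbind(m1 = u), yy, xv, lambda = 0.2, gamma_mcp = 3,
                  tol = 1e-12)
  expect_equal(unname(fit1$beta_penalized), oracle_mcp_univariate(0.5, 0.2, 3),
               tolerance = 1e-8)
  expect_equal(unname(fit1$beta_penalized), 0.45, tolerance = 1e-8)

  # lambda beyond every correlation shrinks all mediators to zero
  fit2 <- mcp_fit(M, y, x, lambda = 10)
  expect_identical(fit2$support, character(0))
})

test_that("the BIC-selected support ignores mediator column order", {
  set.seed(34)
  n <- 250
  M <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, sprintf("m%02d", 1:15)))
  x <- rnorm(n)
  y <- as.numeric(M[, c(2, 9)] %*% c(0.6, -0.5) + 0.3 * x + rnorm(n))
  f1 <- mcp_fit(M, y, x)
  f2 <- mcp_fit(M[, sample(15)], y, x)
  expect_setequal(f1$support, f2$support)
  # support must be empty at the top of the default grid
  top <- mcp_fit(M, y, x, lambda = f1$lambda_grid[1])
  expect_identical(top$support, character(0))
})

test_that("joint significance applies the max-p rule with Bonferroni scaling", {
  set.seed(35)
  n <- 150
  m <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, sprintf("m%d", 1:8)))
  x <- rnorm(n, 20, 3)
  y <- 0.4 * m[, 1] + 0.1 * x + rnorm(n)
  res <- joint_significance(colnames(m)[1:5], m, y, x, covariates = NULL,
                            gamma_star = 0.1)
  expect_identical(nrow(res), 5L)
  expect_equal(res$joint_p_raw, pmax(res$p_alpha, res$p_beta))
  expect_equal(res$joint_p_adjusted, pmin(1, res$joint_p_raw * 5))
  expect_true(all(res$joint_p_adjusted >= res$joint_p_raw))
  expect_true(all(res$joint_p_adjusted <= 1))
  # alpha path matches a direct lm oracle
  o <- summary(lm(m[, 2] ~ x))$coefficients["x", ]
  r2 <- res[res$feature_id == "m2", ]
  expect_equal(r2$alpha_hat, unname(o["Estimate"]), tolerance = 1e-10)
  expect_equal(r2$p_alpha, unname(o["Pr(>|t|)"]), tolerance = 1e-10)
  # beta path comes from the joint refit of all five mediators
  ojoint <- summary(lm(y ~ m[, 1:5] + x))$coefficients
  expect_equal(res$beta_hat, unname(ojoint[2:6, "Estimate"]), tolerance = 1e-10)

  # empty support is a valid empty result
  empty <- joint_significance(character(0), m, y, x, gamma_star = 0.1)
  expect_identical(nrow(empty), 0L)

  # stated-rule arithmetic: (0.001, 0.04) with support 10 -> raw 0.04, adj 0.4
  expect_equal(min(1, max(0.001, 0.04) * 10), 0.4)
  expect_equal(min(1, max(0.5, 0.9) * 3), 1)
})

test_that("percent of total effect follows the product-over-total formula", {
  expect_equal(pct_total_effect(0.3, 0, 0.05), 0)
  expect_equal(pct_total_effect(0.036, -0.049, -0.026), 100 * 0.036 * -0.049 / -0.026)
  # inconsistent mediation: indirect effect opposing the total effect
  expect_lt(pct_total_effect(0.027, 0.106, -0.0177), 0)
  expect_error(pct_total_effect(0.1, 0.1, 0), "nonzero")
})

test_that("run_hima satisfies the exact OLS decomposition on small problems", {
  set.seed(36)
  for (rep in 1:5) {
    n <- 80; p <- 5
    co <- make_cohort(n, seed = 400 + rep)
    m <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("m%d", 1:p)))
    y <- rnorm(n) + 0.2 * co$bmi10 + m %*% rnorm(p, 0, 0.3)
    fit <- run_hima(m, co, outcome = as.numeric(y), exposure = "bmi10",
                    lambda = 0, standardize = FALSE)
    # gamma* - gamma = sum over all mediators of alpha_k beta_k, exactly
    Z <- mediomics:::covariate_matrix(co, model_spec("bmi10")$covariates)
    gamma_direct <- coef(lm(y ~ co$bmi10 + m + Z))[["co$bmi10"]]
    expect_identical(length(fit$penalized$support), 5L)
    gap <- fit$total_effect$gamma_star - gamma_direct
    expect_equal(gap, sum(fit$mediation$alpha_hat * fit$mediation$beta_hat),
                 tolerance = 1e-10)
  }
})

test_that("run_hima end-to-end recovers planted mediators", {
  st <- simulate_cohort(sim_config(n_samples = 300, n_features = 60,
                                   n_true_mediators = 3, alpha_effects = 0.5,
                                   beta_effects = 0.5, noise_sd_outcome = 1,
                                   missing_rate = 0, n_batches = 1,
                                   batch_shift_sd = 0, batch_scale_sd = 0,
                                   seed = 37))
  fit <- run_hima(st$truth$latent_standardized, st$cohort,
                  outcome = st$density$log10_vpd, exposure = "bmi10")
  sig <- fit$mediation$feature_id[fit$mediation$significant]
  expect_true(all(c("feat_0001", "feat_0002", "feat_0003") %in% sig))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  gl <- glance(fit)
  expect_identical(gl$n, 300L)
  expect_identical(gl$p, 60L)
})
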