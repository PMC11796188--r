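#' Exclude features with excess missing observations
#'
#' Drops every feature whose count of missing samples exceeds `max_missing`
#' (default 300, the absolute threshold used for a 700-woman cohort; set
#' `fraction = TRUE` to interpret `max_missing` as a fraction of the sample
#' count for other cohort sizes). Column order of the retained features is
#' preserved.
#'
#' @param features A feature table.
#' @param max_missing Maximum allowed number (or fraction) of missing samples
#'   per feature.
#' @param fraction If `TRUE`, `max_missing` is a fraction of `nrow(features)`.
#' @return The filtered feature table. The removed features and their missing
#'   counts are attached as a tibble in `attr(, "removal_report")`.
#' @export
#' @examples
#' ft <- tibble::tibble(sample_id = c("a", "b"), f1 = c(1, NA), f2 = c(1, 2))
#' filter_features(ft, max_missing = 0)
filter_features <- function(features, max_missing = 300, fraction = FALSE) {
  m <- fm_values(features)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty feature matrix", call. = FALSE)
  if (max_missing < 0) stop("max_missing must be >= 0", call. = FALSE)
  threshold <- if (fraction) max_missing * nrow(m) else max_missing
  miss <- colSums(is.na(m))
  drop <- miss > threshold
  report <- tibble::tibble(feature_id = colnames(m)[drop],
                           n_missing = unname(miss[drop]))
  keep_cols <- c(intersect(RESERVED_COLS, names(features)),
                 colnames(m)[!drop])
  out <- features[keep_cols]
  attr(out, "removal_report") <- report
  out
}

#' Impute missing cells by k-nearest-neighbour averaging
#'
#' Fills each missing cell with the mean value, at that sample, of the `k`
#' features nearest to the incomplete feature. Distance between two features
#' is the Euclidean metric over the samples where both are observed, scaled
#' by the number of shared samples (i.e. the root mean squared difference),
#' so features with different missingness patterns are comparable. Only
#' features observed at the target sample are candidate neighbours. Observed
#' cells are never altered. `orientation = "sample"` transposes the logic and
#' averages over the `k` nearest samples instead.
#'
#' @param features A feature table (already filtered).
#' @param k Number of neighbours (default 10).
#' @param orientation Whether neighbours are features (default) or samples.
#' @return The feature table with no missing cells.
#' @export
knn_impute <- function(features, k = 10, orientation = c("feature", "sample")) {
  orientation <- match.arg(orientation)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  m <- fm_values(features)
  if (!anyNA(m)) return(features)
  imputed <- if (orientation == "feature") {
    t(knn_impute_rows(t(m), k))
  } else {
    knn_impute_rows(m, k)
  }
  fm_rebuild(imputed, features)
}

# impute missing cells row-wise: each incomplete row borrows from its k
# nearest rows (RMS distance over co-observed columns)
knn_impute_rows <- function(x, k) {
  incomplete <- which(rowSums(is.na(x)) > 0)
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  out <- x   # imputations are computed from the original mask only
  for (i in incomplete) {
    # squared RMS distance from row i to every other row over shared columns
    oi <- obs[i, ]
    shared <- obs %*% oi                      # co-observed counts
    # sum over shared cols of (x_i - x_j)^2, computed with zero-filled copies
    d2sum <- as.numeric(
      (x0^2 %*% oi) - 2 * (x0 %*% (x0[i, ] * oi)) +
        obs %*% (x0[i, ]^2 * oi)
    )
    d2 <- ifelse(shared > 0, d2sum / shared, Inf)
    d2[i] <- Inf
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j] & is.finite(d2))
      if (length(cand) == 0)
        stop("no usable neighbours for '", rownames(x)[i] %||% i,
             "' at column ", colnames(x)[j] %||% j, call. = FALSE)
      ord <- cand[order(d2[cand], cand)]     # ties broken by row order
      nn <- utils::head(ord, k)
      out[i, j] <- mean(x0[nn, j])           # x0 == x on observed cells
    }
  }
  out
}

#' Log10-transform and standardize a feature matrix
#'
#' Applies the analysis-scale transform: each feature is log10-transformed
#' (to improve homoscedasticity) and then z-scored so that a unit change
#' equals one standard deviation of the feature. Requires a complete,
#' strictly positive matrix (run after imputation).
#'
#' @param features A complete feature table with positive values.
#' @return A feature table of standardized log10 values (per-feature mean 0,
#'   SD 1).
#' @export
#' @examples
#' ft <- tibble::tibble(sample_id = c("a", "b", "c"), f1 = c(10, 100, 1000))
#' log10_standardize(ft)  # f1 becomes (-1, 0, 1)
log10_standardize <- function(features) {
  m <- fm_values(features)
  if (anyNA(m)) stop("matrix has missing cells; impute first", call. = FALSE)
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive value at sample ", rownames(m)[bad[1, 1]] %||% bad[1, 1],
         ", feature ", colnames(m)[bad[1, 2]], call. = FALSE)
  }
  fm_rebuild(zscore_cols(log10(m)), features)
}

#' Derive volumetric density measures from dense and total volume
#'
#' Computes volumetric percent density (VPD = dense volume / total volume),
#' non-dense volume (NDV = total - dense) and their log10 versions. Records
#' violating the physical constraints (`0 < DV <= total`) are flagged invalid
#' and excluded from the returned table, mirroring how a handful of women in
#' a screening cohort lack usable density measures; a record with `DV ==
#' total` is kept for VPD/DV analyses but its log10 NDV is undefined (`NA`).
#'
#' @param density A data frame with columns `dense_volume` and `total_volume`
#'   (cm^3) and optionally `sample_id`.
#' @return A tibble of valid records with `dense_volume`, `nondense_volume`,
#'   `total_volume`, `vpd` and their `log10_` versions. Flagged records are
#'   attached as `attr(, "invalid_report")`.
#' @export
#' @examples
#' derive_density(tibble::tibble(dense_volume = 100, total_volume = 1000))
derive_density <- function(density) {
  stopifnot(all(c("dense_volume", "total_volume") %in% names(density)))
  d <- tibble::as_tibble(density)
  if (!"sample_id" %in% names(d)) d$sample_id <- sprintf("S%04d", seq_len(nrow(d)))
  dv <- d$dense_volume; total <- d$total_volume
  invalid <- !is.finite(dv) | !is.finite(total) | dv <= 0 | total <= 0 | dv > total
  reason <- dplyr::case_when(
    !is.finite(dv) | !is.finite(total) ~ "non-finite volume",
    dv <= 0 | total <= 0 ~ "non-positive volume",
    dv > total ~ "dense volume exceeds total volume",
    .default = NA_character_
  )
  report <- tibble::tibble(sample_id = d$sample_id[invalid],
                           reason = reason[invalid])
  ok <- d[!invalid, ]
  dv <- ok$dense_volume; total <- ok$total_volume
  ndv <- total - dv
  out <- tibble::tibble(
    sample_id = ok$sample_id,
    dense_volume = dv,
    nondense_volume = ndv,
    total_volume = total,
    vpd = dv / total,
    log10_dv = log10(dv),
    log10_ndv = ifelse(ndv > 0, log10(ndv), NA_real_),
    log10_total = log10(total),
    log10_vpd = log10(dv / total)
  )
  attr(out, "invalid_report") <- report
  out
}

#' Impute missing covariates by chained equations
#'
#' Fills missing exposure/covariate values by iteratively regressing each
#' incomplete variable on all the others — linear regression with a normal
#' residual draw for continuous variables, logistic regression for binary
#' variables, and one-versus-rest logistic scoring for the 3-level race
#' variable — cycling `n_iterations` times from a random-draw initialisation.
#' A single completed table is returned (the analysis uses one imputed
#' dataset, not multiple).
#'
#' @param cohort A cohort tibble (`bmi10`, `bmi18`, `age`, `race`,
#'   `family_history`, `age_menarche`; any may contain `NA`).
#' @param n_iterations Number of chained-equation cycles (default 10).
#' @param seed Integer seed.
#' @return The completed cohort tibble.
#' @export
impute_covariates <- function(cohort, n_iterations = 10, seed = 1L) {
  vars <- intersect(c("bmi10", "bmi18", "age", "race", "family_history",
                      "age_menarche"), names(cohort))
  d <- tibble::as_tibble(cohort)
  miss <- lapply(d[vars], function(col) which(is.na(col)))
  if (all(lengths(miss) == 0)) return(d)
  zero_obs <- vars[vapply(d[vars], function(col) all(is.na(col)), logical(1))]
  if (length(zero_obs) > 0)
    stop("variable(s) with no observed values: ",
         paste(zero_obs, collapse = ", "), call. = FALSE)

  with_seed(seed, {
    # initialise each missing cell with a random observed draw
    for (v in vars) {
      idx <- miss[[v]]
      if (length(idx) > 0) {
        pool <- d[[v]][!is.na(d[[v]])]
        d[[v]][idx] <- sample(pool, length(idx), replace = TRUE)
      }
    }
    active <- vars[lengths(miss) > 0]
    for (iter in seq_len(n_iterations)) {
      for (v in active) {
        idx <- miss[[v]]
        preds <- setdiff(vars, v)
        X <- covariate_design_for_mice(d, preds)
        d[[v]] <- impute_one_variable(d[[v]], X, idx)
      }
    }
  })
  d
}

covariate_design_for_mice <- function(d, preds) {
  blocks <- lapply(preds, function(v) {
    col <- d[[v]]
    if (v == "race") race_dummies(col)
    else matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, v))
  })
  do.call(cbind, blocks)
}

impute_one_variable <- function(y, X, idx) {
  if (is.factor(y) || is.character(y)) {
    # one-vs-rest logistic scores, normalised to class probabilities
    lv <- if (is.factor(y)) levels(y) else sort(unique(y))
    scores <- vapply(lv, function(l) {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, X), as.numeric(y == l),
                       family = stats::binomial())
      )
      as.numeric(cbind(1, X) %*% fit$coefficients)
    }, numeric(length(y)))
    pr <- exp(scores - apply(scores, 1, max))
    pr <- pr / rowSums(pr)
    draws <- vapply(idx, function(i) sample(lv, 1, prob = pr[i, ]), character(1))
    y[idx] <- if (is.factor(y)) factor(draws, levels = lv) else draws
  } else if (all(y %in% c(0, 1))) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), y, family = stats::binomial())
    )
    pr <- 1 / (1 + exp(-as.numeric(cbind(1, X) %*% fit$coefficients)))
    y[idx] <- stats::rbinom(length(idx), 1, pr[idx])
  } else {
    fit <- ols_fit(y, X)
    mu <- cbind(1, X) %*% c(fit$coef)
    sigma <- sqrt(fit$sigma2)
    y[idx] <- mu[idx] + stats::rnorm(length(idx), sd = sigma)
  }
  y
}
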