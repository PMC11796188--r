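#' Covariate sets for the two BMI exposures
#'
#' The BMI-at-age-10 models adjust for age at enrollment, race (non-Hispanic
#' white reference, non-Hispanic black, other) and family history of breast
#' cancer; the BMI-at-age-18 models additionally adjust for age at menarche
#' and BMI at age 10.
#'
#' @param exposure `"bmi10"` or `"bmi18"`.
#' @return A list with `exposure` and the ordered `covariates` vector.
#' @export
model_spec <- function(exposure = c("bmi10", "bmi18")) {
  exposure <- match.arg(exposure)
  covariates <- c("age", "race", "family_history")
  if (exposure == "bmi18") covariates <- c(covariates, "age_menarche", "bmi10")
  list(exposure = exposure, covariates = covariates)
}

# design pieces for an exposure model: exposure vector + covariate matrix
exposure_design <- function(cohort, exposure) {
  spec <- model_spec(exposure)
  list(exposure = as.numeric(cohort[[spec$exposure]]),
       Z = covariate_matrix(cohort, spec$covariates),
       spec = spec)
}

#' Fit one feature's covariate-adjusted exposure model
#'
#' Ordinary least squares of a (standardized) feature on the exposure plus
#' covariates, returning the exposure coefficient with its standard error and
#' two-sided t-test p-value.
#'
#' @param feature Numeric response vector (one feature, analysis scale).
#' @param exposure Numeric exposure vector (e.g. BMI in kg/m^2).
#' @param covariates Numeric covariate matrix (no intercept column), or
#'   `NULL`.
#' @return A one-row tibble: `estimate`, `std_error`, `statistic`, `p_value`,
#'   `direction`.
#' @export
fit_feature_model <- function(feature, exposure, covariates = NULL) {
  X <- cbind(exposure = exposure, covariates)
  fit <- ols_fit(feature, X)
  tibble::tibble(
    estimate = fit$coef[["exposure"]],
    std_error = fit$se[["exposure"]],
    statistic = fit$t[["exposure"]],
    p_value = fit$p[["exposure"]],
    direction = ifelse(fit$coef[["exposure"]] >= 0, "positive", "inverse")
  )
}

#' Metabolome/lipidome-wide association scan against a BMI exposure
#'
#' Regresses every feature on the exposure with the exposure's covariate set
#' (see [model_spec()]), then applies Benjamini-Hochberg false-discovery-rate
#' control across the features of the scanned platform. Features enter as the
#' response (`feature ~ exposure + covariates`, matching the mediator model);
#' `orientation = "exposure_on_feature"` flips the roles.
#'
#' @param features A feature table on the analysis scale (complete; see
#'   [log10_standardize()]).
#' @param cohort A cohort tibble aligned row-for-row with `features`.
#' @param exposure `"bmi10"` or `"bmi18"`.
#' @param fdr_threshold Significance cut point on the BH q-value
#'   (default 0.1).
#' @param orientation Which variable is the regression response.
#' @return A tibble of class `assoc_scan`, one row per feature, sorted by
#'   p-value: `feature_id`, `estimate`, `std_error`, `statistic`, `p_value`,
#'   `q_value`, `direction`, `significant`.
#' @export
scan_associations <- function(features, cohort,
                              exposure = c("bmi10", "bmi18"),
                              fdr_threshold = 0.1,
                              orientation = c("feature_on_exposure",
                                              "exposure_on_feature")) {
  exposure <- match.arg(exposure)
  orientation <- match.arg(orientation)
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop("fdr_threshold must lie in (0, 1]", call. = FALSE)
  m <- fm_values(features)
  if (anyNA(m)) stop("feature matrix has missing cells; preprocess first",
                     call. = FALSE)
  des <- exposure_design(cohort, exposure)
  if (nrow(m) != length(des$exposure))
    stop("features and cohort have different sample counts", call. = FALSE)

  res <- if (orientation == "feature_on_exposure") {
    scan_multiresponse(m, des$exposure, des$Z)
  } else {
    # exposure as response, one fit per feature
    purrr::map_dfr(seq_len(ncol(m)), function(j) {
      fit <- ols_fit(des$exposure, cbind(exposure = m[, j], des$Z))
      tibble::tibble(estimate = fit$coef[["exposure"]],
                     std_error = fit$se[["exposure"]],
                     statistic = fit$t[["exposure"]],
                     p_value = fit$p[["exposure"]])
    })
  }
  out <- dplyr::mutate(
    dplyr::bind_cols(tibble::tibble(feature_id = colnames(m)), res),
    q_value = stats::p.adjust(.data$p_value, method = "BH"),
    direction = ifelse(.data$estimate >= 0, "positive", "inverse"),
    significant = .data$q_value < fdr_threshold
  )
  out <- dplyr::arrange(out, .data$p_value, .data$feature_id)
  structure(out, class = c("assoc_scan", class(out)),
            exposure = exposure, fdr_threshold = fdr_threshold,
            orientation = orientation)
}

# OLS of every feature (columns of Y) on [1, exposure, Z]: one QR, shared
# hat matrix, per-feature residual variance for the exposure SE
scan_multiresponse <- function(Y, exposure, Z) {
  X <- cbind(`(Intercept)` = 1, exposure = exposure, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keepers <- colnames(X)[qrX$pivot[seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(setdiff(colnames(X), keepers), collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  v_exp <- XtXinv["exposure", "exposure"]
  est <- beta["exposure", ]
  se <- sqrt(sigma2 * v_exp)
  tval <- est / se
  tibble::tibble(
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(tval),
    p_value = unname(2 * stats::pt(abs(tval), df, lower.tail = FALSE))
  )
}
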