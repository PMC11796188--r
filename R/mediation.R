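#' Estimate the total effect of the exposure on the outcome
#'
#' Ordinary least squares of the outcome (a log10 breast-density measure) on
#' the exposure and covariates, without any mediators: the exposure
#' coefficient is the total effect `gamma_star` used in the denominator of
#' the proportion-mediated statistic.
#'
#' @param outcome Numeric outcome vector (e.g. log10 VPD).
#' @param exposure Numeric exposure vector (kg/m^2).
#' @param covariates Numeric covariate matrix (no intercept), or `NULL`.
#' @return An object of class `total_effect_fit` with `gamma_star`,
#'   `std_error`, `p_value`, `intercept`, `delta_y`, `n`, `df`.
#' @export
estimate_total_effect <- function(outcome, exposure, covariates = NULL) {
  X <- cbind(exposure = exposure, covariates)
  fit <- ols_fit(outcome, X)
  structure(list(
    gamma_star = unname(fit$coef["exposure"]),
    std_error = unname(fit$se["exposure"]),
    p_value = unname(fit$p["exposure"]),
    intercept = unname(fit$coef["(Intercept)"]),
    delta_y = fit$coef[setdiff(names(fit$coef), c("(Intercept)", "exposure"))],
    residuals = fit$residuals,
    n = length(outcome), df = fit$df
  ), class = "total_effect_fit")
}

#' @export
print.total_effect_fit <- function(x, ...) {
  cat("<total_effect_fit> gamma* = ", format(x$gamma_star, digits = 4),
      " (SE ", format(x$std_error, digits = 3),
      ", p = ", format(x$p_value, digits = 3), "), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Sure-independence screening of candidate mediators
#'
#' Ranks every feature by the absolute t-statistic of its coefficient in the
#' exposure-adjusted outcome model `outcome ~ mediator + exposure +
#' covariates`, and keeps the top `d`. The default screening budget is
#' `ceiling(2 n / log(n))`, the usual sure-independence-screening choice for
#' a continuous outcome. Ties are broken by feature order.
#'
#' @param features Feature table or matrix on the analysis scale (complete).
#' @param outcome,exposure Numeric vectors.
#' @param covariates Numeric covariate matrix or `NULL`.
#' @param d Screening budget; `"auto"` (default) uses `ceiling(2n/log(n))`.
#' @return An object of class `screen_result`: tibble of kept features with
#'   their screening statistic, plus attributes `d` and `statistic_all`.
#' @export
screen_mediators <- function(features, outcome, exposure, covariates = NULL,
                             d = "auto") {
  m <- if (is.matrix(features)) features else fm_values(features)
  n <- nrow(m)
  if (identical(d, "auto")) d <- ceiling(2 * n / log(n))
  d <- as.integer(d)
  if (d <= 0) stop("screening budget d must be > 0", call. = FALSE)

  # Frisch-Waugh: partial outcome and each mediator on [1, exposure, Z];
  # the partial correlation gives the exact OLS t for the mediator term
  W <- cbind(1, exposure, covariates)
  qrW <- qr(W)
  ry <- qr.resid(qrW, outcome)
  RM <- qr.resid(qrW, m)
  df <- n - ncol(W) - 1
  if (df <= 0) stop("not enough samples for the screening model", call. = FALSE)
  num <- colSums(RM * ry)
  den <- sqrt(colSums(RM^2) * sum(ry^2))
  rho <- ifelse(den > 0, num / den, 0)
  rho <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- rho * sqrt(df / (1 - rho^2))

  ids <- colnames(m) %||% sprintf("feat_%04d", seq_len(ncol(m)))
  ord <- order(-abs(tstat), seq_along(tstat))
  keep <- sort(ord[seq_len(min(d, ncol(m)))])
  kept <- tibble::tibble(feature_id = ids[keep],
                         statistic = abs(tstat)[keep],
                         t_mediator = tstat[keep])
  structure(list(kept = kept, d = d,
                 statistic_all = stats::setNames(abs(tstat), ids),
                 tie_break_rule = "descending |t|, ties by feature order"),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> kept ", nrow(x$kept), " of ",
      length(x$statistic_all), " features (budget d = ", x$d, ")\n", sep = "")
  invisible(x)
}

#' Minimax-concave-penalty selection of mediators
#'
#' Coordinate-descent solution of penalized least squares
#' `(1/2n)||y - Xb||^2 + sum_j MCP(b_j; lambda, gamma_mcp)` where only the
#' mediator columns are penalized; the exposure and covariates always stay in
#' the model. Mediator columns are internally centred and scaled to
#' `x'x/n = 1` (coefficients are reported on the original scale). The
#' penalty level is chosen by BIC over a 100-point log-spaced grid from
#' `lambda_max` (smallest lambda with an empty mediator support) down to
#' `0.01 * lambda_max`, solved with warm starts; ties in BIC go to the
#' sparser (larger) lambda. The solver is deterministic.
#'
#' @param mediators Matrix (or feature table) of candidate mediators,
#'   analysis scale.
#' @param outcome,exposure Numeric vectors.
#' @param covariates Numeric covariate matrix or `NULL`.
#' @param lambda Optional penalty grid (decreasing); default as above. A
#'   single value fits just that penalty.
#' @param gamma_mcp MCP concavity parameter (> 1; default 3).
#' @param tol Convergence tolerance on the maximum coefficient change
#'   (default 1e-7).
#' @param max_iter Maximum coordinate-descent sweeps per lambda.
#' @return An object of class `penalized_fit`: `support` (selected feature
#'   ids), `beta_penalized` (mediator coefficients at the selected lambda,
#'   original scale), `selected_lambda`, `lambda_grid`, `bic`, `gamma_mcp`,
#'   and the full coefficient `path`.
#' @export
mcp_fit <- function(mediators, outcome, exposure, covariates = NULL,
                    lambda = NULL, gamma_mcp = 3, tol = 1e-7,
                    max_iter = 10000L) {
  m <- if (is.matrix(mediators)) mediators else fm_values(mediators)
  ids <- colnames(m) %||% sprintf("feat_%04d", seq_len(ncol(m)))
  if (gamma_mcp <= 1) stop("gamma_mcp must be > 1", call. = FALSE)
  n <- nrow(m)
  U <- cbind(exposure = exposure, covariates)   # unpenalized block
  colnames(U)[1] <- "exposure"

  # centre everything (intercept handled implicitly); scale mediators to
  # x'x/n = 1 so lambda is on the standardized scale
  yc <- outcome - mean(outcome)
  mc <- sweep(m, 2, colMeans(m), "-")
  scale_m <- sqrt(colSums(mc^2) / n)
  if (any(scale_m <= 0)) stop("constant mediator column(s)", call. = FALSE)
  ms <- sweep(mc, 2, scale_m, "/")
  Uc <- sweep(U, 2, colMeans(U), "-")

  X <- cbind(ms, Uc)
  penalized <- c(rep(1L, ncol(ms)), rep(0L, ncol(Uc)))

  if (is.null(lambda)) {
    r0 <- qr.resid(qr(cbind(1, Uc)), yc)
    lambda_max <- max(abs(crossprod(ms, r0)) / n)
    lambda <- if (lambda_max > 0) {
      exp(seq(log(lambda_max), log(0.01 * lambda_max), length.out = 100))
    } else 0
  } else {
    lambda <- as.numeric(lambda)
  }
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)

  G <- crossprod(X) / n
  cvec <- as.numeric(crossprod(X, yc)) / n
  sol <- mcp_cd_cov(G, cvec, penalized, lambda, gamma_mcp, tol,
                    as.integer(max_iter))
  if (!all(sol$converged)) {
    bad <- which(!sol$converged)
    stop("MCP coordinate descent did not converge at lambda = ",
         paste(format(lambda[bad], digits = 4), collapse = ", "),
         " after ", max_iter, " sweeps (tol ", tol, ")", call. = FALSE)
  }

  beta_path <- sol$beta
  fit_path <- X %*% beta_path
  rss <- colSums((yc - fit_path)^2)
  df <- colSums(beta_path != 0) + 1   # + intercept
  bic <- n * log(rss / n) + log(n) * df
  best <- which.min(bic)              # ties resolve to the larger lambda

  b_sel <- beta_path[seq_len(ncol(ms)), best] / scale_m   # original scale
  names(b_sel) <- ids
  support <- ids[b_sel != 0]

  structure(list(
    support = support,
    beta_penalized = b_sel,
    unpenalized = stats::setNames(beta_path[-seq_len(ncol(ms)), best],
                                  colnames(Uc)),
    selected_lambda = lambda[best],
    lambda_grid = lambda,
    bic = bic,
    gamma_mcp = gamma_mcp,
    path = beta_path,
    n = n
  ), class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat("<penalized_fit> ", length(x$support), " mediators selected at lambda = ",
      format(x$selected_lambda, digits = 4), " (gamma_mcp = ", x$gamma_mcp,
      ")\n", sep = "")
  invisible(x)
}

#' Joint-significance test for the selected mediators
#'
#' For each mediator in the support: the mediator-to-outcome path `beta_k`
#' comes from one unpenalized OLS refit of the outcome on all selected
#' mediators plus exposure and covariates; the exposure-to-mediator path
#' `alpha_k` comes from OLS of the mediator on exposure and covariates. The
#' raw joint p-value is `max(p_alpha, p_beta)` and is Bonferroni-scaled by
#' the support size (reported as the FDR p-value, following the convention of
#' the high-dimensional mediation literature; `adjust = "BH"` gives
#' Benjamini-Hochberg instead).
#'
#' @param support Character vector of selected feature ids (may be empty).
#' @param features Feature table or matrix containing at least the support
#'   columns.
#' @param outcome,exposure Numeric vectors.
#' @param covariates Numeric covariate matrix or `NULL`.
#' @param gamma_star Total effect used for the proportion mediated (from
#'   [estimate_total_effect()]).
#' @param threshold Significance cut point on the adjusted p (default 0.1).
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return A tibble, one row per supported mediator: `feature_id`,
#'   `alpha_hat`, `alpha_se`, `p_alpha`, `beta_hat`, `beta_se`, `p_beta`,
#'   `gamma_star`, `pct_total_effect`, `joint_p_raw`, `joint_p_adjusted`,
#'   `significant`.
#' @export
joint_significance <- function(support, features, outcome, exposure,
                               covariates = NULL, gamma_star,
                               threshold = 0.1,
                               adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  if (length(support) == 0) return(empty_mediation_tbl())
  m <- if (is.matrix(features)) features else fm_values(features)
  missing_ids <- setdiff(support, colnames(m))
  if (length(missing_ids) > 0)
    stop("support ids not in feature matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  M <- m[, support, drop = FALSE]

  # outcome refit: y ~ all selected mediators + exposure + covariates
  yfit <- ols_fit(outcome, cbind(M, exposure = exposure, covariates))
  beta_hat <- yfit$coef[support]
  beta_se <- yfit$se[support]
  p_beta <- yfit$p[support]

  # mediator models: M_k ~ exposure + covariates (shared design, one QR)
  W <- cbind(`(Intercept)` = 1, exposure = exposure, covariates)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) stop("rank-deficient exposure/covariate design",
                               call. = FALSE)
  Bm <- qr.coef(qrW, M)
  resM <- M - W %*% Bm
  dfm <- nrow(W) - ncol(W)
  sig2 <- colSums(resM^2) / dfm
  WtWinv <- chol2inv(qr.R(qrW))[order(qrW$pivot), order(qrW$pivot), drop = FALSE]
  dimnames(WtWinv) <- list(colnames(W), colnames(W))
  alpha_hat <- Bm["exposure", ]
  alpha_se <- sqrt(sig2 * WtWinv["exposure", "exposure"])
  p_alpha <- 2 * stats::pt(abs(alpha_hat / alpha_se), dfm, lower.tail = FALSE)

  raw <- pmax(p_alpha, p_beta)
  adj <- if (adjust == "bonferroni") pmin(1, raw * length(support))
         else stats::p.adjust(raw, method = "BH")
  pct <- pct_total_effect(unname(alpha_hat), unname(beta_hat), gamma_star)

  tibble::tibble(
    feature_id = support,
    alpha_hat = unname(alpha_hat), alpha_se = unname(alpha_se),
    p_alpha = unname(p_alpha),
    beta_hat = unname(beta_hat), beta_se = unname(beta_se),
    p_beta = unname(p_beta),
    gamma_star = gamma_star,
    pct_total_effect = pct,
    joint_p_raw = unname(raw),
    joint_p_adjusted = unname(adj),
    significant = unname(adj) < threshold
  )
}

empty_mediation_tbl <- function() {
  tibble::tibble(
    feature_id = character(), alpha_hat = numeric(), alpha_se = numeric(),
    p_alpha = numeric(), beta_hat = numeric(), beta_se = numeric(),
    p_beta = numeric(), gamma_star = numeric(), pct_total_effect = numeric(),
    joint_p_raw = numeric(), joint_p_adjusted = numeric(),
    significant = logical()
  )
}

#' Proportion of the total effect carried by a mediator
#'
#' Computes `100 * alpha_hat * beta_hat / gamma_star`, the percentage of the
#' exposure's total effect on the outcome that flows through the mediator.
#' The value is negative under inconsistent mediation (indirect effect
#' opposing the total effect) and may exceed 100.
#'
#' @param alpha_hat Exposure-to-mediator coefficient(s).
#' @param beta_hat Mediator-to-outcome coefficient(s).
#' @param gamma_star Total effect (nonzero scalar).
#' @return Percentage(s).
#' @export
#' @examples
#' pct_total_effect(0.036, -0.049, -0.0265)  # about 6.7%
pct_total_effect <- function(alpha_hat, beta_hat, gamma_star) {
  if (length(gamma_star) != 1 || !is.finite(gamma_star) || gamma_star == 0)
    stop("gamma_star must be a single nonzero finite value", call. = FALSE)
  100 * alpha_hat * beta_hat / gamma_star
}

#' High-dimensional mediation analysis
#'
#' The full procedure linking a BMI exposure to a breast-density outcome
#' through an omics panel: (1) total-effect OLS of the outcome on exposure
#' and covariates; (2) sure-independence screening of the mediators
#' ([screen_mediators()]); (3) minimax-concave-penalty selection among the
#' screened mediators with exposure and covariates unpenalized
#' ([mcp_fit()]); (4) joint-significance testing of the surviving mediators
#' with multiplicity adjustment ([joint_significance()]); and (5) the
#' proportion of the total effect carried by each mediator. Deterministic
#' end to end.
#'
#' @param features Feature table (analysis scale, complete) or matrix.
#' @param cohort Cohort tibble aligned with `features`; ignored if both
#'   `exposure` and `covariates` are supplied as numerics.
#' @param outcome Numeric outcome vector (e.g. `log10_vpd` from
#'   [derive_density()]).
#' @param exposure `"bmi10"`, `"bmi18"` (looked up in `cohort` with the
#'   matching covariate set) or a numeric vector.
#' @param covariates Numeric covariate matrix; derived from `cohort` via
#'   [model_spec()] when `exposure` is named.
#' @param d Screening budget (see [screen_mediators()]).
#' @param lambda,gamma_mcp,tol Passed to [mcp_fit()].
#' @param threshold Significance cut point on the adjusted joint p
#'   (default 0.1).
#' @param adjust Multiplicity adjustment, `"bonferroni"` (default) or
#'   `"BH"`.
#' @param standardize Re-standardize mediator columns before analysis
#'   (default `TRUE`; a no-op on an already standardized grid).
#' @return An object of class `hima_fit`: `mediation` (tibble of all tested
#'   mediators), `total_effect`, `screen`, `penalized`, plus run metadata.
#'   `tidy()` returns the mediation table, `glance()` the run summary.
#' @export
run_hima <- function(features, cohort = NULL, outcome,
                     exposure = c("bmi10", "bmi18"), covariates = NULL,
                     d = "auto", lambda = NULL, gamma_mcp = 3, tol = 1e-7,
                     threshold = 0.1, adjust = c("bonferroni", "BH"),
                     standardize = TRUE) {
  adjust <- match.arg(adjust)
  m <- if (is.matrix(features)) features else fm_values(features)
  if (is.null(colnames(m))) colnames(m) <- sprintf("feat_%04d", seq_len(ncol(m)))
  if (is.character(exposure)) {
    exposure <- match.arg(exposure)
    if (is.null(cohort)) stop("named exposure requires a cohort table", call. = FALSE)
    des <- exposure_design(cohort, exposure)
    exposure_name <- des$spec$exposure
    exposure <- des$exposure
    if (is.null(covariates)) covariates <- des$Z
  } else {
    exposure_name <- "exposure"
  }
  if (anyNA(m) || anyNA(outcome) || anyNA(exposure))
    stop("inputs contain missing values; preprocess first", call. = FALSE)
  if (standardize) m <- zscore_cols(m, label = "mediator")

  total <- estimate_total_effect(outcome, exposure, covariates)
  screen <- screen_mediators(m, outcome, exposure, covariates, d = d)
  kept <- m[, screen$kept$feature_id, drop = FALSE]
  pen <- mcp_fit(kept, outcome, exposure, covariates,
                 lambda = lambda, gamma_mcp = gamma_mcp, tol = tol)
  mediation <- joint_significance(pen$support, m, outcome, exposure,
                                  covariates, gamma_star = total$gamma_star,
                                  threshold = threshold, adjust = adjust)
  structure(list(
    mediation = mediation,
    total_effect = total,
    screen = screen,
    penalized = pen,
    exposure = exposure_name,
    threshold = threshold,
    adjust = adjust,
    n = nrow(m), p = ncol(m), d = screen$d,
    support_size = length(pen$support)
  ), class = "hima_fit")
}

#' @export
print.hima_fit <- function(x, ...) {
  cat("<hima_fit> exposure ", x$exposure, ": n = ", x$n, ", p = ", x$p,
      ", screened d = ", x$d, ", support = ", x$support_size, "\n", sep = "")
  cat("  total effect gamma* = ", format(x$total_effect$gamma_star, digits = 4),
      " (p = ", format(x$total_effect$p_value, digits = 3), ")\n", sep = "")
  sig <- dplyr::filter(x$mediation, .data$significant)
  cat("  significant mediators at adjusted p < ", x$threshold, ": ",
      nrow(sig), "\n", sep = "")
  if (nrow(sig) > 0) print(sig[c("feature_id", "alpha_hat", "beta_hat",
                                 "pct_total_effect", "joint_p_adjusted")])
  invisible(x)
}
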