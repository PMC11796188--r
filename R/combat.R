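#' Empirical-Bayes location/scale batch adjustment
#'
#' Removes per-batch location and scale artifacts from a feature matrix using
#' the ComBat model: each feature is standardized against its grand mean and
#' pooled variance, per-batch means and variances of the standardized data
#' are estimated, optionally shrunk across features by parametric empirical
#' Bayes (normal prior on the location effects, inverse-gamma prior on the
#' scale effects, solved by the usual fixed-point iteration), and the
#' adjusted data are back-transformed. After adjustment, per-feature means
#' and variances are homogeneous across batches.
#'
#' Because assay intensities are approximately log-normal, the adjustment is
#' applied on the log10 scale by default and back-transformed to the positive
#' scale (`transform = "log10"`); use `transform = "none"` for values already
#' on an analysis scale. With `eb = FALSE` the raw batch estimates are used
#' without shrinkage, which makes the operation exactly idempotent.
#'
#' @param features A feature table (complete; no missing cells).
#' @param batch Batch labels; defaults to the table's `batch` column.
#' @param eb Apply parametric empirical-Bayes shrinkage across features
#'   (default `TRUE`).
#' @param transform `"log10"` (adjust log10 values, back-transform) or
#'   `"none"`.
#' @return The adjusted feature table.
#' @export
combat_adjust <- function(features, batch = NULL,
                          eb = TRUE, transform = c("log10", "none")) {
  transform <- match.arg(transform)
  m <- fm_values(features)
  if (anyNA(m)) stop("matrix has missing cells; impute before batch adjustment",
                     call. = FALSE)
  batch <- batch %||% features[["batch"]]
  if (is.null(batch)) stop("no batch labels supplied", call. = FALSE)
  batch <- as.character(batch)
  if (length(batch) != nrow(m)) stop("batch length != sample count", call. = FALSE)

  tab <- table(batch)
  if (length(tab) == 1L) {
    message("single batch; nothing to adjust")
    return(features)
  }
  if (any(tab < 2))
    stop("batch(es) with < 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)

  if (transform == "log10") {
    if (any(m <= 0)) stop("log10 transform requires positive values", call. = FALSE)
    m <- log10(m)
  }
  adj <- combat_core(m, batch, eb = eb)
  if (transform == "log10") adj <- 10^adj
  fm_rebuild(adj, features)
}

combat_core <- function(X, batch, eb) {
  labels <- sort(unique(batch))
  B <- length(labels); n <- nrow(X)
  idx <- lapply(labels, function(b) which(batch == b))
  nb <- lengths(idx)

  batch_means <- t(vapply(idx, function(rows) colMeans(X[rows, , drop = FALSE]),
                          numeric(ncol(X))))
  grand <- colSums(batch_means * (nb / n))
  # unbiased pooled within-batch variance (denominator n - B); keeping the
  # estimators consistent makes the non-EB adjustment exactly idempotent
  ss <- 0
  for (b in seq_len(B)) {
    dev <- sweep(X[idx[[b]], , drop = FALSE], 2, batch_means[b, ], "-")
    ss <- ss + colSums(dev^2)
  }
  pooled_var <- ss / (n - B)
  if (any(pooled_var <= 0))
    stop("feature(s) with zero pooled variance cannot be batch-adjusted",
         call. = FALSE)
  sdat <- sweep(sweep(X, 2, grand, "-"), 2, sqrt(pooled_var), "/")

  gamma_hat <- t(vapply(idx, function(rows) colMeans(sdat[rows, , drop = FALSE]),
                        numeric(ncol(X))))
  delta_hat <- t(vapply(idx, function(rows)
    apply(sdat[rows, , drop = FALSE], 2, stats::var), numeric(ncol(X))))

  if (eb) {
    gamma_star <- gamma_hat; delta_star <- delta_hat
    for (b in seq_len(B)) {
      sol <- eb_fixed_point(sdat[idx[[b]], , drop = FALSE],
                            gamma_hat[b, ], delta_hat[b, ], nb[b])
      gamma_star[b, ] <- sol$gamma
      delta_star[b, ] <- sol$delta
    }
  } else {
    gamma_star <- gamma_hat; delta_star <- delta_hat
  }

  out <- sdat
  for (b in seq_len(B)) {
    rows <- idx[[b]]
    out[rows, ] <- sweep(sweep(sdat[rows, , drop = FALSE], 2,
                               gamma_star[b, ], "-"),
                         2, sqrt(delta_star[b, ]), "/")
  }
  sweep(sweep(out, 2, sqrt(pooled_var), "*"), 2, grand, "+")
}

# parametric EB fixed point for one batch (normal prior on gamma,
# inverse-gamma prior on delta, hyperparameters by method of moments)
eb_fixed_point <- function(s_b, g_hat, d_hat, n_b, tol = 1e-6, max_iter = 500) {
  g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
  m <- mean(d_hat); s2 <- stats::var(d_hat)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_new <- g_hat; d_new <- d_hat
  for (it in seq_len(max_iter)) {
    g_old <- g_new; d_old <- d_new
    g_new <- (t2 * n_b * g_hat + d_new * g_bar) / (t2 * n_b + d_new)
    sse <- colSums(sweep(s_b, 2, g_new, "-")^2)
    d_new <- (0.5 * sse + b_prior) / (n_b / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                  abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
    if (change < tol) break
  }
  list(gamma = g_new, delta = d_new)
}
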