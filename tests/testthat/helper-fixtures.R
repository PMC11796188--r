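# Shared fixture builders and independent oracles.

# small feature table with optional NA cells
make_feature_table <- function(values, sample_ids = NULL, batch = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  tb <- tibble::as_tibble(as.data.frame(values))
  ids <- sample_ids %||% sprintf("s%02d", seq_len(nrow(values)))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = ids), tb)
  if (!is.null(batch)) out <- dplyr::bind_cols(out[1], tibble::tibble(batch = batch), out[-1])
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# toy cohort with all covariates, no missingness
make_cohort <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    bmi10 = rnorm(n, 17.4, 2.8),
    bmi18 = rnorm(n, 22.1, 4.4),
    age = rnorm(n, 46, 5),
    race = factor(sample(c("non-hispanic white", "non-hispanic black", "other"),
                         n, replace = TRUE, prob = c(0.72, 0.23, 0.05)),
                  levels = c("non-hispanic white", "non-hispanic black", "other")),
    family_history = rbinom(n, 1, 0.22),
    age_menarche = rnorm(n, 12.9, 1.5)
  )
}

# Brute-force oracle for feature-space kNN imputation: exhaustive pairwise
# RMS distances over co-observed samples, k nearest features observed at the
# target sample, plain mean. Written independently of the package internals.
oracle_knn_impute <- function(m, k) {
  out <- m
  p <- ncol(m)
  for (f in seq_len(p)) {
    miss_samples <- which(is.na(m[, f]))
    for (s in miss_samples) {
      d <- rep(Inf, p)
      for (g in seq_len(p)) {
        if (g == f) next
        shared <- which(!is.na(m[, f]) & !is.na(m[, g]))
        if (length(shared) == 0 || is.na(m[s, g])) next
        d[g] <- sqrt(sum((m[shared, f] - m[shared, g])^2) / length(shared))
      }
      cand <- which(is.finite(d))
      ord <- cand[order(d[cand], cand)]
      nn <- head(ord, k)
      out[s, f] <- mean(m[s, nn])
    }
  }
  out
}

# closed-form univariate MCP solution for an orthonormal predictor
oracle_mcp_univariate <- function(z, lambda, gamma) {
  if (abs(z) <= lambda) return(0)
  if (abs(z) <= gamma * lambda) return(sign(z) * (abs(z) - lambda) / (1 - 1 / gamma))
  z
}
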