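# Internal helpers shared across modules.
#
# A "feature table" throughout the package is a tibble with a `sample_id`
# column, an optional `batch` column, and one numeric column per feature
# (metabolite peak area or lipid concentration). Samples are rows.

RESERVED_COLS <- c("sample_id", "batch")

feature_cols <- function(df) setdiff(names(df), RESERVED_COLS)

# tibble -> samples x features numeric matrix (rownames = sample ids)
fm_values <- function(df) {
  stopifnot(is.data.frame(df))
  feats <- feature_cols(df)
  if (length(feats) == 0L) stop("feature table has no feature columns", call. = FALSE)
  m <- as.matrix(df[feats])
  storage.mode(m) <- "double"
  if ("sample_id" %in% names(df)) rownames(m) <- as.character(df$sample_id)
  m
}

# matrix -> tibble, carrying over sample_id/batch from a template table
fm_rebuild <- function(values, template) {
  out <- tibble::as_tibble(as.data.frame(values))
  keep <- intersect(RESERVED_COLS, names(template))
  dplyr::bind_cols(template[keep], out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

RACE_LEVELS <- c("non-hispanic white", "non-hispanic black", "other")

# race factor -> two dummies against the non-Hispanic-white reference
race_dummies <- function(race) {
  race <- factor(as.character(race), levels = RACE_LEVELS)
  if (anyNA(race)) stop("race contains values outside the three recognised levels", call. = FALSE)
  cbind(
    race_nhb   = as.numeric(race == RACE_LEVELS[2]),
    race_other = as.numeric(race == RACE_LEVELS[3])
  )
}

# Covariate design (no intercept column) for a model_spec applied to a cohort
covariate_matrix <- function(cohort, covariates) {
  blocks <- lapply(covariates, function(v) {
    switch(v,
      race = race_dummies(cohort$race),
      {
        col <- cohort[[v]]
        if (is.null(col)) stop("covariate '", v, "' not found in cohort", call. = FALSE)
        m <- matrix(as.numeric(col), ncol = 1)
        colnames(m) <- v
        m
      }
    )
  })
  do.call(cbind, blocks)
}

# OLS of y on cbind(1, X); returns estimates, SEs, t, p and residuals.
# Errors on rank deficiency, naming the collinear columns.
ols_fit <- function(y, X) {
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keepers <- colnames(X)[qrX$pivot[seq_len(qrX$rank)]]
    bad <- setdiff(colnames(X), keepers)
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop("not enough observations for the design (n <= p)", call. = FALSE)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- as.numeric(beta) / se
  list(
    coef = stats::setNames(as.numeric(beta), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    t = stats::setNames(tval, colnames(X)),
    p = stats::setNames(2 * stats::pt(abs(tval), df, lower.tail = FALSE), colnames(X)),
    residuals = as.numeric(res),
    df = df,
    sigma2 = sigma2
  )
}

# column z-score with sample SD; errors on zero variance
zscore_cols <- function(m, label = "feature") {
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad) > 0) {
    stop("zero-variance ", label, "(s): ",
         paste(colnames(m)[bad] %||% bad, collapse = ", "), call. = FALSE)
  }
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}
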