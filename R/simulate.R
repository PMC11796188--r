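#' Simulation configuration for a synthetic premenopausal cohort
#'
#' Bundles every knob of the data-generating process: the cohort size, the
#' omics panel size, the sparse mediation structure (which features truly sit
#' on the path from BMI to breast density and with what strength), covariate
#' and exposure distributions, residual noise, and the artifact layers
#' (missing cells, batch shifts/scales) that the preprocessing pipeline must
#' undo.
#'
#' The structural model is the standard high-dimensional mediation triplet:
#' mediators follow `M_k = c_k + BMI * alpha_k + Z * delta_k + e_k` on the
#' standardized analysis scale, and the outcome (log10 volumetric percent
#' density) follows `y = c + BMI * gamma + sum_k M_k * beta_k + Z * delta_y +
#' eps`. The implied total effect is `gamma_star = gamma + sum(alpha * beta)`.
#'
#' Defaults mirror the cohort the package emulates: n = 700 women, p = 828
#' features, BMI at age 10 with mean 17.4 and SD 2.8 kg/m^2, BMI at age 18
#' with mean 22.1 and SD 4.4 kg/m^2, race proportions of roughly 72/23/5
#' percent (non-Hispanic white / non-Hispanic black / other), about 22% with
#' a family history of breast cancer, and a metabolite-like 1.3% rate of
#' missing cells.
#'
#' @param n_samples Number of women.
#' @param n_features Number of omics features (metabolites or lipid species).
#' @param n_true_mediators Number of features that truly mediate; these are
#'   the first `n_true_mediators` feature columns.
#' @param alpha_effects Exposure-to-mediator coefficients (SD of mediator per
#'   kg/m^2), scalar or length `n_true_mediators`.
#' @param beta_effects Mediator-to-outcome coefficients (log10-density per SD
#'   of mediator), scalar or length `n_true_mediators`.
#' @param gamma_direct Direct exposure-to-outcome coefficient.
#' @param exposure Which BMI drives the structural equations, `"bmi10"` or
#'   `"bmi18"`.
#' @param exposure_spec List with `mean_bmi10`, `sd_bmi10`, `mean_bmi18`,
#'   `sd_bmi18`, `cor` (correlation between the two BMI measures).
#' @param covariate_spec List with `age_mean`, `age_sd`, `race_probs`
#'   (length 3, sums to 1), `family_history_prob`, `menarche_mean`,
#'   `menarche_sd`.
#' @param delta_mediator,delta_outcome Covariate coefficients for the
#'   mediator and outcome equations, scalar (recycled) or length 5 in the
#'   design order age, race (2 dummies), family history, age at menarche.
#' @param intercept_outcome Outcome intercept `c`; the default places mean
#'   log10 VPD near -1 (about 10% density) at the exposure mean.
#' @param noise_sd_mediator Residual SD of each mediator equation.
#' @param noise_sd_outcome Residual SD of the outcome equation.
#' @param missing_rate Fraction of feature cells deleted completely at random.
#' @param n_batches Number of assay batches.
#' @param batch_shift_sd,batch_scale_sd SD of the per-batch/per-feature
#'   additive shift and of the log multiplicative factor, both on the log10
#'   scale.
#' @param total_volume_spec List with `log10_mean`, `log10_sd` for total
#'   breast volume (cm^3); the default centres volumes near 800 cm^3.
#' @param feature_shift_range Range of per-feature affine shifts applied
#'   before exponentiation to the positive peak-area scale.
#' @param seed Integer seed; the whole simulation is bit-reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 700,
                       n_features = 828,
                       n_true_mediators = 4,
                       alpha_effects = 0.04,
                       beta_effects = -0.05,
                       gamma_direct = -0.02,
                       exposure = c("bmi10", "bmi18"),
                       exposure_spec = list(mean_bmi10 = 17.4, sd_bmi10 = 2.8,
                                            mean_bmi18 = 22.1, sd_bmi18 = 4.4,
                                            cor = 0.6),
                       covariate_spec = list(age_mean = 46, age_sd = 5,
                                             race_probs = c(0.724, 0.231, 0.045),
                                             family_history_prob = 0.219,
                                             menarche_mean = 12.9, menarche_sd = 1.5),
                       delta_mediator = 0,
                       delta_outcome = 0,
                       intercept_outcome = NULL,
                       noise_sd_mediator = 1,
                       noise_sd_outcome = 0.2,
                       missing_rate = 0.013,
                       n_batches = 5,
                       batch_shift_sd = 0.3,
                       batch_scale_sd = 0.1,
                       total_volume_spec = list(log10_mean = 2.9, log10_sd = 0.15),
                       feature_shift_range = c(3, 7),
                       seed = 1L) {
  exposure <- match.arg(exposure)
  cfg <- list(
    n_samples = as.integer(n_samples), n_features = as.integer(n_features),
    n_true_mediators = as.integer(n_true_mediators),
    alpha_effects = rep_len(alpha_effects, max(n_true_mediators, 1L))[seq_len(n_true_mediators)],
    beta_effects = rep_len(beta_effects, max(n_true_mediators, 1L))[seq_len(n_true_mediators)],
    gamma_direct = gamma_direct, exposure = exposure,
    exposure_spec = exposure_spec, covariate_spec = covariate_spec,
    delta_mediator = rep_len(delta_mediator, 5L),
    delta_outcome = rep_len(delta_outcome, 5L),
    intercept_outcome = intercept_outcome,
    noise_sd_mediator = noise_sd_mediator, noise_sd_outcome = noise_sd_outcome,
    missing_rate = missing_rate, n_batches = as.integer(n_batches),
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    total_volume_spec = total_volume_spec,
    feature_shift_range = feature_shift_range,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_true_mediators > cfg$n_features)
    stop("n_true_mediators must not exceed n_features", call. = FALSE)
  if (cfg$n_true_mediators < 0 || cfg$n_samples < 2 || cfg$n_features < 1)
    stop("invalid cohort/panel dimensions", call. = FALSE)
  sds <- c(cfg$noise_sd_mediator, cfg$noise_sd_outcome,
           cfg$exposure_spec$sd_bmi10, cfg$exposure_spec$sd_bmi18,
           cfg$covariate_spec$age_sd, cfg$covariate_spec$menarche_sd,
           cfg$total_volume_spec$log10_sd)
  if (any(sds <= 0)) stop("all SDs must be > 0", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (cfg$n_batches < 1) stop("n_batches must be >= 1", call. = FALSE)
  if (abs(sum(cfg$covariate_spec$race_probs) - 1) > 1e-8)
    stop("race probabilities must sum to 1", call. = FALSE)
  if (cfg$batch_shift_sd < 0 || cfg$batch_scale_sd < 0)
    stop("batch artifact SDs must be >= 0", call. = FALSE)
  invisible(cfg)
}

# evaluate code under a seed, then restore the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a full synthetic mediation study
#'
#' Draws a cohort (exposures and covariates), latent standardized mediators
#' and a log10 volumetric-percent-density outcome from the structural
#' mediation equations, then layers on the measurement artifacts a real
#' metabolomics matrix carries: features are pushed to a positive peak-area
#' scale (`10^(M + shift_k)`), batch location/scale effects are applied on the
#' log scale, and cells are deleted completely at random. Dense and non-dense
#' volumes are back-derived from the simulated VPD and total breast volume so
#' the three density measures are mutually consistent.
#'
#' @param config A [sim_config()].
#' @return An object of class `simulated_study`: a list with
#'   * `cohort` — tibble of `sample_id`, `bmi10`, `bmi18`, `age`, `race`,
#'     `family_history`, `age_menarche`;
#'   * `features_raw` — feature table (`sample_id`, `batch`, features) on the
#'     positive scale with missing cells;
#'   * `density` — tibble of `sample_id`, `dense_volume`, `nondense_volume`,
#'     `total_volume`, `vpd` and `log10_vpd`;
#'   * `truth` — the generator-side parameters (class `true_params`),
#'     including the latent standardized mediator matrix the preprocessing
#'     pipeline should reconstruct.
#' @export
#' @examples
#' study <- simulate_cohort(sim_config(n_samples = 50, n_features = 20, seed = 7))
#' dim(study$features_raw)
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples; p <- cfg$n_features; ntrue <- cfg$n_true_mediators
  es <- cfg$exposure_spec; cs <- cfg$covariate_spec

  # correlated BMI pair
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  bmi10 <- es$mean_bmi10 + es$sd_bmi10 * z1
  bmi18 <- es$mean_bmi18 + es$sd_bmi18 * (es$cor * z1 + sqrt(1 - es$cor^2) * z2)
  cohort <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    bmi10 = bmi10, bmi18 = bmi18,
    age = stats::rnorm(n, cs$age_mean, cs$age_sd),
    race = factor(sample(RACE_LEVELS, n, replace = TRUE, prob = cs$race_probs),
                  levels = RACE_LEVELS),
    family_history = stats::rbinom(n, 1, cs$family_history_prob),
    age_menarche = stats::rnorm(n, cs$menarche_mean, cs$menarche_sd)
  )

  B <- cohort[[cfg$exposure]]
  Z <- covariate_matrix(cohort, c("age", "race", "family_history", "age_menarche"))

  alpha <- numeric(p); beta <- numeric(p)
  if (ntrue > 0) {
    alpha[seq_len(ntrue)] <- cfg$alpha_effects
    beta[seq_len(ntrue)] <- cfg$beta_effects
  }
  exposure_mean <- if (cfg$exposure == "bmi10") es$mean_bmi10 else es$mean_bmi18
  c_k <- -exposure_mean * alpha   # centres each mediator at the exposure mean

  # mediators on the standardized (analysis) scale
  M <- matrix(stats::rnorm(n * p, sd = cfg$noise_sd_mediator), n, p)
  M <- M + outer(B, alpha) + matrix(rep(c_k, each = n), n, p) +
    (Z %*% cfg$delta_mediator)[, 1]

  c0 <- cfg$intercept_outcome %||% (-1 - exposure_mean * cfg$gamma_direct)
  y <- c0 + B * cfg$gamma_direct + as.numeric(M %*% beta) +
    as.numeric(Z %*% cfg$delta_outcome) +
    stats::rnorm(n, sd = cfg$noise_sd_outcome)

  feature_ids <- sprintf("feat_%04d", seq_len(p))
  colnames(M) <- feature_ids
  latent_std <- zscore_cols(M)

  # positive peak-area scale; log10 of the raw value is an affine image of M
  shifts <- stats::runif(p, cfg$feature_shift_range[1], cfg$feature_shift_range[2])
  raw <- 10^sweep(latent_std, 2, shifts, "+")
  batch <- sample(sprintf("batch%02d", seq_len(cfg$n_batches)), n, replace = TRUE)
  features <- dplyr::bind_cols(
    tibble::tibble(sample_id = cohort$sample_id, batch = batch),
    tibble::as_tibble(as.data.frame(raw))
  )
  if (cfg$n_batches > 1 && (cfg$batch_shift_sd > 0 || cfg$batch_scale_sd > 0)) {
    features <- inject_batch_effects(features, n_batches = cfg$n_batches,
                                     shift_sd = cfg$batch_shift_sd,
                                     scale_sd = cfg$batch_scale_sd,
                                     seed = cfg$seed + 1L)
  }
  if (cfg$missing_rate > 0) {
    features <- inject_missingness(features, rate = cfg$missing_rate,
                                   seed = cfg$seed + 2L)
  }

  tv <- cfg$total_volume_spec
  total <- 10^stats::rnorm(n, tv$log10_mean, tv$log10_sd)
  vpd <- 10^y
  density <- tibble::tibble(
    sample_id = cohort$sample_id,
    dense_volume = vpd * total,
    nondense_volume = total - vpd * total,
    total_volume = total,
    vpd = vpd,
    log10_vpd = y
  )

  truth <- structure(list(
    alpha = stats::setNames(alpha, feature_ids),
    beta = stats::setNames(beta, feature_ids),
    gamma_direct = cfg$gamma_direct,
    delta_mediator = cfg$delta_mediator,
    delta_outcome = cfg$delta_outcome,
    intercepts = list(outcome = c0, mediator = stats::setNames(c_k, feature_ids)),
    implied_total_effect = cfg$gamma_direct + sum(alpha * beta),
    exposure = cfg$exposure,
    latent_standardized = latent_std,
    feature_shifts = stats::setNames(shifts, feature_ids)
  ), class = "true_params")

  structure(list(cohort = cohort, features_raw = features,
                 density = density, truth = truth, config = cfg),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> ", nrow(x$cohort), " women x ",
      length(feature_cols(x$features_raw)), " features; ",
      sum(x$truth$alpha != 0), " true mediators; exposure ", x$truth$exposure,
      "\n", sep = "")
  invisible(x)
}

#' Delete feature cells completely at random
#'
#' Emulates the sparse missingness of assay matrices (about 0.4% of lipid and
#' 1.3% of metabolite cells in the cohort this package models). Each cell is
#' deleted independently with probability `rate`; observed values are never
#' altered.
#'
#' @param features A feature table (tibble with `sample_id`, optional `batch`,
#'   and numeric feature columns).
#' @param rate Deletion probability in `[0, 1)`.
#' @param seed Integer seed for the mask.
#' @return The feature table with cells set to `NA`.
#' @export
inject_missingness <- function(features, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(features)
  m <- fm_values(features)
  mask <- with_seed(seed, matrix(stats::runif(length(m)) < rate, nrow(m), ncol(m)))
  m[mask] <- NA_real_
  fm_rebuild(m, features)
}

#' Apply batch location/scale artifacts on the log scale
#'
#' For each batch and feature, draws an additive shift `~ Normal(0,
#' shift_sd^2)` and a multiplicative factor `exp(Normal(0, scale_sd^2))` and
#' applies them to the log10 values: deviations from the feature's grand mean
#' are scaled by the factor, then shifted. This creates exactly the
#' location/scale structure that empirical-Bayes batch adjustment
#' ([combat_adjust()]) is designed to remove. Explicit `shift_matrix` /
#' `scale_matrix` (batches x features, recycled from shorter input) override
#' the random draws, which is convenient for constructing exact fixtures.
#'
#' @param features A feature table; if it lacks a `batch` column, labels are
#'   assigned uniformly at random.
#' @param n_batches Number of batches (>= 1).
#' @param shift_sd,scale_sd Artifact magnitudes on the log10 scale.
#' @param seed Integer seed.
#' @param shift_matrix,scale_matrix Optional explicit artifact matrices.
#' @return The feature table with artifacts applied and `batch` recorded.
#' @export
inject_batch_effects <- function(features, n_batches, shift_sd = 0.3,
                                 scale_sd = 0.1, seed = 1L,
                                 shift_matrix = NULL, scale_matrix = NULL) {
  if (n_batches < 1) stop("n_batches must be >= 1", call. = FALSE)
  m <- fm_values(features)
  p <- ncol(m)
  labels <- sprintf("batch%02d", seq_len(n_batches))
  if (!"batch" %in% names(features)) {
    features$batch <- with_seed(seed + 7L,
                                sample(labels, nrow(m), replace = TRUE))
  }
  batch <- as.character(features$batch)
  if (n_batches == 1 && is.null(shift_matrix) && is.null(scale_matrix) &&
      shift_sd == 0 && scale_sd == 0) {
    return(features)
  }
  shifts <- if (is.null(shift_matrix)) {
    with_seed(seed, matrix(stats::rnorm(n_batches * p, sd = shift_sd), n_batches, p))
  } else matrix(shift_matrix, n_batches, p)
  scales <- if (is.null(scale_matrix)) {
    with_seed(seed + 1L, matrix(exp(stats::rnorm(n_batches * p, sd = scale_sd)), n_batches, p))
  } else matrix(scale_matrix, n_batches, p)
  unique_labels <- sort(unique(batch))
  if (length(unique_labels) > n_batches)
    stop("batch column has ", length(unique_labels), " labels but n_batches = ",
         n_batches, call. = FALSE)
  shifts <- shifts[seq_along(unique_labels), , drop = FALSE]
  scales <- scales[seq_along(unique_labels), , drop = FALSE]
  rownames(shifts) <- rownames(scales) <- unique_labels

  L <- log10(m)
  mu <- colMeans(L, na.rm = TRUE)
  for (b in unique_labels) {
    rows <- which(batch == b)
    dev <- sweep(L[rows, , drop = FALSE], 2, mu, "-")
    dev <- sweep(dev, 2, scales[b, ], "*")
    L[rows, ] <- sweep(dev, 2, mu + shifts[b, ], "+")
  }
  out <- fm_rebuild(10^L, features)
  out$batch <- batch
  out
}

#' Write a simulated study to plain-text files
#'
#' Writes `cohort.csv`, `features.csv`, `density.csv` and a `truth.txt`
#' key-value sidecar (true coefficients, one `name<TAB>value` pair per line)
#' into `dir`.
#'
#' @param study A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$cohort, file.path(dir, "cohort.csv"), na = "NA")
  readr::write_csv(study$features_raw, file.path(dir, "features.csv"), na = "NA")
  readr::write_csv(study$density, file.path(dir, "density.csv"), na = "NA")
  tr <- study$truth
  kv <- c(
    sprintf("gamma_direct\t%.17g", tr$gamma_direct),
    sprintf("implied_total_effect\t%.17g", tr$implied_total_effect),
    sprintf("exposure\t%s", tr$exposure),
    sprintf("alpha_%s\t%.17g", names(tr$alpha)[tr$alpha != 0], tr$alpha[tr$alpha != 0]),
    sprintf("beta_%s\t%.17g", names(tr$beta)[tr$beta != 0], tr$beta[tr$beta != 0])
  )
  writeLines(kv, file.path(dir, "truth.txt"))
  invisible(dir)
}
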