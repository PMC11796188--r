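#' Configuration for an end-to-end pipeline run
#'
#' Declares every stage input of [run_pipeline()]: either paths to cohort /
#' feature / density CSVs, or a [sim_config()] used to simulate them;
#' preprocessing thresholds (missingness cutoff, kNN neighbours, batch
#' adjustment); and the analysis settings (exposures, outcomes, FDR cut
#' point).
#'
#' @param out_dir Output directory for tables and the run report.
#' @param simulation A [sim_config()] (used when no input paths are given).
#' @param cohort_csv,features_csv,density_csv Optional input paths; when all
#'   three are given the simulation stage is skipped.
#' @param platform `"metabolite"` (batch-adjusted with ComBat) or `"lipid"`
#'   (concentrations; ComBat skipped).
#' @param max_missing Missingness cutoff for [filter_features()].
#' @param k Neighbour count for [knn_impute()].
#' @param fdr FDR cut point for scans and mediation (default 0.1).
#' @param exposures Exposures to analyse.
#' @param outcomes Density outcomes to analyse (`"vpd"`, `"dv"`, `"ndv"`).
#' @param adjust Multiplicity adjustment for the joint test.
#' @param seed Integer seed (simulation and covariate imputation).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("mediomics_run_"),
                            simulation = sim_config(),
                            cohort_csv = NULL, features_csv = NULL,
                            density_csv = NULL,
                            platform = c("metabolite", "lipid"),
                            max_missing = 300, k = 10, fdr = 0.1,
                            exposures = c("bmi10", "bmi18"),
                            outcomes = "vpd",
                            adjust = "bonferroni",
                            seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(max_missing >= 0, k >= 1, fdr > 0, fdr <= 1)
  exposures <- match.arg(exposures, c("bmi10", "bmi18"), several.ok = TRUE)
  outcomes <- match.arg(outcomes, c("vpd", "dv", "ndv"), several.ok = TRUE)
  paths <- c(cohort_csv, features_csv, density_csv)
  if (length(paths) > 0) {
    if (length(paths) != 3)
      stop("supply all three of cohort_csv, features_csv, density_csv, or none",
           call. = FALSE)
    missing_paths <- paths[!file.exists(paths)]
    if (length(missing_paths) > 0)
      stop("input file(s) not found: ", paste(missing_paths, collapse = ", "),
           call. = FALSE)
  }
  structure(list(
    out_dir = out_dir, simulation = simulation,
    cohort_csv = cohort_csv, features_csv = features_csv,
    density_csv = density_csv, platform = platform,
    max_missing = max_missing, k = k, fdr = fdr,
    exposures = exposures, outcomes = outcomes, adjust = adjust,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Sequences the stages of the study design: simulate (or load) the cohort,
#' feature matrix and density table; impute missing covariates by chained
#' equations; filter features on missingness, impute remaining cells by
#' k-nearest neighbours, batch-adjust (metabolite platform only) and
#' log10-standardize; derive the volumetric density measures; run the
#' association scan and the high-dimensional mediation analysis for each
#' requested exposure and outcome; and write every result table under
#' `config$out_dir`. Fully reproducible under a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `report` (per-stage record counts and
#'   parameters), `scans` and `hima` (named lists of results), and the
#'   processed tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[mediomics] ", ...)

  if (is.null(config$cohort_csv)) {
    log_stage("simulating study (seed ", config$seed, ")")
    sim <- config$simulation
    sim$seed <- config$seed
    study <- simulate_cohort(sim)
    cohort <- study$cohort
    features <- study$features_raw
    density_in <- study$density
  } else {
    log_stage("loading input tables")
    cohort <- readr::read_csv(config$cohort_csv, show_col_types = FALSE,
                              na = c("", "NA"))
    if ("race" %in% names(cohort)) cohort$race <- factor(cohort$race,
                                                         levels = RACE_LEVELS)
    features <- readr::read_csv(config$features_csv, show_col_types = FALSE,
                                na = c("", "NA"))
    density_in <- readr::read_csv(config$density_csv, show_col_types = FALSE,
                                  na = c("", "NA"))
  }
  counts <- list(samples_in = nrow(cohort),
                 features_in = length(feature_cols(features)))

  log_stage("imputing covariates (chained equations)")
  cohort <- impute_covariates(cohort, seed = config$seed + 10L)

  log_stage("filtering features (max_missing = ", config$max_missing, ")")
  features <- filter_features(features, max_missing = config$max_missing)
  removal <- attr(features, "removal_report")
  counts$features_removed <- nrow(removal)
  counts$features_kept <- length(feature_cols(features))
  readr::write_tsv(removal, file.path(config$out_dir, "removed_features.tsv"))

  log_stage("imputing feature cells (", config$k, "-NN)")
  features <- knn_impute(features, k = config$k)

  if (config$platform == "metabolite" &&
      length(unique(features$batch %||% "b1")) > 1) {
    log_stage("batch adjustment (empirical Bayes)")
    features <- combat_adjust(features)
  } else {
    log_stage("skipping batch adjustment (", config$platform, " platform)")
  }

  log_stage("log10 transform + unit-SD standardization")
  grid <- log10_standardize(features)

  log_stage("deriving density measures")
  density <- derive_density(density_in)
  invalid <- attr(density, "invalid_report")
  counts$density_in <- nrow(density_in)
  counts$density_valid <- nrow(density)
  if (nrow(invalid) > 0)
    readr::write_tsv(invalid, file.path(config$out_dir, "invalid_density.tsv"))

  # align all tables on the valid density records
  keep <- match(density$sample_id, cohort$sample_id)
  cohort_a <- cohort[keep, ]
  grid_a <- grid[keep, ]
  outcome_cols <- c(vpd = "log10_vpd", dv = "log10_dv", ndv = "log10_ndv")

  scans <- list(); hima <- list()
  for (exp in config$exposures) {
    log_stage("association scan: ", exp)
    sc <- scan_associations(grid_a, cohort_a, exposure = exp,
                            fdr_threshold = config$fdr)
    scans[[exp]] <- sc
    readr::write_tsv(tibble::as_tibble(sc),
                     file.path(config$out_dir, paste0("scan_", exp, ".tsv")))
    for (out in config$outcomes) {
      y <- density[[outcome_cols[[out]]]]
      ok <- is.finite(y)
      log_stage("mediation: ", exp, " -> ", out,
                " (n = ", sum(ok), ")")
      fit <- run_hima(grid_a[ok, ], cohort_a[ok, ], outcome = y[ok],
                      exposure = exp, threshold = config$fdr,
                      adjust = config$adjust)
      key <- paste(exp, out, sep = "_")
      hima[[key]] <- fit
      write_mediation_table(
        dplyr::mutate(fit$mediation, exposure = exp, outcome = toupper(out)),
        file.path(config$out_dir, paste0("mediation_", key, ".tsv"))
      )
    }
  }

  report <- list(
    counts = counts,
    parameters = config[c("platform", "max_missing", "k", "fdr",
                          "exposures", "outcomes", "adjust", "seed")],
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  writeLines(
    c(paste0(names(unlist(counts)), "\t", unlist(counts)),
      paste0("wall_time_s\t", format(report$wall_time_s, digits = 4))),
    file.path(config$out_dir, "run_report.tsv")
  )
  invisible(list(report = report, scans = scans, hima = hima,
                 cohort = cohort, features = grid, density = density))
}

#' Write a publication-style mediation table
#'
#' Renders mediation results in the layout of the study tables: one row per
#' mediator with the exposure-to-mediator coefficient, mediator-to-outcome
#' coefficient, percent of total effect and adjusted (FDR) p-value, grouped
#' into labelled blocks when `exposure`/`outcome` columns are present.
#' Coefficients are formatted to 3 decimals, percentages to 2.
#'
#' @param results A mediation tibble (from `tidy()` on a [run_hima()] fit),
#'   optionally with `exposure`, `outcome` and `super_pathway` columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mediation_table <- function(results, path) {
  cols <- c(mediator = "feature_id", alpha = "alpha_hat", beta = "beta_hat",
            pct_total_effect = "pct_total_effect",
            fdr_p_value = "joint_p_adjusted")
  present <- cols[cols %in% names(results)]
  out <- tibble::as_tibble(results)[unname(present)]
  names(out) <- names(present)
  if ("super_pathway" %in% names(results)) out$super_pathway <- results$super_pathway
  fmt <- dplyr::mutate(
    out,
    dplyr::across(dplyr::any_of(c("alpha", "beta")), ~ sprintf("%.3f", .x)),
    dplyr::across(dplyr::any_of("pct_total_effect"), ~ sprintf("%.2f", .x)),
    dplyr::across(dplyr::any_of("fdr_p_value"), ~ sprintf("%.3g", .x))
  )
  group_cols <- intersect(c("exposure", "outcome"), names(results))
  lines <- paste(names(fmt), collapse = "\t")
  if (length(group_cols) > 0 && nrow(results) > 0) {
    keys <- do.call(paste, c(results[group_cols], sep = " / "))
    for (kk in unique(keys)) {
      lines <- c(lines, paste0("# ", kk))
      block <- fmt[keys == kk, ]
      lines <- c(lines, do.call(paste, c(block, sep = "\t")))
    }
  } else if (nrow(fmt) > 0) {
    lines <- c(lines, do.call(paste, c(fmt, sep = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}
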