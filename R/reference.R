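#' Published mediation estimates bundled with the package
#'
#' The per-mediator estimates printed for the premenopausal screening cohort
#' the package models: exposure-to-mediator coefficient (`alpha`),
#' mediator-to-outcome coefficient (`beta`), percent of the total effect
#' mediated and the FDR p-value, for each exposure (BMI at age 10 / 18),
#' outcome (volumetric percent density, non-dense volume) and platform
#' (metabolites, lipid species). These rows are *inputs* to consistency
#' checks — the cohort itself is private — and anchor the arithmetic that
#' ties `alpha * beta / (pct/100)` back to a common total effect per block.
#'
#' @param platform `"both"` (default), `"metabolite"` or `"lipid"`.
#' @return A tibble with columns `platform`, `outcome`, `exposure`,
#'   `mediator`, `alpha`, `beta`, `pct_total_effect`, `fdr_p`,
#'   `super_pathway`.
#' @export
reference_mediation_tables <- function(platform = c("both", "metabolite", "lipid")) {
  platform <- match.arg(platform)
  files <- c(metabolite = "table2_metabolites.tsv", lipid = "table3_lipids.tsv")
  if (platform != "both") files <- files[platform]
  tbl <- purrr::map_dfr(files, function(f) {
    readr::read_tsv(system.file("extdata", f, package = "mediomics"),
                    show_col_types = FALSE)
  })
  tibble::as_tibble(tbl)
}

#' Reconstruct the total effect implied by printed mediation rows
#'
#' Each printed row satisfies `pct = 100 * alpha * beta / gamma_star`, so the
#' total effect it implies is `alpha * beta / (pct / 100)`. Within one
#' exposure-outcome-platform block every row shares the same `gamma_star`,
#' which makes the implied values a strong internal-consistency check on the
#' printed bookkeeping: their spread reflects only rounding of the printed
#' coefficients.
#'
#' @param tbl A tibble shaped like [reference_mediation_tables()] (needs
#'   `alpha`, `beta`, `pct_total_effect` and the block columns `platform`,
#'   `outcome`, `exposure`).
#' @return The input with an `implied_gamma_star` column, plus a per-block
#'   summary (median, coefficient of variation, row count) in
#'   `attr(, "block_summary")`.
#' @export
implied_total_effects <- function(tbl) {
  out <- dplyr::mutate(tbl,
    implied_gamma_star = .data$alpha * .data$beta / (.data$pct_total_effect / 100))
  summary <- dplyr::summarise(
    dplyr::group_by(out, .data$platform, .data$outcome, .data$exposure),
    n = dplyr::n(),
    median_gamma_star = stats::median(.data$implied_gamma_star),
    cv = stats::sd(.data$implied_gamma_star) /
      abs(mean(.data$implied_gamma_star)),
    .groups = "drop"
  )
  attr(out, "block_summary") <- summary
  out
}

#' Recover each printed percent-mediated value from its block
#'
#' Recomputes every row's percent of total effect from its printed `alpha`
#' and `beta` and the block-median implied total effect (computed from the
#' *other* rows of its block, so the row under test is held out), via
#' [pct_total_effect()]. Agreement within rounding tolerance demonstrates
#' that the three printed quantities are mutually consistent.
#'
#' @param tbl As in [implied_total_effects()].
#' @return The input tibble with `pct_reconstructed` and `pct_error`
#'   (reconstructed minus printed, percentage points) columns.
#' @export
reconstruct_pct_total_effect <- function(tbl) {
  imp <- implied_total_effects(tbl)
  blocks <- paste(imp$platform, imp$outcome, imp$exposure)
  rec <- vapply(seq_len(nrow(imp)), function(i) {
    others <- setdiff(which(blocks == blocks[i]), i)
    g <- if (length(others) > 0) stats::median(imp$implied_gamma_star[others])
         else imp$implied_gamma_star[i]
    pct_total_effect(imp$alpha[i], imp$beta[i], g)
  }, numeric(1))
  dplyr::mutate(tbl, pct_reconstructed = rec,
                pct_error = rec - .data$pct_total_effect)
}
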