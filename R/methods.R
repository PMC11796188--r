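# broom-style accessors and ggplot2 autoplot methods

#' @export
tidy.hima_fit <- function(x, ...) x$mediation

#' @export
glance.hima_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p, d = x$d,
    support_size = x$support_size,
    n_significant = sum(x$mediation$significant),
    gamma_star = x$total_effect$gamma_star,
    gamma_star_se = x$total_effect$std_error,
    gamma_star_p = x$total_effect$p_value,
    selected_lambda = x$penalized$selected_lambda,
    threshold = x$threshold,
    adjust = x$adjust
  )
}

#' @export
tidy.total_effect_fit <- function(x, ...) {
  tibble::tibble(term = "exposure", estimate = x$gamma_star,
                 std_error = x$std_error, p_value = x$p_value)
}

#' @export
glance.total_effect_fit <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, gamma_star = x$gamma_star,
                 p_value = x$p_value)
}

#' @export
tidy.assoc_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.assoc_scan <- function(x, ...) {
  tibble::tibble(
    exposure = attr(x, "exposure"),
    n_features = nrow(x),
    n_significant = sum(x$significant),
    fdr_threshold = attr(x, "fdr_threshold")
  )
}

#' Volcano-style summary of an association scan
#'
#' Plots each feature's covariate-adjusted exposure coefficient against its
#' -log10 p-value, coloured by FDR significance.
#'
#' @param object An [scan_associations()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "estimate (per-SD feature change per unit exposure)",
      y = expression(-log[10] * "(p)"),
      colour = paste0("FDR q < ", attr(object, "fdr_threshold")),
      title = paste0("Association scan: ", attr(object, "exposure"))
    ) +
    ggplot2::theme_minimal()
}

#' Proportion-mediated summary of a mediation fit
#'
#' Dot plot of the percent of the total effect carried by each tested
#' mediator, coloured by joint-significance outcome.
#'
#' @param object A [run_hima()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hima_fit <- function(object, ...) {
  df <- object$mediation
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no mediators selected") +
             ggplot2::theme_void())
  }
  df <- dplyr::mutate(df, feature_id = stats::reorder(.data$feature_id,
                                                      .data$pct_total_effect))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct_total_effect,
                                   y = .data$feature_id,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "% of total effect mediated", y = NULL,
                  colour = paste0("adjusted p < ", object$threshold)) +
    ggplot2::theme_minimal()
}
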