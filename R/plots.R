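#' Plot GMT score distribution by stratum
#'
#' @param strata Tibble from [stratify_by_median()].
#' @return A ggplot object.
#' @export
plot_gmt_scores <- function(strata) {
  ggplot2::ggplot(strata, ggplot2::aes(x = .data$group, y = .data$score,
                                       fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "GMT stratum", y = "GMT score (mes - pn enrichment)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential expression results
#'
#' @param de Tibble from [de_test()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$flag)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heat map
#'
#' @param mtc Tibble from [module_trait_correlation()].
#' @return A ggplot object.
#' @export
plot_module_trait <- function(mtc) {
  ggplot2::ggplot(mtc, ggplot2::aes(x = .data$trait, y = .data$module,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(p=%.1e)", .data$r, .data$p_value)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson R") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curve plot
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  steps <- bind_rows(tibble(time = 0, surv = 1),
                     object$steps[c("time", "surv")])
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Connectivity summary plot
#'
#' Compounds ranked by summary tau with the reversal threshold marked.
#'
#' @param compound_summary The `$compound` element of
#'   [connectivity_scores()].
#' @param threshold Reversal threshold to draw.
#' @return A ggplot object.
#' @export
plot_connectivity <- function(compound_summary, threshold = -90) {
  df <- arrange(compound_summary, .data$summary_tau) |>
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$summary_tau)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "#c0392b") +
    ggplot2::labs(x = "Compound rank", y = "Summary tau") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
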