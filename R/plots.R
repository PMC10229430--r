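# ggplot2 views of the main result types.

#' Plot a clamp record
#'
#' Faceted traces of glucose, insulin, C-peptide, GIR and enrichment over the
#' clamp, with the phase boundaries marked.
#'
#' @param record A ClampRecord tibble (one or more participant-visits).
#' @return A ggplot.
#' @export
plot_clamp_record <- function(record) {
  long <- record %>%
    tidyr::pivot_longer(c("glucose", "insulin", "cpeptide", "gir",
                          "enrichment"),
                        names_to = "analyte", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = time, y = value,
                                     colour = visit,
                                     group = interaction(participant_id, visit))) +
    ggplot2::geom_vline(xintercept = c(0, 10, 90, 120, 180, 190),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~analyte, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Time (min from start of hyperglycemia)", y = NULL,
                  title = "Hyperglycemic clamp traces") +
    ggplot2::theme_bw()
}

#' Plot a meal-test record
#'
#' @param record An MMTTRecord tibble.
#' @return A ggplot.
#' @export
plot_mmtt_record <- function(record) {
  long <- record %>%
    tidyr::pivot_longer(c("glucose", "insulin", "cpeptide", "glp1_total",
                          "gip_total", "paracetamol"),
                        names_to = "analyte", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = time, y = value, colour = visit,
                                     group = interaction(participant_id, visit))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL,
                  title = "Mixed meal tolerance test") +
    ggplot2::theme_bw()
}

#' @export
autoplot.isr_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = interval_start, xend = interval_end,
                                       y = .data$isr_pmol_kg_min,
                                       yend = .data$isr_pmol_kg_min)) +
    ggplot2::labs(x = "Time (min)", y = "ISR (pmol/kg/min)",
                  title = "Deconvolved insulin secretion rate") +
    ggplot2::theme_bw()
}

#' @export
autoplot.comparison_report <- function(object, ...) {
  df <- as_tibble(object)
  df$pair <- factor(df$pair, levels = rev(df$pair))
  has_pct <- "pct_change" %in% names(df)
  ggplot2::ggplot(df, ggplot2::aes(
    y = pair,
    x = if (has_pct) .data$pct_change else estimate,
    xmin = if (has_pct) .data$pct_low else conf.low,
    xmax = if (has_pct) .data$pct_high else conf.high,
    colour = status
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange() +
    ggplot2::labs(
      x = if (has_pct) "Difference in change (%)" else "Difference in change",
      y = NULL,
      title = "Pairwise comparisons of change",
      subtitle = paste0("Global P = ", signif(attr(object, "global_p"), 3))
    ) +
    ggplot2::theme_bw()
}
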