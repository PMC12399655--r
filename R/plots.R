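#' Heterogeneity quadrant scatter plot
#'
#' Intra- versus inter-tumoral score per gene, colored by quadrant, with
#' the quantile thresholds as dashed lines.
#'
#' @param quadrants Tibble from [classify_quadrants()].
#' @return A ggplot.
#' @export
plot_quadrants <- function(quadrants) {
  thr <- attr(quadrants, "thresholds")
  p <- ggplot2::ggplot(quadrants,
                       ggplot2::aes(x = .data$inter_score,
                                    y = .data$intra_score,
                                    color = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "Inter-tumoral heterogeneity (SD of patient means)",
                  y = "Intra-tumoral heterogeneity (median within-patient SD)",
                  color = "Quadrant") +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p +
      ggplot2::geom_vline(xintercept = thr["inter"], linetype = "dashed") +
      ggplot2::geom_hline(yintercept = thr["intra"], linetype = "dashed")
  }
  p
}

#' Kaplan-Meier step plot
#'
#' @param km Tibble from [km_curve()].
#' @return A ggplot.
#' @export
plot_km <- function(km) {
  start <- dplyr::distinct(km, .data$group)
  start$time <- 0; start$surv <- 1
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$group)) +
    ggplot2::geom_step(data = dplyr::bind_rows(
      start[, c("group", "time", "surv")],
      km[, c("group", "time", "surv")])) +
    ggplot2::geom_point(data = km[km$n_censor > 0, ], shape = 3, size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", color = "Group") +
    ggplot2::theme_minimal()
}

#' Stability-selection frequency plot
#'
#' Selection frequency per candidate gene with the cutoff line.
#'
#' @param freqs Tibble from [stability_select()].
#' @param freq_min Cutoff to draw (defaults to the run's own).
#' @return A ggplot.
#' @export
plot_selection_frequencies <- function(freqs, freq_min = NULL) {
  freq_min <- freq_min %||% attr(freqs, "params")$freq_min %||% 0.85
  df <- dplyr::mutate(freqs,
                      gene = stats::reorder(.data$gene, .data$frequency))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$frequency,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = freq_min, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Selection frequency", fill = "Selected") +
    ggplot2::theme_minimal()
}

#' Calibration plot: observed versus predicted survival
#'
#' @param cal Tibble from [calibration_curve()].
#' @return A ggplot.
#' @export
plot_calibration <- function(cal) {
  ggplot2::ggplot(cal, ggplot2::aes(x = .data$predicted,
                                    y = .data$observed_corrected)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           width = 0.01) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted survival", y = "Observed survival") +
    ggplot2::theme_minimal()
}
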