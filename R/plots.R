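#' Plot a beat's reservoir-excess pressure decomposition
#'
#' Measured aortic pressure with the reservoir and excess components, and
#' the valve-closure landmark.
#'
#' @param decomposition Tibble `time_s`, `p_ao`, `p_res`, `p_ex` (one
#'   element of the `decomposition` list-column from [decompose_beats()]).
#' @param t_d Optional diastole-onset time to mark (s).
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomposition, t_d = NULL) {
  long <- tidyr::pivot_longer(decomposition, c("p_ao", "p_res", "p_ex"),
                              names_to = "component", values_to = "pressure")
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$pressure,
                                           colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(t_d)) {
    gg <- gg + ggplot2::geom_vline(xintercept = t_d, linetype = "dashed")
  }
  gg
}

#' Bland-Altman plot of measured versus estimated stroke volume
#'
#' Difference (measured - estimated) against the pair mean, with the
#' median and 5th/95th percentile lines.
#'
#' @param sv_est,sv_meas Per-beat stroke volumes (ml).
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(sv_est, sv_meas) {
  ok <- is.finite(sv_est) & is.finite(sv_meas)
  df <- tibble::tibble(mean_sv = (sv_est[ok] + sv_meas[ok]) / 2,
                       diff_sv = sv_meas[ok] - sv_est[ok])
  ba <- bland_altman(sv_est, sv_meas)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_sv, .data$diff_sv)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = ba$median_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$p5_diff, ba$p95_diff),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "mean SV (ml)", y = "measured - estimated SV (ml)") +
    ggplot2::theme_minimal()
}

#' Beat-to-beat stroke-volume trend plot
#'
#' Estimated series against the measured (or true) series by beat index.
#'
#' @param per_beat Per-beat tibble with `beat_index`, a measured column and
#'   estimate columns.
#' @param estimators Estimate columns to draw; defaults as in
#'   [evaluate_run()].
#' @param measured Name of the reference column.
#' @return A ggplot object.
#' @export
plot_sv_trend <- function(per_beat,
                          estimators = intersect(
                            c("sv_r_ml", "sv_c_ml", "sv_rprox_ml"),
                            names(per_beat)),
                          measured = "sv_measured_ml") {
  long <- tidyr::pivot_longer(
    per_beat[, c("beat_index", measured, estimators)],
    -"beat_index", names_to = "series", values_to = "sv_ml")
  ggplot2::ggplot(long, ggplot2::aes(.data$beat_index, .data$sv_ml,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "beat", y = "stroke volume (ml)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Objective curves of a fixed-parameter calibration
#'
#' @param object A [calibrate_fixed_params()] result.
#' @param ... Unused.
#' @return A ggplot object marking each parameter's grid optimum.
#' @export
autoplot.pwk_calibration <- function(object, ...) {
  ggplot2::ggplot(object$optima,
                  ggplot2::aes(.data$parameter, .data$value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = NULL, y = "calibrated fixed value (native units)") +
    ggplot2::theme_minimal()
}
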