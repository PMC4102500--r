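#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fixed-parameter calibration
#'
#' @param x A [calibrate_fixed_params()] result.
#' @param ... Unused.
#' @return Tibble with one row per calibrated parameter: `parameter`,
#'   `value`, `objective`, `at_boundary`.
#' @export
tidy.pwk_calibration <- function(x, ...) {
  x$optima
}

#' One-row summary of a fixed-parameter calibration
#'
#' @param x A [calibrate_fixed_params()] result.
#' @param ... Unused.
#' @return One-row tibble: `n_beats`, `step`, `total_objective`.
#' @export
glance.pwk_calibration <- function(x, ...) {
  tibble::tibble(n_beats = x$n_beats, step = x$step,
                 total_objective = sum(x$optima$objective))
}
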