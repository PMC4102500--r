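#' Bland-Altman agreement summary between measured and estimated SV
#'
#' Summarises the paired differences `measured - estimated` (so a positive
#' median means the estimator underestimates) by their median and 5th/95th
#' percentiles, the robust analogue of limits of agreement. Quantiles use
#' linear interpolation between closest order statistics
#' (`stats::quantile` type 7).
#'
#' @param sv_est Estimated per-beat stroke volumes (ml).
#' @param sv_meas Measured per-beat stroke volumes (ml), same length.
#' @param na_rm Drop pairs with a missing value (default `TRUE`).
#' @return One-row tibble: `median_diff`, `p5_diff`, `p95_diff` (ml),
#'   `n_beats`.
#' @export
bland_altman <- function(sv_est, sv_meas, na_rm = TRUE) {
  if (length(sv_est) != length(sv_meas)) {
    stop("sv_est and sv_meas must have equal length", call. = FALSE)
  }
  d <- sv_meas - sv_est
  if (na_rm) d <- d[is.finite(d)]
  if (length(d) < 2) stop("need at least 2 paired beats", call. = FALSE)
  qs <- stats::quantile(d, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  tibble::tibble(median_diff = qs[2], p5_diff = qs[1], p95_diff = qs[3],
                 n_beats = length(d))
}

#' Zero-lag cross-correlation between estimated and measured SV trends
#'
#' Pearson correlation at lag zero of the two beat-indexed series,
#' optionally restricted to a region of induced SV change (e.g. a PEEP
#' recruitment manoeuvre). Invariant to affine rescaling of either series,
#' so it measures trend tracking independently of calibration error.
#'
#' @param sv_est,sv_meas Per-beat series (ml), equal length.
#' @param region Optional `c(start_beat, end_beat)` (1-based, inclusive);
#'   `NULL` uses all beats.
#' @return One-row tibble: `r`, `start_beat`, `end_beat`, `n_beats`.
#' @export
zero_lag_crosscorr <- function(sv_est, sv_meas, region = NULL) {
  if (length(sv_est) != length(sv_meas)) {
    stop("sv_est and sv_meas must have equal length", call. = FALSE)
  }
  n <- length(sv_est)
  region <- region %||% c(1L, n)
  if (region[1] < 1 || region[2] > n || region[1] > region[2]) {
    stop("region outside series", call. = FALSE)
  }
  ix <- seq(region[1], region[2])
  x <- sv_est[ix]
  y <- sv_meas[ix]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 beats in region", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in region", call. = FALSE)
  }
  tibble::tibble(r = stats::cor(x, y), start_beat = region[1],
                 end_beat = region[2], n_beats = length(x))
}

#' Agreement and trend report for a per-beat result table
#'
#' Computes a Bland-Altman summary per estimator over all beats, and a
#' zero-lag trend correlation per estimator per designated region (e.g.
#' recruitment-manoeuvre stretches where SV changes are induced).
#'
#' @param per_beat Per-beat tibble with a measured-SV column and one or
#'   more estimated-SV columns.
#' @param regions Optional data frame `start_beat`, `end_beat` (and
#'   optionally `label`); `NULL` or zero rows yields agreement summaries
#'   only.
#' @param estimators Names of the estimate columns; defaults to whichever
#'   of `sv_r_ml`, `sv_c_ml`, `sv_rprox_ml` are present.
#' @param measured Name of the measured-SV column.
#' @return An object of class `"pwk_evaluation"`: list with `agreement`
#'   (one row per estimator) and `trend` (one row per estimator x region,
#'   or zero rows).
#' @export
evaluate_run <- function(per_beat, regions = NULL,
                         estimators = intersect(
                           c("sv_r_ml", "sv_c_ml", "sv_rprox_ml"),
                           names(per_beat)),
                         measured = "sv_measured_ml") {
  if (!measured %in% names(per_beat)) {
    stop("per-beat table lacks measured SV column '", measured, "'",
         call. = FALSE)
  }
  if (!length(estimators)) {
    stop("per-beat table has no estimated SV columns", call. = FALSE)
  }
  if (!any(vapply(estimators,
                  function(e) any(is.finite(per_beat[[e]])), TRUE))) {
    stop("no converged beats to evaluate", call. = FALSE)
  }
  sv_meas <- per_beat[[measured]]

  agreement <- dplyr::bind_rows(lapply(estimators, function(e) {
    dplyr::mutate(bland_altman(per_beat[[e]], sv_meas), estimator = e,
                  .before = 1)
  }))

  trend <- tibble::tibble(estimator = character(0), label = character(0),
                          r = numeric(0), start_beat = integer(0),
                          end_beat = integer(0), n_beats = integer(0))
  if (!is.null(regions) && nrow(regions) > 0) {
    lab <- regions$label %||% paste0("region_", seq_len(nrow(regions)))
    trend <- dplyr::bind_rows(lapply(estimators, function(e) {
      dplyr::bind_rows(lapply(seq_len(nrow(regions)), function(i) {
        dplyr::mutate(
          zero_lag_crosscorr(per_beat[[e]], sv_meas,
                             c(regions$start_beat[i], regions$end_beat[i])),
          estimator = e, label = lab[i], .before = 1)
      }))
    }))
  }
  structure(list(agreement = agreement, trend = trend),
            class = "pwk_evaluation")
}

#' @export
print.pwk_evaluation <- function(x, ...) {
  cat("Agreement (measured - estimated, ml):\n")
  print(x$agreement)
  if (nrow(x$trend)) {
    cat("\nTrend correlations (zero lag):\n")
    print(x$trend)
  }
  invisible(x)
}
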