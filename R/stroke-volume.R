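#' Three-element Windkessel parameter set
#'
#' Bundles the systemic resistance `R` (mmHg·s/ml), arterial compliance `C`
#' (ml/mmHg), characteristic impedance `R_prox` (mmHg·s/ml) and mean
#' systemic filling pressure `P_msf` (mmHg). Defaults are the optimised
#' values for ~30 kg pigs used throughout the package's examples, with a
#' filling pressure chosen so the simulated mean arterial pressure lands in
#' the porcine range.
#'
#' @param R,C,R_prox,P_msf Parameter values; all must be positive.
#' @return A list of class `"windkessel_params"`.
#' @export
windkessel_params <- function(R = 1.663, C = 0.533, R_prox = 0.088,
                              P_msf = 20) {
  vals <- c(R = R, C = C, R_prox = R_prox, P_msf = P_msf)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all Windkessel parameters must be positive and finite", call. = FALSE)
  }
  structure(list(R = R, C = C, R_prox = R_prox, P_msf = P_msf),
            class = "windkessel_params")
}

#' @export
print.windkessel_params <- function(x, ...) {
  cat(sprintf(
    "Windkessel parameters: R = %.4g mmHg.s/ml, C = %.4g ml/mmHg, R_prox = %.4g mmHg.s/ml, P_msf = %.4g mmHg\n",
    x$R, x$C, x$R_prox, x$P_msf))
  invisible(x)
}

#' Close the one-parameter ambiguity of a decomposed beat
#'
#' Pressure-only identification yields the two time constants `RC` and
#' `R_prox C` (plus `P_msf`); the individual parameters are under-determined
#' by one degree of freedom. Fixing any one of `R`, `C` or `R_prox`
#' determines the other two through the identified products:
#' fixed `R` gives `C = RC/R`, then `R_prox = R_prox C / C`; fixed `C` gives
#' `R = RC/C` and `R_prox = R_prox C / C`; fixed `R_prox` gives
#' `C = R_prox C / R_prox`, then `R = RC/C`.
#'
#' @param rc Identified diastolic time constant (s).
#' @param rproxc Identified proximal time constant (s).
#' @param p_msf Identified mean systemic filling pressure (mmHg).
#' @param fixed Which parameter is fixed: `"R"`, `"C"` or `"R_prox"`.
#' @param value The fixed parameter's value (native units), positive.
#' @return A [windkessel_params()] object with the full closed triple.
#' @export
close_parameters <- function(rc, rproxc, p_msf,
                             fixed = c("R", "C", "R_prox"), value) {
  fixed <- match.arg(fixed)
  if (!is.finite(value) || value <= 0) {
    stop("fixed parameter value must be positive", call. = FALSE)
  }
  if (!is.finite(rc) || !is.finite(rproxc) || rc <= 0 || rproxc <= 0) {
    stop("rc and rproxc must be positive (converged beat required)",
         call. = FALSE)
  }
  switch(fixed,
    R = {
      C <- rc / value
      windkessel_params(R = value, C = C, R_prox = rproxc / C, P_msf = p_msf)
    },
    C = {
      windkessel_params(R = rc / value, C = value, R_prox = rproxc / value,
                        P_msf = p_msf)
    },
    R_prox = {
      C <- rproxc / value
      windkessel_params(R = rc / C, C = C, R_prox = value, P_msf = p_msf)
    }
  )
}

# Trapezoidal integral of excess pressure over each beat (mmHg.s);
# NA for non-converged beats.
excess_pressure_integral <- function(beats) {
  fs_dt <- function(d) d$time_s[2] - d$time_s[1]
  purrr::map_dbl(beats$decomposition, function(d) {
    if (is.null(d)) return(NA_real_)
    trapz(d$p_ex, fs_dt(d))
  })
}

#' Beat-to-beat stroke volume under fixed-parameter closures
#'
#' Stroke volume is the integral of aortic inflow over the beat. Since
#' excess pressure is proportional to inflow (`p_ex = R_prox q_in`),
#' \deqn{SV = \frac{1}{R_{prox}} \int_{beat} p_{ex}\, dt,}
#' with `R_prox` obtained from the chosen closure ([close_parameters()]).
#' The integral runs over the full beat (trapezoidal rule); the diastolic
#' excess pressure is essentially zero so the tail contributes nothing.
#' Supply any subset of the three fixed values to get the corresponding
#' estimate columns. Beats whose excess-pressure integral is negative
#' beyond 5\% of its absolute integral are flagged (`sv_flag`) and get `NA`
#' estimates, as do non-converged beats.
#'
#' @param beats Decomposed beat table from [decompose_beats()].
#' @param r_fixed,c_fixed,rprox_fixed Fixed values of `R` (mmHg·s/ml),
#'   `C` (ml/mmHg) and `R_prox` (mmHg·s/ml); `NULL` skips that closure.
#' @return `beats` with columns `sv_r_ml`, `sv_c_ml`, `sv_rprox_ml` (for
#'   the closures requested) and `sv_flag`.
#' @export
estimate_sv <- function(beats, r_fixed = NULL, c_fixed = NULL,
                        rprox_fixed = NULL) {
  for (v in c(r_fixed, c_fixed, rprox_fixed)) {
    if (!is.finite(v) || v <= 0) {
      stop("fixed parameter values must be positive", call. = FALSE)
    }
  }
  ipe <- excess_pressure_integral(beats)
  aipe <- purrr::map_dbl(beats$decomposition, function(d) {
    if (is.null(d)) return(NA_real_)
    trapz(abs(d$p_ex), d$time_s[2] - d$time_s[1])
  })
  flag <- !beats$converged | (is.finite(ipe) & ipe < -0.05 * aipe)
  ipe[flag] <- NA_real_
  out <- dplyr::mutate(beats, sv_flag = flag)
  if (!is.null(r_fixed)) {
    out$sv_r_ml <- ipe * out$rc_s / (r_fixed * out$rproxc_s)
  }
  if (!is.null(c_fixed)) {
    out$sv_c_ml <- ipe * c_fixed / out$rproxc_s
  }
  if (!is.null(rprox_fixed)) {
    out$sv_rprox_ml <- ipe / rprox_fixed
  }
  out
}

#' Calibrate the fixed Windkessel parameters by grid search
#'
#' Identifies, for each of `R`, `C` and `R_prox` independently, the fixed
#' value minimising the sum over beats of squared differences between
#' estimated and measured stroke volume, by exhaustive search over a
#' physiological range at a fixed resolution (default step 0.001 in each
#' parameter's native units). Ties break toward the smaller value. The
#' per-beat estimates reduce to `k_i f(theta)` with precomputed sufficient
#' statistics (`k_i` from the excess-pressure integral and time constants),
#' so the scan is vectorised and fast.
#'
#' @param beats Decomposed beat table with a `sv_measured_ml` column
#'   ([compute_sv_from_volume()]); at least 10 converged paired beats.
#' @param ranges Named list of length-2 numeric ranges. Defaults:
#'   `R` \[0.5, 4.0\] mmHg·s/ml, `C` \[0.1, 2.0\] ml/mmHg,
#'   `R_prox` \[0.010, 0.300\] mmHg·s/ml.
#' @param step Grid resolution in native units (default 0.001).
#' @return An object of class `"pwk_calibration"`: a list with `optima`
#'   (tibble `parameter`, `value`, `objective`, `at_boundary`), `n_beats`,
#'   `ranges`, `step`. Supports [generics::tidy()] and [generics::glance()].
#' @export
calibrate_fixed_params <- function(beats,
                                   ranges = list(R = c(0.5, 4.0),
                                                 C = c(0.1, 2.0),
                                                 R_prox = c(0.010, 0.300)),
                                   step = 0.001) {
  if (!"sv_measured_ml" %in% names(beats)) {
    stop("beats must carry 'sv_measured_ml' (see compute_sv_from_volume)",
         call. = FALSE)
  }
  ipe <- excess_pressure_integral(beats)
  use <- beats$converged & is.finite(ipe) & is.finite(beats$sv_measured_ml)
  if (sum(use) < 10) {
    stop("need at least 10 converged beats with measured SV (have ",
         sum(use), ")", call. = FALSE)
  }
  m <- beats$sv_measured_ml[use]
  rc <- beats$rc_s[use]
  rpc <- beats$rproxc_s[use]
  a <- ipe[use]

  scan_one <- function(par, k, inverse) {
    grid <- seq(ranges[[par]][1], ranges[[par]][2], by = step)
    f <- if (inverse) 1 / grid else grid
    s_kk <- sum(k^2)
    s_km <- sum(k * m)
    obj <- f^2 * s_kk - 2 * f * s_km + sum(m^2)
    bad <- !is.finite(obj)
    if (any(bad)) {
      warning(sum(bad), " non-finite objective values skipped for ", par)
      obj[bad] <- Inf
    }
    i <- which.min(obj)  # first minimum = smaller value on an ascending grid
    at_edge <- i == 1L || i == length(grid)
    if (at_edge) {
      warning("calibration optimum for ", par,
              " lies on the search-range boundary; consider widening")
    }
    tibble::tibble(parameter = par, value = grid[i], objective = obj[i],
                   at_boundary = at_edge)
  }

  optima <- dplyr::bind_rows(
    scan_one("R", k = a * rc / rpc, inverse = TRUE),
    scan_one("C", k = a / rpc, inverse = FALSE),
    scan_one("R_prox", k = a, inverse = TRUE)
  )
  structure(list(optima = optima, n_beats = sum(use), ranges = ranges,
                 step = step),
            class = "pwk_calibration")
}

#' @export
print.pwk_calibration <- function(x, ...) {
  cat("Fixed-parameter calibration over", x$n_beats, "beats (grid step",
      x$step, ")\n")
  print(x$optima)
  invisible(x)
}
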