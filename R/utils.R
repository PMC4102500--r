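# Internal numerical helpers shared across modules.

# Exact exponential-integrator step for dP/dt = -beta * P + g(t) with g
# piecewise linear between uniform samples. Returns P on the same grid.
# Closed-form per-interval update; no grid-dependent quadrature bias.
expint_lin <- function(g, dt, beta, p0) {
  stopifnot(beta > 0, dt > 0, length(g) >= 2)
  n <- length(g)
  a <- exp(-beta * dt)
  i0 <- (1 - a) / beta
  i1 <- dt * (1 - a) / beta - (1 - a * (1 + beta * dt)) / beta^2
  g0 <- g[-n]
  slope <- (g[-1] - g0) / dt
  x <- g0 * i0 + slope * i1
  p <- stats::filter(x, a, method = "recursive", init = p0)
  c(p0, as.numeric(p))
}

# Trapezoidal integral on a uniform grid.
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - 0.5 * (y[1] + y[n]))
}

# Zero-phase moving-average smoothing (symmetric window, default 5 samples);
# edge samples where the window does not fit are left unsmoothed.
smooth_ma <- function(x, window = 5L) {
  if (length(x) < window) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  s[is.na(s)] <- x[is.na(s)]
  s
}

# Central-difference derivative on a uniform grid, one-sided at the ends.
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

# Validate the uniform-grid waveform contract and return the sampling rate.
# `value_col` names the signal column (pressure_mmhg or volume_ml).
validate_waveform <- function(wave, value_col = "pressure_mmhg",
                              tol_s = 1e-6) {
  if (!is.data.frame(wave)) stop("waveform must be a data frame", call. = FALSE)
  if (!all(c("time_s", value_col) %in% names(wave))) {
    stop("waveform must have columns 'time_s' and '", value_col, "'",
         call. = FALSE)
  }
  t <- wave$time_s
  v <- wave[[value_col]]
  if (length(t) < 2) stop("waveform has no samples (need at least 2)", call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(v))) {
    stop("waveform contains non-finite values", call. = FALSE)
  }
  dts <- diff(t)
  if (any(dts <= 0)) stop("time must be strictly increasing", call. = FALSE)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > tol_s) {
    stop("waveform grid is not uniform (spacing deviates by more than ",
         tol_s, " s)", call. = FALSE)
  }
  1 / dt
}

# Centered rolling median, shrinking the window at the edges; NAs ignored.
rolling_median <- function(x, window = 15L) {
  n <- length(x)
  h <- window %/% 2L
  vapply(seq_len(n), function(i) {
    v <- x[max(1L, i - h):min(n, i + h)]
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  }, numeric(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
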