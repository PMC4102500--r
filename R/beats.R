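#' Split an aortic pressure recording into annotated heartbeats
#'
#' Segments a continuous aortic pressure waveform into individual beats and
#' annotates each with its landmarks. Beat onsets are located at the foot of
#' the systolic upstroke: maxima of the smoothed pressure derivative (with a
#' 0.25 s refractory period) mark upstrokes, and the onset is the local
#' pressure minimum immediately preceding each. Diastole onset `t_d` (aortic
#' valve closure) is the time of minimum rate of change of pressure after the
#' systolic peak. Beats are contiguous and half-open: each beat's end `t_f`
#' is the next beat's onset. Partial beats at the segment edges, and beats
#' failing the landmark-ordering or plausible-duration guards
#' (`t0 < t_peak < t_d < t_f`, duration 0.25--2.5 s), are dropped.
#'
#' @param wave Pressure waveform tibble (`time_s`, `pressure_mmhg`).
#' @param min_upstroke_frac Upstroke candidates must exceed this fraction of
#'   the 98th percentile of positive smoothed slopes. Default 0.4.
#' @param refractory_s Minimum spacing between detected upstrokes (s).
#' @param min_pulse_mmhg Minimum peak-to-foot amplitude for a candidate
#'   beat (mmHg); anything flatter is treated as artifact or noise, not a
#'   heartbeat. Default 10.
#' @return A tibble with one row per beat: `beat_index`, `t0`, `t_peak`,
#'   `t_d`, `t_f` (seconds, absolute recording time) and a list-column
#'   `data` holding each beat's `time_s` / `pressure_mmhg` slice
#'   (samples in `[t0, t_f)`). Zero rows, with a warning, if no beats are
#'   detectable.
#' @export
split_beats <- function(wave, min_upstroke_frac = 0.4, refractory_s = 0.25,
                        min_pulse_mmhg = 10) {
  fs <- validate_waveform(wave, "pressure_mmhg")
  t <- wave$time_s
  p <- wave$pressure_mmhg
  dt <- 1 / fs
  ps <- smooth_ma(p)  # landmarks come off the smoothed trace; data stay raw
  dp <- central_diff(ps, dt)
  # first/last samples sit outside the smoothing support; their raw
  # derivative noise must not seed candidates or inflate the threshold
  edge <- min(3L, length(dp))
  dp[c(seq_len(edge), length(dp) - seq_len(edge) + 1L)] <- 0

  if (max(dp) <= 0) {
    warning("no upstrokes detected; returning zero beats")
    return(empty_beats())
  }
  # threshold on a high quantile of the positive slopes, not the maximum,
  # so one outlying spike cannot mask every genuine upstroke
  thr <- min_upstroke_frac * stats::quantile(dp[dp > 0], 0.98, names = FALSE)
  n <- length(p)
  is_peak <- dp > thr &
    dp >= c(-Inf, dp[-n]) & dp >= c(dp[-1], -Inf)
  cand <- which(is_peak)
  if (length(cand) == 0) {
    warning("no upstrokes detected; returning zero beats")
    return(empty_beats())
  }
  # refractory: greedy by descending derivative magnitude
  cand <- cand[order(dp[cand], decreasing = TRUE)]
  accepted <- integer(0)
  refr <- round(refractory_s * fs)
  for (ix in cand) {
    if (!length(accepted) || min(abs(accepted - ix)) >= refr) {
      accepted <- c(accepted, ix)
    }
  }
  ups <- sort(accepted)

  # onset = pressure minimum (smoothed trace) in the window preceding the
  # upstroke; an argmin over the window, not a walk-back, so measurement
  # noise on the foot cannot stop the search early
  back_limit <- round(0.3 * fs)
  onsets <- vapply(ups, function(ix) {
    lim <- max(1L, as.integer(ix - back_limit))
    lim + which.min(ps[lim:ix]) - 1L
  }, 1L)
  onsets <- unique(onsets)
  if (length(onsets) < 2) {
    warning("fewer than two beat onsets detected; returning zero beats")
    return(empty_beats())
  }

  rows <- list()
  for (k in seq_len(length(onsets) - 1)) {
    i0 <- onsets[k]
    i1 <- onsets[k + 1]
    dur <- t[i1] - t[i0]
    if (dur < 0.25 || dur > 2.5) next
    idx <- i0:(i1 - 1)
    ts <- t[idx]
    praw <- p[idx]
    ipk <- which.max(ps[idx])
    if (ipk <= 1 || ipk >= length(idx)) next
    if (ps[idx[ipk]] - ps[i0] < min_pulse_mmhg) next
    t_d <- tryCatch(detect_diastole_onset(ts, praw, t_peak = ts[ipk]),
                    error = function(e) NA_real_)
    if (!is.finite(t_d)) next
    if (!(t[i0] < ts[ipk] && ts[ipk] < t_d && t_d < t[i1])) next
    # systole occupies a plausible fraction of the cycle; a t_d outside
    # [0.15, 0.6] of the beat is a missed or spurious closure notch
    if ((t_d - t[i0]) < 0.15 * dur || (t_d - t[i0]) > 0.6 * dur) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      t0 = t[i0], t_peak = ts[ipk], t_d = t_d, t_f = t[i1],
      data = list(tibble::tibble(time_s = ts, pressure_mmhg = praw))
    )
  }
  if (!length(rows)) {
    warning("no plausible beats after landmark guards")
    return(empty_beats())
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, beat_index = dplyr::row_number(), .before = 1)
  attr(out, "fs") <- fs
  out
}

empty_beats <- function() {
  tibble::tibble(beat_index = integer(0), t0 = numeric(0), t_peak = numeric(0),
                 t_d = numeric(0), t_f = numeric(0), data = list())
}

#' Locate diastole onset (aortic valve closure) within one beat
#'
#' Diastole onset is defined as the time of the minimum rate of change of
#' aortic pressure after the systolic peak. The derivative is taken by
#' central differences after zero-phase moving-average smoothing over a
#' 5-sample window, to keep the minimum-slope rule robust to measurement
#' noise.
#'
#' @param t Sample times of one beat (s, uniform grid).
#' @param p Aortic pressure samples (mmHg).
#' @param t_peak Time of the systolic pressure maximum; located from `p` if
#'   omitted.
#' @return Diastole-onset time `t_d` (s), strictly after `t_peak`.
#' @export
detect_diastole_onset <- function(t, p, t_peak = NULL) {
  if (length(t) < 5) stop("beat too short to locate diastole", call. = FALSE)
  dt <- t[2] - t[1]
  if (is.null(t_peak)) t_peak <- t[which.max(p)]
  dp <- central_diff(smooth_ma(p), dt)
  # trailing samples are outside the zero-phase smoothing support; their
  # raw-derivative noise would otherwise masquerade as the closure notch
  after <- which(t > t_peak & seq_along(t) <= length(t) - 3L)
  if (!length(after)) stop("no samples after systolic peak", call. = FALSE)
  if (min(dp[after]) >= 0) {
    stop("no diastole: pressure never falls after the peak", call. = FALSE)
  }
  t[after[which.min(dp[after])]]
}

#' Measured stroke volume from a ventricular volume trace
#'
#' For each beat interval `[t0, t_f)` the measured stroke volume is the
#' difference between maximum and minimum left-ventricular volume.
#'
#' @param beats Beat table from [split_beats()].
#' @param volume Volume waveform tibble (`time_s`, `volume_ml`) on the same
#'   time base as the pressure recording.
#' @return `beats` with an added `sv_measured_ml` column.
#' @export
compute_sv_from_volume <- function(beats, volume) {
  validate_waveform(volume, "volume_ml")
  tv <- volume$time_s
  vv <- volume$volume_ml
  sv <- purrr::map2_dbl(beats$t0, beats$t_f, function(a, b) {
    v <- vv[tv >= a & tv < b]
    if (!length(v)) stop("empty volume slice for beat [", a, ", ", b, ")",
                         call. = FALSE)
    max(v) - min(v)
  })
  dplyr::mutate(beats, sv_measured_ml = sv)
}
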