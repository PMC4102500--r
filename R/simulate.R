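#' Parametric aortic inflow profile for one beat
#'
#' Half-sine ejection over the systolic interval, zero flow over diastole.
#' The peak is chosen so the inflow integrates exactly to the prescribed
#' stroke volume: \eqn{Q_{peak} = \pi\, SV / (2\, T_{sys})}.
#'
#' @param sv Stroke volume to eject (ml), non-negative.
#' @param period Beat period (s).
#' @param systolic_fraction Systolic duration as a fraction of the period,
#'   in \[0.2, 0.5\].
#' @return A vectorised function of time-within-beat (s) returning inflow
#'   (ml/s), with the systolic duration attached as attribute `"t_sys"`.
#' @examples
#' q <- inflow_profile(25.3, period = 0.665, systolic_fraction = 0.375)
#' integrate(q, 0, 0.665)$value # 25.3
#' @export
inflow_profile <- function(sv, period, systolic_fraction = 0.375) {
  if (sv < 0 || period <= 0) stop("sv must be >= 0 and period > 0", call. = FALSE)
  if (systolic_fraction < 0.2 || systolic_fraction > 0.5) {
    stop("systolic_fraction must lie in [0.2, 0.5]", call. = FALSE)
  }
  t_sys <- systolic_fraction * period
  q_peak <- pi * sv / (2 * t_sys)
  f <- function(t) {
    ifelse(t >= 0 & t < t_sys, q_peak * sin(pi * t / t_sys), 0)
  }
  attr(f, "t_sys") <- t_sys
  attr(f, "q_peak") <- q_peak
  f
}

#' Piecewise-constant per-beat stroke-volume staircase
#'
#' Builds a per-beat target SV sequence emulating step-wise PEEP
#' recruitment manoeuvres, where each increase in airway pressure lowers
#' venous return and hence stroke volume for a stretch of beats.
#'
#' @param levels Stroke-volume levels (ml), all positive.
#' @param beats_per_level Number of beats held at each level (recycled).
#' @return Numeric vector of per-beat target SV (ml).
#' @examples
#' sv_staircase(c(25, 20, 15, 20, 25), 20) # 100 beats
#' @export
sv_staircase <- function(levels, beats_per_level) {
  if (any(levels <= 0)) stop("all SV levels must be positive", call. = FALSE)
  rep(levels, times = rep_len(beats_per_level, length(levels)))
}

#' Simulate a multi-beat aortic pressure recording (forward Windkessel)
#'
#' Integrates the forward three-element Windkessel
#' \deqn{C\,dP_{res}/dt = Q_{in}(t) - (P_{res} - P_{msf})/R, \qquad
#'   P_{ao} = P_{res} + R_{prox} Q_{in}}
#' driven by a half-sine systolic inflow ([inflow_profile()]) with a
#' prescribed per-beat stroke volume, at a fine internal step (sample
#' interval / `n_substeps`, 0.1 ms at 200 Hz), then samples the aortic
#' pressure at `fs` and optionally adds i.i.d. Gaussian measurement noise.
#' Warm-up beats at the first SV level are simulated and discarded so the
#' emitted recording starts in periodic steady state. A matching synthetic
#' left-ventricular volume trace is emitted whose per-beat max minus min
#' equals the prescribed SV exactly, alongside a ground-truth table.
#'
#' The beat period and systolic duration are quantised to whole output
#' samples so beat onsets and the volume minimum fall on the sampling grid.
#'
#' @param params [windkessel_params()] ground truth.
#' @param heart_rate Heart rate (bpm).
#' @param systolic_fraction Systolic duration / beat period, in \[0.2, 0.5\].
#' @param sv_trend Per-beat target stroke volumes (ml), e.g. from
#'   [sv_staircase()]; its length sets the number of emitted beats.
#' @param fs Output sampling rate (Hz), at least 100.
#' @param noise_sigma Std. dev. of additive Gaussian pressure noise (mmHg).
#' @param seed Integer seed for the noise; `NULL` uses the current RNG
#'   state. The global RNG state is restored on exit.
#' @param warmup_beats Beats simulated then discarded to reach steady state.
#' @param n_substeps Internal integration substeps per output sample.
#' @param v_ed End-diastolic volume of the synthetic LV trace (ml).
#' @return An object of class `"pwk_simulation"`: list with `pressure`
#'   (tibble `time_s`, `pressure_mmhg`), `volume` (tibble `time_s`,
#'   `volume_ml`), `truth` (tibble `beat_index`, `t0_true_s`, `t_d_true_s`,
#'   `tau_true_s`, `sv_true_ml`, `R`, `C`, `R_prox`, `P_msf`) and `config`.
#' @export
simulate_recording <- function(params = windkessel_params(),
                               heart_rate = 90,
                               systolic_fraction = 0.375,
                               sv_trend = rep(25.3, 30),
                               fs = 200,
                               noise_sigma = 0,
                               seed = NULL,
                               warmup_beats = 5,
                               n_substeps = 50,
                               v_ed = 55) {
  stopifnot(inherits(params, "windkessel_params"))
  if (fs < 100) stop("fs must be at least 100 Hz", call. = FALSE)
  if (systolic_fraction < 0.2 || systolic_fraction > 0.5) {
    stop("systolic_fraction must lie in [0.2, 0.5]", call. = FALSE)
  }
  if (any(sv_trend <= 0)) stop("all SV targets must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)

  dt_s <- 1 / fs
  period_n <- round(fs * 60 / heart_rate)       # beat period in samples
  if (period_n < 2) stop("heart_rate too high for fs", call. = FALSE)
  period <- period_n * dt_s
  tsys_n <- round(systolic_fraction * period_n) # systole in samples
  t_sys <- tsys_n * dt_s

  sv_all <- c(rep(sv_trend[1], warmup_beats), sv_trend)
  n_beats_all <- length(sv_all)
  n_out <- length(sv_trend) * period_n
  dt_f <- dt_s / n_substeps
  n_fine <- n_beats_all * period_n * n_substeps + 1L

  # inflow on the fine grid: half-sine per beat, per-beat peak
  tf <- (seq_len(n_fine) - 1L) * dt_f
  beat_of <- pmin(floor(tf / period), n_beats_all - 1L)
  phase <- tf - beat_of * period
  q_peak <- pi * sv_all / (2 * t_sys)
  q <- ifelse(phase < t_sys, q_peak[beat_of + 1L] * sin(pi * phase / t_sys), 0)

  R <- params$R; C <- params$C; R_prox <- params$R_prox; P_msf <- params$P_msf
  beta <- 1 / (R * C)
  g <- q / C + P_msf / (R * C)
  p0 <- P_msf + R * sv_all[1] / period   # rough steady-state mean
  p_res_f <- expint_lin(g, dt_f, beta, p0)
  if (any(!is.finite(p_res_f)) || max(p_res_f) > 1e4) {
    stop("forward simulation blew up: non-physical configuration", call. = FALSE)
  }
  p_ao_f <- p_res_f + R_prox * q

  # sample at fs and discard warm-up
  coarse <- seq(1L, n_fine, by = n_substeps)
  keep <- coarse[(warmup_beats * period_n + 1L):(n_beats_all * period_n)]
  t_out <- (seq_len(n_out) - 1L) * dt_s
  p_out <- p_ao_f[keep]

  if (noise_sigma > 0) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (!is.null(old_seed))
          assign(".Random.seed", old_seed, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    p_out <- p_out + stats::rnorm(n_out, 0, noise_sigma)
  }

  # synthetic LV volume: ejection mirrors the inflow integral, linear refill
  ph_out <- t_out %% period
  b_out <- pmin(floor(t_out / period), length(sv_trend) - 1L)
  sv_out <- sv_trend[b_out + 1L]
  v_out <- ifelse(
    ph_out < t_sys,
    v_ed - sv_out * (1 - cos(pi * ph_out / t_sys)) / 2,
    v_ed - sv_out + sv_out * (ph_out - t_sys) / (period - t_sys)
  )

  # truth: tau = fine-grid argmax of reservoir pressure within each beat
  t0s <- (seq_along(sv_trend) - 1L) * period
  fine_per_beat <- period_n * n_substeps
  tau <- vapply(seq_along(sv_trend), function(k) {
    a <- (warmup_beats + k - 1L) * fine_per_beat + 1L
    i <- which.max(p_res_f[a:(a + fine_per_beat - 1L)])
    (i - 1L) * dt_f
  }, numeric(1))

  truth <- tibble::tibble(
    beat_index = seq_along(sv_trend),
    t0_true_s = t0s,
    t_d_true_s = t0s + t_sys,
    tau_true_s = t0s + tau,
    sv_true_ml = sv_trend,
    R = R, C = C, R_prox = R_prox, P_msf = P_msf
  )

  structure(list(
    pressure = tibble::tibble(time_s = t_out, pressure_mmhg = p_out),
    volume = tibble::tibble(time_s = t_out, volume_ml = v_out),
    truth = truth,
    config = list(params = params, heart_rate = heart_rate,
                  systolic_fraction = systolic_fraction, sv_trend = sv_trend,
                  fs = fs, noise_sigma = noise_sigma, seed = seed,
                  warmup_beats = warmup_beats, n_substeps = n_substeps,
                  v_ed = v_ed, period_s = period, t_sys_s = t_sys)
  ), class = "pwk_simulation")
}

#' @export
print.pwk_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulated Windkessel recording: %d beats at %.1f Hz (period %.4g s, noise sigma %.3g mmHg)\n",
    nrow(x$truth), cfg$fs, cfg$period_s, cfg$noise_sigma))
  invisible(x)
}

#' Attach ground-truth stroke volume to detected beats
#'
#' Matches each detected beat to the simulator truth record whose onset
#' time is nearest (within half a beat period), joining the true SV and
#' parameters; beats without a match (e.g. at segment edges) get `NA`.
#'
#' @param beats Beat table from [split_beats()] run on a simulated pressure
#'   trace.
#' @param truth Truth tibble from [simulate_recording()].
#' @return `beats` with `sv_true_ml` and `t_d_true_s` columns added.
#' @export
match_beats_to_truth <- function(beats, truth) {
  period <- stats::median(diff(truth$t0_true_s))
  idx <- vapply(beats$t0, function(t0) {
    i <- which.min(abs(truth$t0_true_s - t0))
    if (abs(truth$t0_true_s[i] - t0) < period / 2) i else NA_integer_
  }, 1L)
  dplyr::mutate(beats,
                sv_true_ml = truth$sv_true_ml[idx],
                t_d_true_s = truth$t_d_true_s[idx])
}
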