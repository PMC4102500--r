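test_that("identical simulated beats at 90 bpm are segmented with exact tiling", {
  beats <- beats_clean()   # 12 simulated beats, noiseless
  expect_gte(nrow(beats), 10)
  expect_lte(nrow(beats), 12)
  period <- beats$t_f - beats$t0
  # one beat period, within one sample of the simulated cycle length
  # (60/90 s quantised to the 200 Hz grid)
  expect_true(all(abs(period - sim_clean()$config$period_s) <= 0.005 + 1e-9))
  expect_lt(abs(sim_clean()$config$period_s - 60 / 90), 0.005)
  # contiguous tiling: each beat ends where the next starts
  expect_equal(beats$t_f[-nrow(beats)], beats$t0[-1])
  # landmark ordering for every beat
  expect_true(all(beats$t0 < beats$t_peak & beats$t_peak < beats$t_d &
                    beats$t_d < beats$t_f))
  # sample accounting: beat slices hold exactly the samples in [t0, t_f)
  n_in_slices <- sum(vapply(beats$data, nrow, 1L))
  n_expected <- sum(sim_clean()$pressure$time_s >= beats$t0[1] &
                      sim_clean()$pressure$time_s < beats$t_f[nrow(beats)])
  expect_equal(n_in_slices, n_expected)
})

test_that("constant pressure yields no beats, with a warning", {
  w <- tibble::tibble(time_s = seq(0, 5, by = 0.005),
                      pressure_mmhg = rep(80, 1001))
  expect_warning(beats <- split_beats(w), "no upstrokes")
  expect_equal(nrow(beats), 0)
})

test_that("beats never span an excluded gap", {
  pr <- sim_clean()$pressure
  mask <- tibble::tibble(start_s = 3.2, end_s = 4.1)
  beats <- split_beats_masked(pr, mask)
  expect_gt(nrow(beats), 2)
  spans_gap <- beats$t0 < 3.2 & beats$t_f > 4.1
  expect_false(any(spans_gap))
  inside_gap <- beats$t0 >= 3.2 & beats$t0 < 4.1
  expect_false(any(inside_gap))
})

test_that("diastole onset sits at the minimum-slope corner of a rise-decay beat", {
  t <- seq(0, 1, by = 0.005)
  p <- ifelse(t <= 0.3, 80 + 100 * t, 80 + 30 * exp(-(t - 0.3) / 0.5))
  td <- detect_diastole_onset(t, p)
  # the declared 5-sample zero-phase smoothing spreads the corner by up to
  # half a window; the detected onset must stay within 3 samples of it
  expect_gte(td, 0.2999)
  expect_lte(td, 0.3151)
})

test_that("diastole onset matches simulated valve closure within 2 samples", {
  beats <- beats_clean()
  t_sys <- sim_clean()$config$t_sys_s
  err <- beats$t_d - (beats$t0 + t_sys)
  expect_true(all(abs(err) <= 2 * 0.005 + 1e-9))
})

test_that("monotone non-decreasing beats raise a no-diastole error", {
  t <- seq(0, 0.6, by = 0.005)
  expect_error(detect_diastole_onset(t, 80 + 40 * t),
               "no diastole|after systolic peak")
  # non-monotone but never falling after its peak plateau
  p <- c(80 + 40 * t[1:100], rep(120, 21))
  expect_error(detect_diastole_onset(t, p, t_peak = t[100]), "no diastole")
})

test_that("measured stroke volume is max minus min volume over the beat", {
  # constructed volume trace: 60 -> 35 ml
  beats <- beats_clean()[1, ]
  tv <- seq(beats$t0 - 0.1, beats$t_f + 0.1, by = 0.005)
  frac <- (tv - beats$t0) / (beats$t_f - beats$t0 - 0.1)
  vol <- tibble::tibble(time_s = tv,
                        volume_ml = 60 - 25 * pmax(0, pmin(1, frac)))
  got <- compute_sv_from_volume(beats, vol)
  expect_equal(got$sv_measured_ml, 25, tolerance = 1e-9)

  vol$volume_ml <- 50
  expect_equal(compute_sv_from_volume(beats, vol)$sv_measured_ml, 0)

  # simulated LV trace reproduces the prescribed ejection exactly
  all_beats <- compute_sv_from_volume(beats_clean(), sim_clean()$volume)
  expect_equal(all_beats$sv_measured_ml, rep(25.3, nrow(all_beats)),
               tolerance = 1e-9)
})
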