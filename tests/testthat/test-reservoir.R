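test_that("reservoir ODE solution holds its equilibrium fixed point", {
  t <- seq(0, 1, by = 0.005)
  p <- rep(20, length(t))
  pr <- solve_reservoir_pressure(t, p, rc = 0.9, rproxc = 0.05, p_msf = 20)
  expect_equal(pr, p, tolerance = 1e-12)
})

test_that("reservoir solution satisfies the Windkessel ODE pointwise", {
  set.seed(31)
  t <- seq(0, 0.8, by = 0.005)
  for (k in 1:10) {
    p <- 90 + 12 * sin(2 * pi * 1.5 * t + rnorm(1)) +
      2 * sin(2 * pi * 3 * t + rnorm(1))
    rc <- 0.886
    rpc <- 0.0469
    pr <- solve_reservoir_pressure(t, p, rc, rpc, 20)
    beta <- 1 / rpc + 1 / rc
    # centred finite-difference residual of dP_res/dt + beta P_res - g(t);
    # evaluated after the initial-condition transient (time scale 1/beta
    # ~ 45 ms) has relaxed, where the solution is as smooth as the input
    dpr <- (pr[-(1:2)] - pr[1:(length(pr) - 2)]) / (2 * 0.005)
    mid <- 2:(length(pr) - 1)
    resid <- dpr + beta * pr[mid] - p[mid] / rpc - 20 / rc
    expect_lt(max(abs(resid[t[mid] > 0.2])), 0.5)
  }
})

test_that("reservoir solution matches an adaptive reference integrator", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  t <- seq(0, 0.8, by = 0.005)
  for (k in 1:5) {
    p <- 90 + 10 * sin(2 * pi * 1.5 * t + rnorm(1)) +
      3 * cos(2 * pi * 3.7 * t + rnorm(1))
    rc <- runif(1, 0.4, 1.2)
    rpc <- runif(1, 0.02, 0.08)
    mine <- solve_reservoir_pressure(t, p, rc, rpc, 20)
    pf <- stats::approxfun(t, p, rule = 2)
    ref <- deSolve::lsoda(c(P = p[1]), t, function(tt, y, parms) {
      list((pf(tt) - y) / rpc - (y - 20) / rc)
    }, rtol = 1e-10, atol = 1e-10)
    expect_lt(max(abs(mine - ref[, 2])), 0.05)
  }
  expect_error(solve_reservoir_pressure(t, t, -1, 0.05, 20), "positive")
})

test_that("diastolic decay fit recovers Table-scale parameters exactly when noiseless", {
  tw <- seq(0, 0.415, by = 0.005)
  p <- 20 + (99.2 - 20) * exp(-tw / TRUE_RC)
  fit <- fit_diastolic_decay(tw, p, t_d = 0)
  expect_true(fit$ok)
  expect_equal(fit$rc, TRUE_RC, tolerance = 1e-6)
  expect_equal(fit$p_msf, 20, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
})

test_that("degenerate diastolic windows are flagged unusable", {
  tw <- seq(0, 0.4, by = 0.005)
  expect_false(fit_diastolic_decay(tw, rep(20, length(tw)), 0)$ok)
  expect_false(fit_diastolic_decay(tw, 20 + 10 * tw, 0)$ok)   # rising
  expect_false(fit_diastolic_decay(tw[1:8], 30 - tw[1:8], 0)$ok) # too short
})

test_that("decay fit with across-beat filling-pressure pooling recovers RC under noise", {
  set.seed(2)
  tw <- seq(0, 0.415, by = 0.005)
  truth <- 20 + (99.2 - 20) * exp(-tw / TRUE_RC)
  sims <- replicate(200, truth + rnorm(length(tw), 0, 0.5))
  free_pmsf <- apply(sims, 2, function(pw) fit_diastolic_decay(tw, pw, 0)$p_msf)
  pooled <- stats::median(free_pmsf, na.rm = TRUE)
  rcs <- apply(sims, 2, function(pw) {
    fit_diastolic_decay(tw, pw, 0, p_msf_fixed = pooled)$rc
  })
  expect_lt(stats::median(abs(rcs / TRUE_RC - 1), na.rm = TRUE), 0.05)
})

test_that("zero-net-flow identification recovers the proximal time constant", {
  dec <- decomp_clean()
  expect_true(all(dec$converged))
  expect_true(all(abs(dec$rproxc_s / TRUE_RPC - 1) < 0.02))
  # identified invariants: RC > RproxC > 0, beta consistent, tau inside
  # the systolic search window
  expect_true(all(dec$rc_s > dec$rproxc_s & dec$rproxc_s > 0))
  expect_equal(dec$beta_1s, 1 / dec$rproxc_s + 1 / dec$rc_s)
  expect_true(all(dec$tau_s > dec$t_peak & dec$tau_s < dec$t_d))
})

test_that("net flow vanishes at the identified tau (self-consistency)", {
  dec <- decomp_clean()
  b <- dec[3, ]
  d <- b$decomposition[[1]]
  fl <- compute_flows(d, close_parameters(b$rc_s, b$rproxc_s, b$pmsf_mmhg,
                                          "R_prox", 0.088))
  qnet <- stats::approxfun(d$time_s, fl$q_in - fl$q_out)
  expect_lt(abs(qnet(b$tau_s)) / max(fl$q_in), 1e-3)
})

test_that("a monotonically rising systole has no zero-net-flow point", {
  t <- seq(0, 0.6, by = 0.005)
  p <- 80 + 60 * t
  out <- identify_rproxc(t, p, t_peak = 0.2, t_d = 0.45, rc = 0.9, p_msf = 20)
  expect_false(out$converged)
})

test_that("decomposition identity and model-consistency hold on simulated beats", {
  dec <- decomp_clean()
  for (i in seq_len(nrow(dec))) {
    d <- dec$decomposition[[i]]
    expect_lt(max(abs(d$p_res + d$p_ex - d$p_ao)), 1e-12)
    # diastolic excess pressure is negligible for model-consistent beats
    dia <- d$time_s >= dec$t_d[i]
    pulse <- diff(range(d$p_ao))
    expect_lt(mean(abs(d$p_ex[dia])), 0.01 * pulse)
    # reservoir pressure is continuous with the fitted diastolic decay
    i_d <- which.min(abs(d$time_s - dec$t_d[i]))
    f <- fit_diastolic_decay(d$time_s, d$p_ao, dec$t_d[i])
    expect_lt(abs(d$p_res[i_d] - f$p_td_fit), 0.5)
    expect_true(all(d$p_res >= dec$pmsf_mmhg[i] - 1e-6))
  }
})

test_that("noiseless parameter recovery holds across the physiological range", {
  set.seed(42)
  n <- 12
  R <- runif(n, 1, 3)
  C <- runif(n, 0.3, 1.0)
  Rp <- runif(n, 0.03, 0.15)
  ok <- logical(n)
  for (i in seq_len(n)) {
    sim <- simulate_recording(windkessel_params(R[i], C[i], Rp[i], 20),
                              sv_trend = rep(25.3, 4), noise_sigma = 0)
    beats <- split_beats(sim$pressure)
    b <- beats[2, ]
    d <- b$data[[1]]
    f <- fit_diastolic_decay(d$time_s, d$pressure_mmhg, b$t_d)
    idf <- identify_rproxc(d$time_s, d$pressure_mmhg, b$t_peak, b$t_d,
                           f$rc, f$p_msf, f$p_td_fit)
    ok[i] <- f$ok && idf$converged &&
      abs(f$rc / (R[i] * C[i]) - 1) < 0.02 &&
      abs(idf$rproxc / (Rp[i] * C[i]) - 1) < 0.05
  }
  expect_true(all(ok))
})

test_that("flows follow Ohm-law relations and recover the simulated inflow", {
  dec <- decomp_clean()
  b <- dec[3, ]
  d <- b$decomposition[[1]]
  params <- close_parameters(b$rc_s, b$rproxc_s, b$pmsf_mmhg, "R_prox", 0.088)

  z <- compute_flows(tibble::tibble(time_s = d$time_s, p_ao = d$p_ao,
                                    p_res = rep(params$P_msf, nrow(d)),
                                    p_ex = rep(0, nrow(d))), params)
  expect_true(all(z$q_in == 0))
  expect_true(all(abs(z$q_out) < 1e-12))

  fl <- compute_flows(d, params)
  qf <- inflow_profile(25.3, sim_clean()$config$period_s, 0.375)
  t0s <- sim_clean()$truth$t0_true_s
  q_true <- qf(d$time_s - t0s[which.min(abs(t0s - b$t0))])
  expect_lt(max(abs(fl$q_in - q_true)) / max(q_true), 0.03)
  # cyclic mass balance: inflow and outflow volumes agree over the beat
  dt <- d$time_s[2] - d$time_s[1]
  vin <- pulsewk:::trapz(fl$q_in, dt)
  vout <- pulsewk:::trapz(fl$q_out, dt)
  expect_lt(abs(vin - vout) / vin, 0.02)

  expect_error(compute_flows(d, list(R = -1, R_prox = 0.1, P_msf = 20)),
               "positive")
})
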