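test_that("parameter closure reproduces the full triple from either product", {
  p1 <- close_parameters(0.9, 0.05, 20, "R", 1.8)
  expect_equal(p1$C, 0.5)
  expect_equal(p1$R_prox, 0.1)

  p2 <- close_parameters(0.9, 0.05, 20, "C", 0.5)
  expect_equal(p2$R_prox, 0.1)
  expect_equal(p2$R, 1.8)

  # algebraic consistency: every closure at its true value returns the
  # same full triple
  rc <- 1.663 * 0.533
  rpc <- 0.088 * 0.533
  cl <- list(close_parameters(rc, rpc, 20, "R", 1.663),
             close_parameters(rc, rpc, 20, "C", 0.533),
             close_parameters(rc, rpc, 20, "R_prox", 0.088))
  for (x in cl) {
    expect_equal(x$R, 1.663, tolerance = 1e-9)
    expect_equal(x$C, 0.533, tolerance = 1e-9)
    expect_equal(x$R_prox, 0.088, tolerance = 1e-9)
    expect_equal(x$P_msf, 20)
  }
  expect_error(close_parameters(0.9, 0.05, 20, "R", -2), "positive")
  expect_error(close_parameters(NA_real_, 0.05, 20, "R", 2), "converged")
})

test_that("stroke volume scales exactly inversely with the fixed impedance", {
  dec <- decomp_clean()
  a <- estimate_sv(dec, rprox_fixed = 0.088)
  b <- estimate_sv(dec, rprox_fixed = 0.044)
  ok <- a$converged
  expect_true(all(abs(b$sv_rprox_ml[ok] / a$sv_rprox_ml[ok] - 2) < 1e-12))

  # a wrong-by-20% fixed value rescales but preserves the series shape
  c20 <- estimate_sv(dec, rprox_fixed = 0.088 * 1.2)
  expect_equal(stats::cor(a$sv_rprox_ml[ok], c20$sv_rprox_ml[ok]), 1,
               tolerance = 1e-6)
})

test_that("each closure fixed at truth recovers the simulated stroke volume", {
  est <- estimate_sv(decomp_clean(), r_fixed = 1.663, c_fixed = 0.533,
                     rprox_fixed = 0.088)
  for (cn in c("sv_r_ml", "sv_c_ml", "sv_rprox_ml")) {
    v <- est[[cn]][est$converged]
    expect_true(all(abs(v / 25.3 - 1) < 0.05))
  }
})

test_that("median stroke-volume error stays under 10% at 1 mmHg noise", {
  dec <- decomp_noisy()
  est <- estimate_sv(dec, r_fixed = 1.663, c_fixed = 0.533,
                     rprox_fixed = 0.088)
  est <- match_beats_to_truth(est, sim_noisy()$truth)
  for (cn in c("sv_r_ml", "sv_c_ml", "sv_rprox_ml")) {
    err <- abs(est[[cn]] / est$sv_true_ml - 1)
    expect_lt(stats::median(err, na.rm = TRUE), 0.10)
  }
})

test_that("zero excess pressure yields zero stroke volume", {
  dec <- decomp_clean()[1, ]
  dec$decomposition[[1]]$p_ex <- 0
  est <- estimate_sv(dec, rprox_fixed = 0.088)
  expect_equal(est$sv_rprox_ml, 0)
})

test_that("grid-search calibration recovers each fixed parameter", {
  beats <- compute_sv_from_volume(decomp_clean(), sim_clean()$volume)
  cal <- calibrate_fixed_params(beats)
  opt <- tidy(cal)
  expect_equal(opt$value[opt$parameter == "R"], 1.663, tolerance = 0.0011)
  expect_equal(opt$value[opt$parameter == "C"], 0.533, tolerance = 0.0011)
  expect_equal(opt$value[opt$parameter == "R_prox"], 0.088,
               tolerance = 0.0011)
  expect_false(any(opt$at_boundary))
  # near-exact identification makes the optimum objective essentially zero
  expect_lt(max(opt$objective), 0.1)
  g <- glance(cal)
  expect_equal(g$n_beats, sum(beats$converged))

  # the objective is unimodal within +/-20% of the optimum
  ipe <- pulsewk:::excess_pressure_integral(beats)
  use <- beats$converged
  k <- ipe[use]
  m <- beats$sv_measured_ml[use]
  grid <- seq(0.088 * 0.8, 0.088 * 1.2, by = 0.001)
  obj <- vapply(grid, function(th) sum((k / th - m)^2), numeric(1))
  expect_equal(sum(diff(sign(diff(obj))) != 0), 1)
})

test_that("calibration guards its preconditions and search range", {
  beats <- compute_sv_from_volume(decomp_clean(), sim_clean()$volume)
  expect_error(calibrate_fixed_params(decomp_clean()), "sv_measured_ml")
  expect_error(calibrate_fixed_params(beats[1:3, ]), "at least 10")
  # a range excluding the truth ends at the boundary, with a warning
  expect_warning(
    cal <- calibrate_fixed_params(beats,
                                  ranges = list(R = c(2.5, 3.0),
                                                C = c(0.1, 2.0),
                                                R_prox = c(0.010, 0.300))),
    "boundary")
  expect_true(tidy(cal)$at_boundary[tidy(cal)$parameter == "R"])
  expect_equal(tidy(cal)$value[tidy(cal)$parameter == "R"], 2.5)
})
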