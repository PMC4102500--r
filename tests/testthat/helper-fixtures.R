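# Shared fixtures, built in code and memoised for the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Table-2-like ground truth used throughout: R = 1.663 mmHg.s/ml,
# C = 0.533 ml/mmHg, R_prox = 0.088 mmHg.s/ml -> RC = 0.886379 s,
# RproxC = 0.046904 s.
true_params <- function() windkessel_params(1.663, 0.533, 0.088, 20)
TRUE_RC <- 1.663 * 0.533
TRUE_RPC <- 0.088 * 0.533

sim_clean <- function() cached("sim_clean", {
  simulate_recording(true_params(), sv_trend = rep(25.3, 12), noise_sigma = 0)
})

beats_clean <- function() cached("beats_clean", {
  split_beats(sim_clean()$pressure)
})

decomp_clean <- function() cached("decomp_clean", {
  decompose_beats(beats_clean())
})

sim_noisy <- function() cached("sim_noisy", {
  simulate_recording(true_params(), sv_trend = rep(25.3, 40),
                     noise_sigma = 1, seed = 3)
})

decomp_noisy <- function() cached("decomp_noisy", {
  decompose_beats(split_beats(sim_noisy()$pressure))
})

# brute-force type-7 quantile: linear interpolation between closest order
# statistics, written independently of stats::quantile
quantile_oracle <- function(x, prob) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
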