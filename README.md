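# pulsewk

Beat-to-beat left-ventricular stroke volume (SV) from a continuous aortic
pressure waveform alone, by pulse-contour analysis under a three-element
Windkessel model — plus a forward simulator so that every inverse step can
be verified by parameter and SV recovery without animal data.

The package is aimed at researchers in computational physiology and
hemodynamic monitoring who have an invasive aortic pressure signal
(e.g. from large-animal ICU experiments sampled at 200 Hz) and want a
continuous, per-beat SV estimate, calibrated either against a measured
ventricular volume trace or by fixing one Windkessel parameter from prior
knowledge.

## The model

Aortic pressure is decomposed into a **reservoir** component, driven by the
elastic storage and discharge of the arterial walls, and an **excess**
component proportional to aortic inflow:

```
P_ao(t) = P_res(t) + P_ex(t),        P_ex = R_prox * Q_in
C dP_res/dt = Q_in - (P_res - P_msf) / R
```

with systemic resistance `R` (mmHg·s/ml), arterial compliance `C`
(ml/mmHg), characteristic impedance `R_prox` (mmHg·s/ml) and mean systemic
filling pressure `P_msf` (mmHg). The reservoir pressure obeys

```
P_res(t) = e^{-beta t} [ P_res(0) + ∫_0^t (P_ao/(R_prox C) + P_msf/(R C)) e^{beta s} ds ],
beta = 1/(R_prox C) + 1/(R C)
```

so it depends only on the two time constants `R C` and `R_prox C` (plus
`P_msf`). Per beat, the pipeline identifies:

1. **`RC` and `P_msf`** from the exponential diastolic decay after valve
   closure (`t_d` = time of minimum dP_ao/dt), by nonlinear least squares;
2. **`R_prox C`** from the zero-net-flow condition: between the systolic
   peak and `t_d` there is a time `tau` at which inflow equals outflow,
   i.e. the reservoir pressure is stationary, and the reservoir curve must
   join the diastolic decay continuously;
3. **SV** after closing the remaining one-parameter ambiguity by fixing
   `R`, `C` or `R_prox`:  `SV = (1/R_prox) ∫_beat P_ex dt`.

Fixed values are calibrated against measured SV (max − min ventricular
volume per beat) by an exhaustive grid search at 0.001 resolution over
physiological ranges, minimising the summed squared SV error over all
beats. Agreement is reported as median and 5th–95th percentiles of the
paired differences (Bland-Altman), and trend tracking as the zero-lag
cross-correlation over regions of induced SV change (e.g. PEEP
recruitment manoeuvres, which lower venous return and hence SV in steps).

## Worked example

Simulate a noisy PEEP-like SV staircase (25 → 20 → 14 → 20 → 25 ml, 12
beats per level, Gaussian pressure noise of 1 mmHg), then estimate SV from
the pressure trace alone with `R_prox` fixed at its true value:

```r
library(pulsewk)

sim <- simulate_recording(sv_trend = sv_staircase(c(25, 20, 14, 20, 25), 12),
                          noise_sigma = 1, seed = 42)
est <- sim$pressure |>
  split_beats() |>
  decompose_beats() |>
  compute_sv_from_volume(sim$volume) |>
  estimate_sv(rprox_fixed = 0.088)

dplyr::select(est, beat_index, t0, rc_s, rproxc_s, pmsf_mmhg,
              sv_measured_ml, sv_rprox_ml)
#> # A tibble: 54 × 7
#>   beat_index    t0  rc_s rproxc_s pmsf_mmhg sv_measured_ml sv_rprox_ml
#>        <int> <dbl> <dbl>    <dbl>     <dbl>          <dbl>       <dbl>
#> 1          1 0.005 0.846   0.0395      20.9           25.0        21.4
#> 2          2 0.645 0.863   0.0467      21.8           25          24.7
#> 3          3 1.33  0.907   0.0473      19.5           25          24.6
#> 4          4 2.00  0.931   0.0476      17.1           25          24.9
#> 5          5 2.65  0.892   0.0445      19.5           25          24.7
#> # i 49 more rows
```

Per beat this reports the identified diastolic time constant `rc_s`
(truth 0.886 s), proximal time constant `rproxc_s` (truth 0.0469 s),
filling pressure `pmsf_mmhg` (truth 20 mmHg), the measured SV from the
volume trace, and the pressure-only SV estimate.

```r
evaluate_run(est, regions = data.frame(start_beat = 1, end_beat = nrow(est),
                                       label = "staircase"))
#> Agreement (measured - estimated, ml):
#> # A tibble: 1 × 5
#>   estimator   median_diff p5_diff p95_diff n_beats
#>   <chr>             <dbl>   <dbl>    <dbl>   <int>
#> 1 sv_rprox_ml       0.221   -3.06     4.41      54
#>
#> Trend correlations (zero lag):
#> # A tibble: 1 × 6
#>   estimator   label         r start_beat end_beat n_beats
#>   <chr>       <chr>     <dbl>      <dbl>    <dbl>   <int>
#> 1 sv_rprox_ml staircase 0.814          1       54      54
```

The estimator underestimates by a median of 0.2 ml with a 90% range of
−3.1 to +4.4 ml, and tracks the induced SV steps with r = 0.81. With a
measured volume trace the fixed parameters can be calibrated instead of
assumed:

```r
tidy(calibrate_fixed_params(est))
#> # A tibble: 3 × 4
#>   parameter value objective at_boundary
#>   <chr>     <dbl>     <dbl> <lgl>
#> 1 R         1.74      130.  FALSE
#> 2 C         0.53       32.5 FALSE
#> 3 R_prox    0.087     362.  FALSE
```

recovering the generating triple (1.663, 0.533, 0.088) to a few percent
from 54 noisy beats. `plot_decomposition()`, `plot_bland_altman()` and
`plot_sv_trend()` draw the standard figures; `inst/cli/pulsewk` exposes
`simulate`, `estimate`, `calibrate` and `evaluate` subcommands for shell
pipelines.

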