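---
title: "Reservoir-excess pulse contour analysis: model, identification and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reservoir-excess pulse contour analysis: model, identification and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewk)
```

## The model and its assumptions

`pulsewk` estimates left-ventricular stroke volume (SV) beat by beat from
an aortic pressure waveform alone. The arterial system is reduced to a
three-element Windkessel: a characteristic impedance $R_{prox}$ in series
with a parallel pair of systemic resistance $R$ and compliance $C$,
discharging towards the mean systemic filling pressure $P_{msf}$. Measured
aortic pressure splits into a reservoir component $P_{res}$, governed by

$$\frac{dP_{res}}{dt} = \frac{P_{ao} - P_{res}}{R_{prox} C} -
  \frac{P_{res} - P_{msf}}{R C},$$

and an excess component $P_{ex} = P_{ao} - P_{res} = R_{prox} Q_{in}$
proportional to aortic inflow. The working assumptions are:

* parameters are constant within a single heartbeat;
* inflow is zero throughout diastole (competent aortic valve), so the
  diastolic pressure is a mono-exponential relaxation with time constant
  $RC$ towards $P_{msf}$;
* between the systolic pressure peak and valve closure there is a time
  $\tau$ of zero net compartment flow ($Q_{in} = Q_{out}$), where
  $P_{res}$ is stationary;
* the reservoir curve is continuous with the diastolic decay.

Pressure-only identification can only recover the two time constants
$RC$ and $R_{prox}C$ (plus $P_{msf}$); the remaining degree of freedom is
closed by fixing one of $R$, $C$, $R_{prox}$, after which
$SV = R_{prox}^{-1}\int_{beat} P_{ex}\,dt$. Fixing a wrong value rescales
the SV series but cannot change its shape — SV is exactly inversely
proportional to the closed $R_{prox}$ — which is why trend tracking
survives calibration error.

## Parameters that matter

| quantity | units | default | why |
|---|---|---|---|
| `R` | mmHg·s/ml | 1.663 | optimised porcine systemic resistance used as simulator truth |
| `C` | ml/mmHg | 0.533 | optimised porcine compliance |
| `R_prox` | mmHg·s/ml | 0.088 | optimised porcine characteristic impedance |
| `P_msf` | mmHg | 20 | makes simulated MAP land near the porcine median (~84 mmHg) via MAP = P_msf + (R + R_prox)·CO |
| heart rate | bpm | 90 | anesthetized-pig scale |
| systolic fraction | – | 0.375 | 0.25 s systole in a 0.665 s cycle |
| `fs` | Hz | 200 | the sampling rate of the targeted recordings |
| noise sigma | mmHg | 0 (simulator), 1 in the stress tests | catheter-scale measurement noise |
| calibration ranges | native units | R ∈ [0.5, 4], C ∈ [0.1, 2], R_prox ∈ [0.01, 0.3] | wide brackets around the 30-kg-pig optima |
| calibration step | native units | 0.001 | grid resolution of the exhaustive search |

## What the simulator emulates — and what it does not

`simulate_recording()` integrates the forward Windkessel driven by a
half-sine systolic inflow whose peak is chosen so the inflow integrates
exactly to the prescribed per-beat SV; `sv_staircase()` supplies
PEEP-recruitment-like step changes in SV. The emitted volume trace is
constructed so that max − min per beat equals the prescribed SV exactly,
and the truth table records per-beat SV, valve closure and the zero-net-flow
time. Beat period and systolic duration are quantised to whole output
samples so that beat onsets and the volume minimum fall on the sampling
grid; the internal integration step is the sample interval divided by 50
(0.1 ms at 200 Hz), and five warm-up beats are discarded so the emitted
recording starts periodic.

The simulator deliberately omits: a dicrotic notch and reflected waves
(its valve closure is a slope discontinuity, not an incisura), respiratory
intra-beat pressure modulation, beat-to-beat parameter drift, and any
distributed (1-D) arterial effects. Passing the recovery tests therefore
shows that the inverse machinery is correct *under the model's own
assumptions* and robust to additive white measurement noise; it does not
show robustness to wave reflections, notch ringing beyond the simulated
slope break, or model violation in real recordings. The half-sine inflow
shape itself is never seen by the estimator, which only consumes pressure.

## Identification: numerical choices

**Reservoir ODE.** The analytic solution is evaluated with an exact
exponential integrator assuming $P_{ao}$ piecewise linear between samples
(closed-form per-interval update), removing grid-dependent quadrature
bias; the per-beat initial condition is $P_{res}(t_0) = P_{ao}(t_0)$,
consistent with zero inflow at the pulse foot. The tests verify agreement
with an adaptive reference integrator (`deSolve::lsoda` at tolerances
1e-10) to better than 0.05 mmHg.

**Beat segmentation.** Upstrokes are maxima of the smoothed-pressure
derivative (zero-phase 5-sample moving average, central differences)
above 0.4 times the 98th percentile of positive slopes, with a 0.25 s
refractory period. A quantile threshold, rather than the global maximum,
keeps one outlying spike from masking every genuine upstroke. The beat
onset is the minimum of the smoothed pressure in the 0.3 s window before
each upstroke — an argmin, not a walk-back to the nearest local minimum,
because with 1 mmHg noise a walk-back stops at noise dips on the upstroke
flank. Beats are half-open $[t_0, t_f)$ with $t_f$ the next onset; partial
edge beats are discarded, and landmark guards require
$t_0 < t_{peak} < t_d < t_f$, a duration in [0.25, 2.5] s, a systolic
fraction $t_d - t_0$ in [0.15, 0.6] of the cycle, and a pulse amplitude of
at least 10 mmHg (anything flatter is artifact, not a heartbeat).

**Valve closure.** $t_d$ is the minimum rate of change of pressure after
the systolic peak, on the 5-sample zero-phase smoothed trace; samples
whose smoothing window hangs over the beat edge are excluded from the
search, because their raw-derivative noise otherwise masquerades as the
closure notch.

**Diastolic fit.** The decay is fitted by bounded nonlinear least squares
(`minpack.lm::nlsLM`; $RC \in [0.1, 10]$ s, $P_{msf}$ between 0 and the
window minimum) over $[t_d + 20\,\mathrm{ms}, t_f)$ — the first 20 ms are
trimmed as the least trustworthy part of early diastole. The amplitude at
$t_d$ is a *fitted* parameter rather than the raw sample: the
minimum-slope rule fires a sample or two before true closure, where the
measurement still contains excess pressure, and anchoring there biases
both $RC$ and $P_{msf}$ substantially. Start values come from a
log-linear regression of the decay; fits pinned at the $RC$ bounds are
flagged unusable.

**Filling-pressure pooling.** Over a single sub-second diastole $RC$ and
$P_{msf}$ trade off strongly under noise — per-beat scatter in $RC$ of
order 15% at 1 mmHg noise is information-limited, not an optimisation
defect. Since the filling pressure is a slowly varying volume-state
quantity, `decompose_beats()` runs two passes: free per-beat fits, then a
centered rolling median of $P_{msf}$ over 15 beats, then a refit of each
beat's $RC$ with $P_{msf}$ held fixed. On noiseless data the passes
coincide; under noise the refit restores $RC$ precision to a few percent.

**Zero-net-flow identification.** For each candidate $\tau$ on the sample
grid strictly inside $(t_{peak}, t_d)$, a bisection on
$R_{prox}C \in [10^{-3}, 0.9\,RC]$ (located by a 48-point log-spaced scan
for a rising sign change, terminated at relative width $10^{-6}$)
enforces $dP_{res}/dt(\tau) = 0$. Stationarity alone does not pin the
solution — distinct $(\tau, R_{prox}C)$ pairs can each be stationary at
their own in-window maximum — so among self-consistent candidates the one
whose reservoir pressure best matches the fitted decay at the first
trusted diastolic sample ($t_d + 20$ ms) is selected, then polished by a
continuous root-find on that same continuity mismatch. The reported
$\tau$ is the interpolated zero crossing of net inflow. Because the
degenerate small-$R_{prox}C$ branch ($P_{res} \to P_{ao}$) can fool the
single-point continuity criterion on noisy beats, beats whose estimate
falls outside a factor of two of the across-beat rolling median are
re-identified inside a bracket around that median and flagged if no root
lives there.

**Calibration.** The grid objective is the sum of squared SV differences
(the printed source of the procedure does not state the norm; squared
error is smooth and standard), with ties broken toward the smaller
parameter value and each parameter scanned independently at step 0.001 in
its native units. Per-beat sufficient statistics
($\int P_{ex}\,dt$, $RC$, $R_{prox}C$) reduce the scan to a vectorised
closed form, so the few-thousand-point grids evaluate in milliseconds.

**Evaluation.** Bland-Altman differences are measured − estimated (a
positive median means underestimation); quantiles use linear
interpolation between closest order statistics (type 7), the most common
convention, declared here because the choice affects the reported 90%
range. Trend correlations are plain Pearson at zero lag, without
detrending.

## Problem sizes in the tests

The test-bed sizes were chosen so the whole suite exercises every claim at
study scale: a 300-beat staircase (60 beats per level, five levels) for
the end-to-end trend check, 50 parameter draws across
$R \in [1,3]$, $C \in [0.3,1]$, $R_{prox} \in [0.03,0.15]$ for recovery,
100 noiseless beats for calibration, 200 Monte-Carlo decays at 0.5 mmHg
noise for the diastolic fit, and 100 random smooth inputs for the ODE
oracle. The Monte-Carlo decay test uses the package's pooled-$P_{msf}$
procedure, since that is how a recording is actually fitted; with
$P_{msf}$ free per beat no estimator can reach the same precision over a
0.4 s window (the likelihood surface is simply too flat).

## Known limitations

* The method inherits the Windkessel's lumped view: wave reflections and
  spatial effects are folded into the reservoir/excess split rather than
  modelled.
* Identification quality depends on a clean diastolic decay; short
  diastoles (high heart rates) and heavy early-diastolic ringing shrink
  the usable window.
* The filling-pressure pooling assumes $P_{msf}$ drifts slowly relative
  to a ~15-beat window; abrupt volume-state interventions inside such a
  window will be smoothed over.
* Absolute SV accuracy is only as good as the fixed-parameter closure;
  without calibration against a measured SV, estimates are accurate in
  trend but scaled by the error in the assumed parameter.
* The exclusion mask is user-supplied; no automatic artifact detection is
  attempted.
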