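---
title: "Quantifying contact skin-temperature sensor error on a benchtop skin model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contact skin-temperature sensor error on a benchtop skin model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoskin)
library(dplyr)
```

## The measurement problem

A contact skin-temperature sensor does not read the temperature the skin
would have had without it. The sensor and its attachment tape change the
local heat balance: an insulating patch traps heat and warms the surface
underneath, while a thermally conductive sensor body sheds heat to the air
like a fin and cools it. On top of that local *disturbance*, the sensing
element itself sits part-way up a temperature gradient between the surface
and the cooler environment, so its reading is biased low whenever the
surface is warmer than the air. This package separates and quantifies these
effects for a benchtop skin simulant — a silicone slab with skin-like
thermal properties, heated from below by a temperature-controlled plate —
and implements the comparison machinery needed to relate different sensor
types to each other at common reference temperatures, both on the simulant
and in a human exercise trial.

Three reference quantities organise everything. For a surface location
under a sensor/attachment, `T_d` is the *disturbed* surface temperature
directly beneath it; `T_u` is the temperature of the same location in its
bare, unmeasured state under otherwise equal conditions; and `T_sen` is the
sensor reading. From these:

* disturbance `= T_d − T_u` (positive when the coverage warms the surface),
* bias from `T_d` `= T_sen − T_d` (error against the surface as disturbed),
* bias from `T_u` `= T_sen − T_u` (systematic error against the unmeasured
  surface).

The third is the sum of the first two, an identity the package enforces
exactly.

## The thermal network model

The simulator represents the rig as two independent one-dimensional columns
per unit area (`solve_thermal_network()`):

* **undisturbed**: plate → slab conduction (`R = L/k`, with `L` = 10 mm,
  `k` = 0.23 W m⁻¹ K⁻¹) → surface → combined convective/radiative boundary
  (`h = h_c + h_r`) → environment;
* **disturbed**: plate → slab → surface → contact resistance `R_c` →
  sensor node → top resistance `R_t` → boundary with conductance scaled by
  an *area factor* `a ≥ 1` → environment.

Convection follows a flat-plate-style correlation `h_c = 15.65 √v`
(≈ 7 W m⁻² K⁻¹ at 0.2 m s⁻¹ and ≈ 11 at 0.5 m s⁻¹); radiation is linearised
at the ambient temperature, `h_r = 4 ε σ T_amb³ ≈ 5.3 W m⁻² K⁻¹`. These
choices reproduce the intended surface-to-environment gradient ranges
(about 0–16 °C at 0.5 m s⁻¹ and 0–18 °C at 0.2 m s⁻¹) with a *single* set
of plate setpoints — the range difference between velocity conditions comes
entirely from the different heat flux, which is how the physical rig
behaved. Because every element is a constant conductance, the whole network
is linear in temperature differences: disturbance and bias grow exactly
linearly with the gradient, which is the behaviour observed on the rig and
the basis for the package's linear summaries.

The sign phenomenology falls out of the resistances. With `a = 1`, any
added `R_c + R_t` raises the total above-surface resistance, the disturbed
column carries less flux, and the surface under the coverage runs *warmer*
(tape-only, custom thermistor + tape). A strongly fin-like metallic body
(`a ≫ 1`) lowers the above-surface resistance instead and *cools* the
surface (iButton without tape, Grant thermistor). The iButton-plus-tape
condition sits between the two regimes and flips sign with air velocity:
its default parameters give warming at 0.5 m s⁻¹ and cooling at
0.2 m s⁻¹. The default coverage parameters in `default_coverages()` were
chosen once to reproduce this sign pattern together with bias magnitudes of
the observed order (≈ −0.4 to −3 °C at a 31 °C sensor reading, depending on
condition).

**Known fidelity limit.** With a velocity-independent area factor, the
cooling produced by fin-like coverages at a *fixed* surface-to-air gradient
is stronger at the lower air velocity (the relative enhancement `(1−1/a)/h`
shrinks as `h` grows). The physical rig showed the opposite ranking for the
un-taped iButton, whose fin effect strengthened with air flow. The
simulator reproduces every sign, the linearity, and the monotonic growth of
errors with the gradient, but not the velocity ordering of fin-cooling
magnitudes; a velocity-dependent area factor would fix this at the cost of
an extra unconstrained parameter, and was deliberately not introduced.
Lateral conduction between the disturbed and undisturbed columns is also
neglected (they are solved independently), and nothing evaporates: the rig
model is dry by construction.

## Simulated data generation

`simulate_rig_run()` drives five 30-min plate steps sampled every 10 s.
Node temperatures relax first-order toward each step's steady state with a
time constant `τ = L²/(π² α) ≈ 79 s` derived from the slab diffusivity
(plus the individual sensor's response time); only steady states are
analysed, so the transient needs to be plausible, not exact. Observations
are `truth × gain + offset + N(0, σ)` then quantized to the logger
resolution — 0.01 °C for logger channels, 0.0625 °C for self-logging
iButtons (applied after noise, modelling the ADC). Defaults (embedded
reference noise 0.005 °C, surface sensors 0.01–0.02 °C) keep within-window
SDs comfortably below the 0.05 °C steady-state gate. The subsurface
reference sensors sit at `z1 = 0.25` mm and `z2 = 5` mm; neither depth is
an observable of the physical rig (only "directly subsurface, within 1 mm"
and "a second depth" are), so both are explicit simulator parameters,
chosen once so that Fourier-law location corrections across the default
design span 0.00–0.39 °C, the range the analysis is designed around. All
randomness flows from explicit seeds; a design's per-run seeds derive
deterministically from one master seed.

`simulate_human_trial()` emulates the in-vivo comparison: 14 participants,
four sites (chest, arm, thigh, leg), three sensor types sharing one smooth
site-level temperature trajectory (rest → slight drop at exercise onset →
rise through two moderate fixed loads → decline through warm-down and
recovery), plus participant/site offsets, sensor-type offsets, noise and
quantization. Skin humidity channels carry an absolute vapor pressure that
*steps* up by 0.8 kPa at the participant's sweat onset (drawn from
N(7.4, 1.6²) min after exercise start, or injected); the step is
instantaneous, an idealisation that makes the generator/detector round trip
exact to one sample. What passing these tests shows is that the analysis
chain is correct on data with this structure; real skin adds site
heterogeneity, movement artefacts, sensor detachment and gradual sweat
onsets that the generator does not attempt.

## The analysis chain

1. **Calibration** (`find_steady_windows()`, `fit_calibration()`,
   `apply_calibration()`): 8-min steady windows are found greedily,
   earliest-first, wherever the precision reference SD is below 0.007 °C,
   at most one window per plateau (plateaus separated by > 0.5 °C).
   Greedy-earliest is a tie-break the procedure itself does not dictate;
   any window inside a plateau gives the same means to within the gate.
   The reference is regressed on the raw sensor means and the line inverted
   so `corrected = (raw − offset)/gain`; the SD criterion gates the
   reference only, with sensor-channel stability recorded but not gated.
2. **Steady states** (`extract_step_means()`): means over minutes 21–29 of
   each step, taken as the half-open window `[21, 29)` (the boundary
   convention is ours), gated at 0.05 °C per channel — applied to *every*
   analysed channel, reading "within-sensor SD" as per-channel.
3. **Surface correction** (`correct_to_surface()`): the two-depth linear
   extrapolation `T(0) = T_z1 + (T_z1 − T_z2) · z1/(z2 − z1)`, applied
   per steady state per run to reference channels only — never to `T_sen`,
   whose uncorrected reading is precisely what is being characterised. In
   the simulator the in-slab profile is exactly linear, so the correction
   is exact; on a real slab curvature from lateral losses would enter.
4. **Pairing and errors** (`match_undisturbed()`): disturbed states pair
   with bare-surface states by (velocity, replicate, step); if a replicate
   has no bare run, `T_u` is interpolated linearly against the plate
   setpoint within that velocity. The gradient is defined as
   `T_u − ambient`, i.e. against the *undisturbed* surface-to-air
   difference.
5. **Fixed-temperature summaries** (`evaluate_at_fixed_sensor_temp()`):
   bias at a realistic 31 °C sensor reading is obtained per replicate by
   OLS of bias against `T_sen` across the five steps, evaluated at 31 °C,
   then summarised over the n = 5 replicates as mean ± t₀.₉₇₅,df=4·SE.
   Regression-then-evaluate was chosen over interpolating between adjacent
   steady states because the errors are demonstrably linear in `T_sen` and
   it uses all five states; the choice is recorded in the output metadata.
   Intervals are unadjusted throughout — no multiplicity correction — and
   a single replicate yields a flagged point estimate with undefined CI.
6. **Inter-sensor comparison** (`sensor_reference_fits()`,
   `compute_anchors()`, `inverse_predict()`,
   `intersensor_differences()`): each individual sensor (one per
   replicate) is fitted as `Y′ = b0 + b1·X` against its matched `T_u`;
   fits with R² ≤ 0.99 are flagged. The custom-thermistor fits convert the
   seven human-trial period means into reference anchors `Y′₁–₇` — when
   several custom sensors exist, the anchor is the mean of their per-sensor
   predictions (the aggregation is not dictated by the procedure; the
   choice is recorded) — and every sensor's temperature at each anchor
   follows by the exact inversion `X′ = (Y′ − b0)/b1`. Differences
   (Grant−custom, iButton−custom, iButton−Grant) are summarised per period
   with unadjusted t-intervals; note the deliberate asymmetry that human
   anchors come from four-site weighted means while model comparisons use
   single sensors.
7. **Human trial** (`weighted_mean_tsk()`, `vapor_pressure()`,
   `detect_sweat_onset()`): weighted-mean skin temperature uses weights
   0.3/0.3/0.2/0.2 (chest/arm/thigh/leg) with no reweighting fallback for
   missing sites. Vapor pressure uses the Magnus form
   `e = (rh/100) · 0.61094 · exp(17.625 T/(T + 243.04))` kPa; the constants
   are configurable in the sense that any alternative saturation formula
   can be applied upstream, and with these constants saturation at 20 °C
   evaluates to 2.3336 kPa. Sweat onset is the first sample after exercise
   start where vapor pressure exceeds the final-3-min pre-exercise baseline
   by more than 0.5 kPa, *sustained for at least 60 s* (the sustain window
   operationalises "distinct increase"; only the 0.5 kPa magnitude is
   given by the procedure), taking the earliest of the four sites. The
   pre-sweating summary period FL1-PS is the 3 min immediately preceding
   the detected onset.

## Numerical choices and degenerate inputs

Rolling window SDs use centered cumulative sums (stable for long series of
near-equal values). Quantization is symmetric rounding to the logger step.
Zero-variance sensor channels, fewer than two calibration windows, fewer
than three regression points, non-invertible (zero-slope) fits, unordered
periods, humidity outside [0, 100] %, and geometry with `z2 ≤ z1` all raise
classed errors rather than propagating NaN. Stored CSVs keep 4 decimal
places (1 × 10⁻⁴ °C), an order of magnitude finer than any logger
resolution, so storage adds no quantization of its own.

## Problem sizes used in the checks

The package's test suite exercises the full default design — 6 coverages ×
5 replicates × 2 velocities = 60 runs of 900 samples × 6 channels — once,
and verifies on it: every sensor-to-reference fit with R² > 0.99, all
location corrections within 0.00–0.39 °C, the additivity identity to
10⁻⁹ °C, the disturbance sign pattern, and zero-gradient nulls within
three propagated noise SDs (the tolerance includes the worst-case mean
offset of a quantized channel, `q/π · exp(−2π²σ²/q²)`, which does not
shrink with averaging). Monte-Carlo checks (calibration gain/offset
recovery; 95 % t-interval coverage under a null) run 1000 repetitions on
directly simulated window means and replicate differences — the
statistically relevant quantities — rather than full logger traces.
Human-trial round trips use 3–4 participants, which is enough to exercise
every code path of the per-participant analysis.

## Worked example

```{r example, eval = FALSE}
suite <- run_rig_suite(replicates = 5, master_seed = 1)
suite$table1 |>
  filter(coverage == "ibutton_only", velocity == 0.5)
#> bias_from_td -2.30 (t-CI ±0.02), bias_from_tu -3.21: an un-taped iButton
#> reading 31 degC sits over a disturbed surface near 33.3 degC whose
#> undisturbed temperature is near 34.2 degC.

trial <- simulate_human_trial(seed = 1)
comparison <- compare_with_trial(suite, analyze_human_trial(trial))
plot_intersensor_comparison(comparison)
```

## Limitations

Beyond the fin-effect velocity ranking discussed above: the two-column
model cannot represent lateral spreading under a coverage edge, so
disturbances are slightly overestimated for small footprints; the human
trial generator's inter-sensor differences are constant offsets, whereas in
vivo the differences varied with thermal state (largest during exercise);
and no attempt is made to model evaporation, sensor depression into the
skin, or moisture at the sensor-surface interface — all mechanisms the
benchtop approach itself deliberately excludes.
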