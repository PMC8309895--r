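# thermoskin

Quantifying measurement error of contact skin-temperature (T_sk) sensors on
a benchtop thermal skin model, for sensor developers and thermal
physiologists who need to know how much a taped-on sensor perturbs — and
misreads — the surface it measures.

A contact sensor changes the local heat balance of the skin it sits on and
reads a point part-way up the surface-to-air temperature gradient. With a
silicone skin simulant heated from below, and a subsurface reference
thermistor that can be read both under a coverage (disturbed reference,
`T_d`) and bare (undisturbed reference, `T_u`), three error quantities
separate cleanly for a sensor reading `T_sen`:

```
disturbance  = T_d  − T_u          (local effect of the sensor/attachment)
bias from T_d = T_sen − T_d        (error vs the surface as disturbed)
bias from T_u = T_sen − T_u        (systematic error vs the unmeasured surface)
```

with `bias from T_u = bias from T_d + disturbance` exactly. All three grow
linearly with the surface-to-environment gradient. To compare sensor types
at common surface temperatures, each individual sensor is fitted against
its matched undisturbed reference, `Y′ = b0 + b1·X` (OLS), reference
anchors are set from custom-thermistor group means, and each sensor's
temperature at an anchor follows by inverse prediction,
`X′ = (Y′ − b0)/b1`; paired differences get unadjusted 95% t-intervals.
Human-trial calculations (four-site weighted-mean T_sk with weights
0.3/0.3/0.2/0.2, 3-min period means, Magnus vapor pressure, sweat-onset
detection from a sustained > 0.5 kPa rise) are included, as is a
physics-based simulator — two one-dimensional thermal resistance columns
with sensor noise and quantization — that generates rig and trial datasets
with the structure the analysis assumes.

## Worked example

Simulate the full design (6 surface coverages × 5 replicates × 2 air
velocities = 60 runs), extract minute-21–29 steady states, correct the
subsurface references to the surface via Fourier's law, and summarize bias
at a fixed 31 °C sensor reading:

```r
library(thermoskin)
library(dplyr)

suite <- run_rig_suite(replicates = 5, master_seed = 1)
filter(suite$table1, velocity == 0.5)
#> # A tibble: 8 × 8
#>   coverage     velocity form         evaluated_at  mean ci_low ci_high     n
#> 1 custom_tape       0.5 bias_from_td           31 -0.51  -0.51   -0.51     5
#> 2 grant_tape        0.5 bias_from_td           31 -1.19  -1.19   -1.19     5
#> 3 ibutton_only      0.5 bias_from_td           31 -2.3   -2.3    -2.3      5
#> 4 ibutton_tape      0.5 bias_from_td           31 -1.31  -1.31   -1.3      5
#> 5 custom_tape       0.5 bias_from_tu           31 -0.18  -0.18   -0.18     5
#> 6 grant_tape        0.5 bias_from_tu           31 -2     -2      -1.99     5
#> 7 ibutton_only      0.5 bias_from_tu           31 -3.21  -3.21   -3.21     5
#> 8 ibutton_tape      0.5 bias_from_tu           31 -1.08  -1.08   -1.08     5
```

Read: at 0.5 m/s, an un-taped iButton reading 31 °C sits on a surface it
has already cooled; it reads 2.3 °C below that disturbed surface and
3.2 °C below what the surface would have been unmeasured. The custom
thermistor (silicone-matched, taped) errs least. Comparing sensor types at
human-trial surface temperatures via inverse prediction:

```r
trial <- simulate_human_trial(seed = 1)
cmp <- compare_with_trial(suite, analyze_human_trial(trial))
filter(cmp, pair == "ibutton-grant", period == "FL3")
#> # A tibble: 3 × 7
#>   pair          period source     mean ci_low ci_high     n
#> 1 ibutton-grant FL3    model-0.2  0.69   0.69    0.7      5
#> 2 ibutton-grant FL3    model-0.5  0.8    0.8     0.8      5
#> 3 ibutton-grant FL3    human      0.15   0.15    0.15    14
```

Each row is a mean inter-sensor difference (°C) with its 95% CI, from the
model at each air velocity and from the simulated human trial.
`plot_disturbance_bias(suite$paired)` and
`plot_intersensor_comparison(cmp)` draw the standard figures.

## Methods

See the methods vignette (`vignettes/thermoskin-methods.Rmd`) for the
thermal network model and its assumptions, the simulator's default
parameters and what they emulate, the analysis decisions (window
conventions, pairing and anchor aggregation rules, CI conventions), and
known limitations.
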