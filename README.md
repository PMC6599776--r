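# piledose

Dose-response and displacement analysis for harbour porpoise responses to
offshore pile-driving noise, from passive acoustic monitoring data.

Wind-farm foundations are installed by impact pile driving, and harbour
porpoises (*Phocoena phocoena*) are temporarily displaced from the area
around active piling. Regulators currently bridge the evidence gap with
radius-based guidance — assume complete displacement of everyone within
26 km — while the observational evidence supports a graded dose-response:
a probability of response that declines with distance (or received level)
and attenuates over a months-long construction campaign. `piledose` is
for ecologists and environmental assessors who need to estimate that
curve from echolocation-detector (CPOD) arrays and turn it into numbers
of displaced individuals that population-consequence frameworks (e.g.
iPCoD) can consume.

## What it does

The package implements the full inference chain as composable, tested
stages:

* **`compute_dph()`** — classified click-train records to hourly
  detection-positive series (high/moderate-quality trains only).
* **`eligible_events()`, `build_windows()`** — selects piling events
  preceded by a >96-h quiet gap and builds diel-matched baseline and
  response windows (baseline 48 h before the start of piling for 24-h
  windows, 48 h before the end for 12-h windows).
* **`build_null_distribution()`** — resampled null distribution of
  proportional change in occurrence at reference sites, whose 1% quantile
  anchors the response threshold (default 0.5, strict).
* **`fit_probit_glmm()`** — binomial probit GLMM with a site x device
  random intercept, fitted by a hand-rolled Laplace approximation
  (inner Newton conditional modes, outer `nlminb`), with AIC ranking
  (`model_table()`) and likelihood-ratio tests (`lrt()`).
* **`threshold_50()`, `predict_curve()`, `add_contrast()`** — closed-form
  ED50s in distance or weighted SEL with fixed-effects-only confidence
  intervals from multivariate-normal coefficient draws.
* **`displaced_individuals()`, `guidance_total()`** — integrates the
  curve over a uniform-density disc, `n = D * integral p(x) 2 pi x dx`,
  and expresses it as a percentage of the radius-based guidance total.
* **`weighting_function()`, `weighted_sel()`** — M-weighting, the NOAA
  high-frequency cetacean function and inverted-audiogram weighting for
  single-pulse sound exposure levels.
* **`truth_config()`, `simulate_study()`** — a synthetic-data generator
  with a known probit ground truth (ED50 declining 7.4 to 1.3 km with
  piling order, ADD and vessel effects, diel/seasonal detection
  structure), used to validate every stage end to end.
* **`run_pipeline()`** — one-call orchestration with seeded determinism
  and a fully serialized result bundle; a thin CLI wrapper lives at
  `inst/scripts/piledose.R`.

The model at the core, for device group *g*:

    Pr(response_i = 1 | u_g) = Phi(x_i' beta + u_g),   u_g ~ N(0, sigma_u^2)

with `x` holding log-distance from piling (or a weighted SEL), the
cumulative number of locations piled, their interaction, ADD use and an
AIS vessel-proximity count; a response is a proportional decrease in
detection-positive hours greater than 0.5 in the 12 or 24 h after piling
ends.

## A worked example

Simulate a default study (60 sites, 17 piling events), classify
responses, fit the distance model and invert it:

```r
library(piledose)

cfg <- truth_config(seed = 42)
sim <- simulate_study(cfg)
dph <- compute_dph(sim$records, sim$t_start, sim$t_end)
rec <- assemble_records(dph, sim$events, sim$sels, sites = sim$sites,
                        ais = sim$ais, duration_h = 24,
                        coverage_start = sim$t_start)
m <- fit_probit_glmm(rec, model_spec("log_distance"))
print(m)
#> Probit mixed model (Laplace), 1020 obs, 60 site:device groups
#>   exposure: log_distance (x order interaction)
#>                    estimate     se       z
#> (Intercept)         -0.1251 0.0418  -2.995
#> log_distance        -0.5427 0.0490 -11.072
#> order               -0.2151 0.0424  -5.077
#> log_distance:order   0.1025 0.0457   2.244
#> vessels_1km         -0.0824 0.0486  -1.697
#>   random intercept: variance = 0.000, s.d. = 0.000
#>   logLik = -612.851, AIC = 1237.7

threshold_50(m, scenario(order = 1), draws = 2000, seed = 1)
#> 50%-response threshold: 7.79 km (95% CI 6.23-10.11)
threshold_50(m, scenario(order = 86), draws = 2000, seed = 2)
#> 50%-response threshold: 1.58 km (95% CI 0.45-2.61)

displaced_individuals(m, scenario(order = 1), draws = 1000, seed = 3)
#> Displaced individuals within 26 km at density 0.274 km^-2:
#>   185 (95% CI 142-231), 32% of the guidance total 582
```

The simulation's ground truth put the first-event ED50 at 7.4 km and the
last-event ED50 at 1.3 km: the fitted thresholds (7.79 and 1.58 km here)
recover them within sampling error, the negative log-distance slope is
strongly supported, and the interaction term captures the attenuation of
the response over the construction sequence. The displacement line reads:
at a density of 0.274 porpoises per km², the fitted first-event curve
predicts 185 displaced individuals, about a third of the 582 that the
26-km complete-displacement guidance would assume.

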