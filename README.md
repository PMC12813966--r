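# flowssm

State-space and dynamic linear models for flow–ecology time series from
long-term fish monitoring surveys.

Estuarine forage fish such as longfin smelt depend on seasonal freshwater
outflow, but four decades of monitoring raise two questions a single
regression cannot answer: at what spatial resolution does the population
actually fluctuate, and is the flow–abundance relationship stationary or
drifting? `flowssm` implements the full analysis chain for multi-station,
two-gear trawl surveys:

* **Preprocessing** — CPUE (count per m³ or m² of effort), a ≥50%
  completeness filter, natural-log transform with per-series zero offset,
  2-SD outlier interpolation, and seasonal-window annual aggregation
  (May–Oct for age-0, Feb–May for age-1+, Jan–Jun for flow).
* **A missing-data Gaussian state-space engine** (RcppArmadillo Kalman
  filter/smoother; EM with monotone likelihood and BFGS estimation;
  AICc; Wald intervals) for the shared model

  $$x_t = x_{t-1} + C c_t + w_t,\; w_t \sim \mathrm{MVN}(0, Q)
  \qquad y_t = Z_t x_t + v_t,\; v_t \sim \mathrm{MVN}(0, R)$$

  with $Q$ diagonal-unequal, $R$ diagonal with sharing groups, and
  $u = a = 0$.
* **MARSS spatial-structure selection** — six hypotheses (estuary-wide,
  gear, region, region×gear, channel/shoal, lateral×vertical habitat)
  encoded as one-hot $Z$ matrices and ranked by AICc, then time-averaged
  flow effects $C$ (per SD of log flow) with 95% CIs on the winning
  structure.
* **DLMs with time-varying coefficients** — random-walk intercept and
  slope per habitat group via a time-varying $Z_t$ array (4 × 8 × 41 for
  the four-group, 41-year design), contemporary and 1-year-lagged flow,
  with a reproducible static/time-varying classification rule.
* **Trend descriptives** — Theil–Sen slopes with Mann–Kendall tests, CVs,
  trend-vs-CV regressions, a fall-survey-style weighted index and
  period-wise flow regressions.
* **Method comparison** — time-averaged effect vs. DLM mean/max/min
  slopes, CI-overlap flags, and the sign-agreement fraction.
* **A seed-deterministic synthetic survey generator** so every step is
  validated by simulation against known truth.

## Worked example

The bundled scenario emulates the survey design: 35 candidate stations
(10 below the completeness cutoff), two gears, 1980–2020, a four-state
lateral×vertical habitat truth with flow effects (0.5, 0, 0.25, 0).

```r
library(flowssm)

sc   <- survey_scenario(seed = 1)
sim  <- simulate_monthly_catch(sc)
cov  <- standardize_flow(annual_flow(sim$flow, months = 1:6,
                                     years = sc$years))

prep <- lapply(c(midwater = "midwater", otter = "otter"), function(g)
  prepare_annual_cpue(sim$catch, sim$stations, g, "age0"))
y      <- rbind(prep$midwater$annual, prep$otter$annual)
labels <- rbind(prep$midwater$labels, prep$otter$labels)

compare_hypotheses(y, labels)[, c("hypothesis", "n_states", "AICc", "dAICc")]
#>   hypothesis n_states     AICc    dAICc
#> 1         H6        4 1770.343    0.000
#> 2         H2        2 5063.544 3293.200
#> 3         H5        2 5129.403 3359.060
#> 4         H4        6 5286.015 3515.672
#> 5         H1        1 6659.960 4889.616
#> 6         H3        3 6743.149 4972.806

fe <- fit_flow_effect(y, labels, cov, hypothesis = "H6", method = "em")
fe$effects
#>              state    estimate       lower     upper sign excludes_zero
#> 1 channel.midwater  0.43828848  0.31824333 0.5583336    1          TRUE
#> 2    channel.otter -0.01285327 -0.13858641 0.1128799   -1         FALSE
#> 3   shoal.midwater  0.39979141  0.30658948 0.4929933    1          TRUE
#> 4      shoal.otter  0.10646306 -0.02988292 0.2428090    1         FALSE
```

The four-state habitat structure wins by thousands of AICc units, and the
two truly nonzero flow effects (channel- and shoal-midwater) are the two
whose intervals exclude zero — fish in pelagic habitats respond to
freshening, benthic series do not. Feeding the smoothed states into the
three DLM variants and comparing:

```r
st  <- extract_states(fe$fit)
dlm <- fit_dlm(build_dlm_design(st$mean, cov, lag = 0))
dlm$dynamics$label
#> [1] "static" "static" "static" "static"
sign_agreement(effect_comparison(fe$effects, dlm))$fraction
#> [1] 0.75
```

Under this static-truth scenario the DLM correctly finds no time-varying
slopes, and the two modelling approaches agree in sign for every group
with a genuinely nonzero effect (near-zero effects carry arbitrary
signs — exactly why sign agreement drops when the world is weak or
non-stationary).

A six-step scripted version of this workflow, writing tidy CSV/JSON
artifacts under `results/`, lives in `analysis/01_simulate.R` …
`analysis/06_compare_trends.R`.

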