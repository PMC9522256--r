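# mixtcc — mixed Tukey MEWMA–MA control charts

`mixtcc` is an R package for designing and evaluating control charts that
monitor the mean of a stream of individual observations — air-quality
loads, incidence counts, lab measurements — and signal when it drifts. Its
focus is the *mixed* charts that smooth the stream twice before testing it,
and their nonparametric Tukey variants whose limits are built from
quartiles instead of a normality assumption. The intended users are
quality/surveillance methodologists who need honest run-length numbers:
every chart here is evaluated by the same compiled Monte Carlo engine, with
closed-form and integral-equation oracles keeping it honest.

## The charts

For observations with in-control mean μ₀ and standard deviation σ:

* **MA**: the span-w moving average, limits μ₀ ± C·σ/√min(t, w).
* **MEWMA**: Mₜ = λXₜ + (1−λ)Mₜ₋₁ + k(Xₜ − Xₜ₋₁) — an EWMA with an extra
  weight k on the newest increment — with limits μ₀ ± C·σ·√v, where
  v = (λ + 2λk + 2k²)/(2 − λ) is the statistic's asymptotic variance ratio.
* **MMME / MMEM**: the two compositions (MA of the MEWMA, MEWMA of the MA),
  with limits scaled by √(v/min(t, w)) and √(v/w) respectively.
* **TCC / MMME-TCC / MMEM-TCC**: Tukey-style limits Q₃ + C·IQR·(scale) and
  Q₁ − C·IQR·(scale) around the quartiles of the monitored statistic's
  smoothing stage — the nonparametric versions, robust to skewness and
  outliers. MMEM-TCC is the proposed chart of the benchmark study this
  package reproduces: the best small-to-moderate-shift detector of the
  family.

Performance is measured on the run-length distribution: ARL (mean), SDRL
(standard deviation), MRL (median), estimated by zero-state Monte Carlo;
`calibrate_coefficient()` solves for the C giving a target in-control ARL
(370 by default), and `expected_arl()` averages ARL over a shift interval.

## A worked example

Compare the proposed MMEM-TCC chart with the plain moving-average chart
under the standard normal model, at the study settings w = 5, λ = 0.25,
k = −0.125 and the published coefficients:

```r
library(mixtcc)
normal <- process_model("normal", c(0, 1))
proposed <- chart_spec("MMEM_TCC", C = 5.320, w = 5, lambda = 0.25, k = -0.125)

estimate_rl_summary(proposed, normal, delta = 0, n_reps = 50000, seed = 1)
#> MMEM_TCC chart run-length summary (delta = 0, location shift, signal counting)
#>   ARL  = 371.48  (MC se 1.722, 50000 replications)
#>   SDRL = 385.05   MRL = 251

estimate_rl_summary(proposed, normal, delta = 0.5, n_reps = 50000, seed = 2)
#>   ARL  = 32.23  (MC se 0.136, 50000 replications)

estimate_rl_summary(chart_spec("MA", C = 2.882, w = 5), normal,
                    delta = 0.5, n_reps = 50000, seed = 3)
#>   ARL  = 51.64  (MC se 0.221, 50000 replications)
```

In control both charts false-alarm about every 370 points, as designed; at
a half-σ drift the mixed Tukey chart signals after ~32 points against ~52
for the MA chart — the small-shift advantage that motivates it. The same
workflow handles Phase I / Phase II monitoring of real series:

```r
x <- make_pm_series("pm25", 260, changepoint = 201, delta = 1, seed = 7)
report <- monitor_series(x, proposed, phase1 = 200)
attr(report, "first_signal")
#> [1] 3
```

Here a synthetic PM2.5-like series (exponential, mean ≈ 25 µg/m³) drifts
upward by one σ at observation 201; with parameters estimated from the
200-point Phase I prefix, the chart flags the change at the third monitored
point.

A thin command-line front end (`inst/cli/mixtcc.R`) exposes the same
functionality as `simulate`, `calibrate`, `earl`, `monitor` and `fixtures`
verbs driven by YAML configs; see the script header for usage.

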