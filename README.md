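# valsize

How many outcome events does the external validation of a time-to-event
prognostic model need? `valsize` answers that question the empirical way:
it takes (or generates) a large validation population whose true performance
is known, repeatedly draws samples containing a fixed number of events —
stratified so each sample keeps the population's event proportion — and
measures how biased, how variable, and how honestly covered the per-sample
performance estimates are as the event count grows.

It is aimed at biostatisticians designing or reviewing external validation
studies of Cox-type risk models (10-year cardiovascular or diabetes risk
scores are the motivating case), where validations are routinely attempted
with a few dozen events.

## What it computes

For each sample, six validation measures with standard errors:

| Measure | Definition | SE |
|---|---|---|
| Harrell's c-index | P(higher prognostic index → earlier event) over usable pairs | concordance variance |
| D statistic | Cox coefficient of kappa-scaled normal order scores of the PI, κ = √(8/π) | model-based |
| R²_D | (D²/κ²) / (σ² + D²/κ²), σ² = π²/6 | delta method |
| ρ²_OXS | 1 − exp{−(2/k)(l_β − l_0)} | bootstrap |
| Brier score (IPCW) | mean of Ŝ(t|X)² I(t≤10, δ=1)/Ĝ(t−) + (1−Ŝ)² I(t>10)/Ĝ(10) | bootstrap |
| Calibration slope | Cox coefficient of the PI | model-based |

and, across B replicates at each event count, the Monte-Carlo evaluation
layer: percent bias, standardized bias, RMSE, coverage of the 95% Wald
interval with its acceptable band p ± 2√(p(1−p)/B), mean CI width, and the
proportion of estimates within 0.5/2.5/5/10% of the truth. A sub-study
compares model-based, empirical and bootstrap standard errors of D and R²_D.

The synthetic population generator emulates a large primary-care registry:
multivariate-normal predictors, Weibull proportional-hazards outcomes, ~5%
events under dropout plus administrative censoring, and a "published model"
whose coefficients can be shrunken/inflated or perturbed so its true
calibration slope differs from 1 by a known amount. See the methods
vignette (`vignettes/validation-sample-size.Rmd`) for every default and why.

## Worked example

```r
library(valsize)

spec  <- covariate_spec()                                  # 8 predictors, rho = 0.2
model <- true_data_model()                                 # ~5.4% events by 15y
cal   <- calibrate_event_rate(spec, model, n_pilot = 2e5, seed = 11)
pop   <- generate_population(spec, cal, 2e5, seed = 11)
(theta <- true_performance(pop))
#>        name   estimate          se    ci_low   ci_high
#> 1   c_index 0.76496258 0.002283467 0.7604871 0.7694381
#> 2    d_stat 1.66744126 0.016015194 1.6360521 1.6988305
#> 3      r2_d 0.39895255 0.004606188 0.3899246 0.4079805
#> 4  rho2_oxs 0.64146336          NA        NA        NA
#> 5     brier 0.04237672          NA        NA        NA
#> 6 cal_slope 0.99228515 0.009498453 0.9736685 1.0109018
```

The population's true performance has the same structure as a large
published cardiovascular score: good discrimination (c ≈ 0.77, D ≈ 1.67),
R²_D ≈ 0.40, a low-event-rate Brier score ≈ 0.042, and a self-validated
calibration slope ≈ 1.

```r
res <- run_grid(pop, c(25, 100), replicates = 2000, seed = 77)
s   <- summarize_results(res, theta)
s[s$measure == "c_index", c("events", "percent_bias", "rmse", "coverage", "mean_ci_width")]
#>   events percent_bias       rmse coverage mean_ci_width
#> 1     25 -0.003964041 0.04723283   0.9255    0.18009010
#> 7    100 -0.008975607 0.02346962   0.9450    0.09214167
```

Read: with 25 events the c-index is essentially unbiased on average but a
single study's estimate is off by ±0.05 (RMSE) and its nominal 95% interval
only covers 92.6% of the time; at 100 events the RMSE halves and coverage
approaches nominal. Across the full grid the package reproduces the
headline finding: fewer than ~100 events gives unreliable validation, and
~200 or more is needed before coverage and precision settle.

## Command line

```sh
valsize all --config run.cfg           # simulate -> resample -> summarise
valsize run --config run.cfg --replicates 10000 --paper-scale
```

`run.cfg` is flat `key = value` text (mandatory `seed`); outputs are CSVs
plus a JSON manifest per step, byte-reproducible given config + seed.

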