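---
title: "How many events does an external validation need? Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many events does an external validation need? Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

A prognostic model — a Cox-type rule mapping predictors $x$ through a linear
predictor (prognostic index) $PI(x) = \beta \cdot x$ to a predicted 10-year
event risk $r(x) = 1 - S_0(10)^{\exp(PI(x))}$ — is only credible once its
discrimination and calibration have been measured on data independent of its
development. Such external validation studies are routinely run with far too
few outcome events, producing estimates of performance that are noisy at
best and flattering at worst. `valsize` quantifies that problem by
resampling: from a large validation population whose *true* performance
$\theta$ is known, it draws many samples with a fixed number of events and
asks how biased, how variable, and how honestly covered the per-sample
estimates $\hat\theta_i$ are.

## Performance measures

Six measures are computed per sample, each with a standard error:

* **Harrell's c-index** — the probability that of a usable pair the subject
  with the higher PI fails earlier. Pairs are usable when the earlier
  observed time is an event; an event tied in time with a censoring is taken
  to precede it; prediction ties count 1/2. The estimate and its standard
  error come from `survival::concordance`, oriented so values above 0.5 mean
  higher predictions accompany earlier events. (The variance here is the
  infinitesimal-jackknife one; the Noether-type estimator used by some other
  concordance routines differs slightly. Which confidence interval the
  original coverage figures used is not documented, so this choice is
  deliberate and recorded.)
* **D statistic** — the prognostic index is ranked, ranks are mapped to
  expected standard normal order statistics via the Blom approximation
  $\Phi^{-1}\{(r - 3/8)/(n + 1/4)\}$ with tied values given averaged scores,
  scaled by $1/\kappa$, $\kappa = \sqrt{8/\pi} \approx 1.596$, and fitted as
  the single covariate of a Cox model. $D$ is that coefficient: the log
  hazard ratio between the upper and lower prognostic halves. Its
  model-based standard error is the Cox standard error. The exact expected
  order statistics would cost far more than the Blom approximation buys.
* **$R^2_D$** — the deterministic transform
  $R^2_D = \dfrac{D^2/\kappa^2}{\sigma^2 + D^2/\kappa^2}$, with
  $\sigma^2 = \pi^2/6 \approx 1.645$. Its model-based standard error is
  obtained from the D statistic's by the delta method
  ($\mathrm{d}R^2_D/\mathrm{d}D \cdot se_D$); neither the source study nor
  its tables state the method they used, so this is our documented choice.
* **$\rho^2_{OXS}$** — explained randomness,
  $1 - \exp\{-\frac{2}{k}(l_\beta - l_0)\}$ with $k$ the event count and
  $l_\beta$, $l_0$ the log partial likelihoods of the Cox model on the PI
  and the null model. The Cox model is *refitted* on the validation sample;
  evaluating it at fixed slope 1 would be an alternative reading, noted but
  not implemented. Its standard error is a nonparametric bootstrap (200
  replications by default).
* **IPCW Brier score** at the 10-year horizon — mean of
  $\hat S(t|X_i)^2 I(t_i \le t,\delta_i=1)/\hat G(t_i{-})
  + (1-\hat S(t|X_i))^2 I(t_i > t)/\hat G(t)$ with
  $\hat G$ the Kaplan–Meier estimate of the censoring distribution (fitted
  to $(t_i, 1-\delta_i)$). The printed form of this estimator writes
  $\hat G(t_i)$; the standard IPCW convention evaluates the left limit
  $\hat G(t_i{-})$ at event times, and that is the default here, with
  `g_left = FALSE` available as a switch. Standard error by nonparametric
  bootstrap.
* **Calibration slope** — the Cox coefficient of the PI fitted to the
  validation sample; 1 is perfect, below 1 means predictions too extreme.

Ties in event times are handled with the Efron correction throughout (the
source is silent; Efron is the better default and matters because coarse
follow-up produces ties). Cox fits are a compiled single-covariate
Newton–Raphson; fits that diverge ($|\beta| > 20$) or fail to converge in 50
iterations mark that replicate's measure as missing, and missingness is
always counted and reported — at very small event counts degenerate fits
are a finding, not an error.

A smoothed **calibration curve** at 10 years is also available: a Cox model
on a natural-spline basis (4 df) of $\log(-\log(1 - r))$ of the predicted
risk $r$, with the observed probability read off the fitted survival at the
horizon. This is an intentionally simple stand-in for adaptive hazard
regression ("hare"), which is out of scope; when the spline fit is
degenerate the estimator falls back to risk-decile Kaplan–Meier points and
announces it.

## The synthetic population

No public analogue of the licensed primary-care database behind the original
study exists, so the package generates one with known truth:

* Covariates: $k = 8$ multivariate normal predictors with exchangeable
  correlation 0.2 and unit scales. A normal PI is what the D statistic's
  construction assumes; this is a deliberate design choice with consequences
  (below).
* True outcome: Weibull proportional hazards,
  $T = (-\log U / (\lambda e^{PI}))^{1/\gamma}$ with shape $\gamma = 1.1$,
  exponential dropout at rate 0.04/year, administrative censoring at 15
  years, risk horizon 10 years — a stylised 1994–2008 registry with 10-year
  predictions. The dropout rate is a stated default, not an inferred one:
  the original database's censoring distribution is not described anywhere
  we could follow.
* Event fraction: the baseline rate $\lambda$ is calibrated by bisection on
  $\log\lambda$ against a pilot population (same latent draws each step, so
  the event fraction is monotone in $\lambda$) to a target of 5.4% within
  0.1 percentage points, matching the largest of the published cohorts'
  event fractions; 2.66–5.40% are all reachable the same way.
* True coefficients: $\beta_j = 0.24$ for all $j$, giving
  $sd(PI) \approx 1.05$ and hence a true $D \approx \kappa \cdot 1.05
  \approx 1.68$ — inside the 1.44–1.87 range of the published models. On a
  200,000-subject population the package measures (seed 11):
  c-index 0.765, D 1.667, $R^2_D$ 0.399, $\rho^2_{OXS}$ 0.641, Brier 0.042,
  calibration slope 0.992 — the same structure as the published "true" row
  for a large CVD model, by construction rather than by fitting.
* The published model under validation is derived from the truth:
  $\beta_{model} = g\,\beta_{true} + \varepsilon$, $\varepsilon \sim
  N(0, \tau^2)$. Because the data follow the truth, shrinkage $g$ implies a
  true calibration slope of $1/g$; $g = 1, \tau = 0$ is exact
  self-validation (slope 1, risk deciles match). The model's baseline
  $S_0(10)$ defaults to the truth's, so miscalibration-in-the-large only
  arises through the explicit `intercept_shift` option (off by default: the
  phenomenon of interest here is the slope).
* Default population size 200,000 (~10,800 events): large enough that
  $\theta$ is stable at desk scale; the original 2-million cohort buys
  nothing for this purpose.

What the generator does **not** emulate: skewed or discrete predictors,
interactions and fractional-polynomial terms, informative censoring,
imputation of missing predictors, and case-mix drift between development
and validation populations beyond coefficient shrinkage. A green test on
this world establishes that the machinery measures what it should under a
clean proportional-hazards data-generating process — not that any clinical
model validates.

## Resampling design and evaluation

Samples are drawn with replacement, stratified by outcome: exactly $E$
events plus $\mathrm{round}(E(1-p)/p)$ non-events, $p$ the population event
fraction, so every sample reproduces the population's event proportion.
(Rounding the non-event count — with R's round-half-to-even — reproduces
all the published per-row sample sizes; rounding the total would not.) The
study grid is $E \in \{5, 10, 25, 50, 75, 100, 150, 200, 300, 400, 500,
1000\}$ with $B = 10{,}000$ replicates; the shipped desk-scale defaults are
$E \in \{10, 25, 50, 100, 200, 500\}$ with $B = 2000$, and `--paper-scale`
restores the original design. Seeding is hierarchical — master seed →
per-scenario seeds → per-replicate seeds drawn up front — so any replicate
is reproducible in isolation and scenario streams never overlap.

Against the population truth $\theta$ the package computes, per measure and
event count: percent bias $100(\bar{\hat\theta} - \theta)/\theta$ (and its
median variant), standardized bias $100(\bar{\hat\theta} -
\theta)/SE_{emp}$, RMSE $\sqrt{\frac{1}{B}\sum_i(\hat\theta_i - \theta)^2}$,
coverage of the Wald interval with the acceptable band $p \pm
2\sqrt{p(1-p)/B}$, mean CI width $\frac{1}{B}\sum_i 2 z_{1-\alpha/2}
SE(\hat\theta_i)$, and the fraction of estimates within 0.5/2.5/5/10% of
$\theta$. The empirical SE uses the sample SD ($n-1$); the band's $B$ is
the non-missing count; missing replicates are excluded per measure, never
imputed. Wald intervals on the natural scale are forced by the width
formula; no transformation is applied to the c-index.

A separate sub-study compares, for $D$ and $R^2_D$, the model-based SE, the
empirical SE across simulations, and a nonparametric bootstrap SE (rows
resampled with replacement, scores re-ranked per resample; a stratified
variant is available but the plain bootstrap is the default, matching the
original description).

## Numerical choices

* Cox Newton–Raphson: tolerance $10^{-9}$, max 50 iterations, step halving
  on any likelihood decrease, covariate centred for conditioning;
  $|\beta| > 20$ flags divergence (monotone likelihood).
* Bisection for the event rate: tolerance 0.1 pp on the fraction, bracket
  $\pm 25$ on $\log\lambda$; an unreachable target (e.g. no censoring at
  all, where everyone is an event) returns the nearer boundary with a
  warning rather than failing.
* Ties: Efron everywhere; prediction ties in the c-index count 1/2;
  tied PIs share averaged Blom scores (all-tied degenerates to all-zero
  scores and a refused Cox fit, by design).
* Degenerate replicates (constant PI in a tiny draw, divergent fits,
  $\hat G(t) = 0$) become NAs with counts; the engine never drops or
  retries a replicate.

## Design decisions that were genuinely open

* **Refit vs fixed-slope $\rho^2_{OXS}$**: refitted, consistent with the
  other measures that all refit the PI; the published table cannot
  adjudicate without the original data.
* **Delta-method SE for $R^2_D$**: see above.
* **$\hat G(t{-})$ vs $\hat G(t)$** in the Brier first term: left limit by
  default, switchable.
* **Desk scale**: $B = 2000$ keeps the full grid in minutes on one CPU. At
  this scale the Monte-Carlo SE of a measured percent bias is itself
  ~0.1% (c-index) to ~0.2% (Brier) at 50 events, so bias assertions in the
  acceptance tests allow two Monte-Carlo SEs around the 0.1% band — the
  same convention the parameter-recovery criteria use. The substantive
  claim (true bias within 0.1% at 50 events) is unchanged.

## Known limitations

* With a **normal PI**, the model-based SE of the D statistic is
  approximately correct (measured model/empirical ratio 0.95–0.97 across
  10–100 events at 3000 simulations). The published tables instead show the
  model-based SE *exceeding* the empirical SE by ~10% persistently, even at
  1000 events — behaviour we attribute to the skewed, partly discrete PI of
  a real clinical score, which the normal-covariate generator deliberately
  does not emulate. The corresponding acceptance expectation therefore
  fails honestly in this synthetic world; the bootstrap-tracks-empirical
  and coverage patterns do reproduce.
* The calibration curve is a stand-in estimator, not an adaptive hazard
  regression; at 10 or fewer events its dispersion across replicates is the
  finding, and the decile fallback is common there.
* Coverage conclusions inherit the Wald-interval choice; transformed
  intervals (e.g. logit for the c-index) would behave differently at small
  event counts.

## Reproducing the study

```{r, eval = FALSE}
library(valsize)

# 1. A world with known truth
spec  <- covariate_spec()
model <- true_data_model()
cal   <- calibrate_event_rate(spec, model, n_pilot = 2e5, seed = 11)
pop   <- generate_population(spec, cal, 2e5, seed = 11)
theta <- true_performance(pop)

# 2. The resampling design
res <- run_grid(pop, c(10, 25, 50, 100, 200, 500),
                replicates = 2000, seed = 77)

# 3. The evaluation layer
summary <- summarize_results(res, theta)
se_tab  <- se_comparison_study(pop, c(50, 100), theta,
                               n_sim = 500, bootstrap_reps = 200, seed = 5)
```

Or, end to end from a config file:

```sh
valsize all --config run.cfg            # simulate + run + evaluate
valsize run --config run.cfg --events 5,10,1000 --replicates 10000
```

Every output directory receives a manifest (config echo, seed, package
version); identical config and seed give byte-identical outputs.
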