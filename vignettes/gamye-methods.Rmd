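---
title: "Hierarchical GAMYE trend models for route-level count surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical GAMYE trend models for route-level count surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continental roadside surveys such as the North American Breeding Bird Survey
(BBS) count birds once per year on fixed ~50-stop routes, during a fixed
late-May-to-early-July window. Estimating multi-decade population trends from
these data has to contend with overdispersed counts, observer differences and
observer turnover, short-term annual fluctuation superimposed on long-term
change, and very uneven spatial coverage. The standard modern answer is the
hierarchical Bayesian Generalized Additive Model with Year Effects (GAMYE),
which this package implements end to end: data screening and minimum-data
filters, the model itself, a phenology-corrected variant, and the
index/trend/credible-interval summaries that conservation assessments quote.

A companion concern motivates the variant model: species have been breeding
earlier in recent decades. If peak detectability drifts away from the fixed
survey window, a fixed-window survey undercounts late-era populations and a
genuine-looking "decline" could be an artifact. The phenology-corrected GAMYE
adds a decade-specific smooth of survey day of year whose peak can lead or lag
the preceding decade's, so this hypothesis can be tested directly against the
standard model.

## The model

For route `r` in stratum `s`, year `y`, observed by observer `o`:

$$
C \sim \text{Poisson}(\lambda), \qquad
\log \lambda = \mu_s + \sum_k \beta_{s,k} X_{y,k} + \gamma_{s,y}
  + \omega_{o} + \eta\, I(\text{first year}) + \varepsilon
$$

* `X` is a cubic B-spline basis over the modeled years (partition of unity,
  evenly spaced interior knots; default dimension one basis function per ~4
  years). The stratum coefficients are shrunk toward a continental mean
  smooth, `beta_{s,k} ~ N(B_k, sigma_B^2)`, with the shrinkage sd pooled
  across knots for stability at small numbers of strata.
* `gamma_{s,y} ~ N(0, sigma_{gamma,s}^2)` are the *year effects*: annual
  departures from the smooth, with per-stratum sds.
* `omega ~ N(0, sigma_omega^2)` is an observer effect, by default one effect
  per observer-route combination (the unit at which observer differences are
  observable in route-level data).
* `eta` is the first-year-observer effect.
* `epsilon ~ N(0, sigma_epsilon^2)` is count-level lognormal overdispersion
  (the Poisson-lognormal family; a negative-binomial option is deliberately
  not offered, keeping one tested code path).

Priors are weakly informative on the log-count scale: `mu_s ~ N(0, 10^2)`,
`B_k ~ N(0, 2^2)`, `eta ~ N(0, 1)`, and half-Normal(0, 1) on every sd. All of
these are configurable through `gamye_spec()`.

### Identifiability of the smooth

Because B-spline rows sum to one, a constant shift of all smooth coefficients
is indistinguishable from a shift of the stratum intercepts. We therefore (a)
center the basis columns over the modeled years, so the smooth is a mean-zero
departure and `mu_s` is the stratum's period-mean log abundance, and (b)
sample the coefficients inside the (K−1)-dimensional subspace orthogonal to
the constant coefficient vector (the null space of the centered basis),
mapping draws back to the full K coefficients afterwards. Without this
reparameterization the sampler shows severe autocorrelation and split-R-hat
values above 2; with it, the same model mixes in a few thousand iterations.
The reported `beta` draws always satisfy `sum_k beta_{s,k} = 0`.

### The phenology-corrected variant

`fit_gamye_phenology()` adds a survey-wide, decade-specific smooth of log
mean over survey day of year:

$$
s_d(\text{day}) = \sum_k \alpha_{d,k}\, D_c(\text{day}, k), \qquad
\alpha_{d,k} \sim N(\alpha_{d-1,k}, \sigma_\alpha^2)
$$

* `D_c` is a B-spline basis over the survey window (default days 145–190,
  five basis functions) with columns centered over the daily grid, so every
  decade's curve has mean zero over the window *by construction, in every
  draw*. This matters: without centering, the date term would absorb decade
  mean abundance and be confounded with the trend it is meant to check.
* The first-order random walk across decades (first decade `~ N(0, 1)`) is
  the minimal "time-series" structure that lets each decade's peak lead or
  lag the preceding decade's while sharing the curve's shape. Higher walk
  orders are not implemented; with at most five or six decades of data a
  second-order walk is weakly identified.
* The date effect is survey-wide rather than per stratum; a per-stratum
  extension is possible but multiplies the coefficient count by the number of
  strata for a term that is usually a small correction.
* Decades are `floor(year/10)*10`. A decade inside the modeled range with no
  records keeps its random-walk prior and is flagged
  (`fit$decades_observed`), not an error.

`estimate_decade_peaks()` takes, per posterior draw, the argmax of each
decade's curve over a day grid, and summarizes peaks and decade-to-decade
shifts with posterior medians and equal-tailed intervals. A decade whose
posterior-median curve has amplitude below 0.01 on the log scale is reported
as having an *undefined* peak: the argmax of an essentially flat curve is a
grid-edge artifact, not a phenological signal.

## Indices, trends, and intervals

`compute_indices()` retransforms to the count scale:
`exp(mu_s + smooth + [gamma] + sigma_omega^2/2 + sigma_epsilon^2/2)` — the
lognormal mean, integrating the observer and overdispersion effects out, so
an index is the expected count on an average route. The half-variance terms
are a deliberate choice of the mean over the median: indices represent
expected counts. The `smooth` component omits `gamma` and is the default for
trend estimation; `full` keeps it and is what one plots.

`composite_index()` aggregates strata by area:
`sum_s A_s I_{s,y} / sum_s A_s`, per draw. Area-only weighting is used; an
area-times-mean-abundance alternative exists in the literature but requires a
population-size model we do not fit.

`endpoint_trend()` is the geometric annual rate
`100((I_{y2}/I_{y1})^{1/(y2-y1)} - 1)` and `trend_to_percent_change()` its
exact compounding inverse `100((1 + r/100)^{y2-y1} - 1)`; over 1970–2019 the
exponent is 49. Both are computed per draw and then summarized — never by
transforming summaries — so the pair satisfies the compound identity draw by
draw (medians of the two summaries, being medians of nonlinear transforms,
need not).

`credible_interval()` uses equal-tailed percentiles with linear interpolation
between order statistics (quantile type 7), declared so interval values are
exactly reproducible. Intervals default to 90%; the standard-vs-corrected
model comparison (`compare_trends()`) uses 95%, following the different
conventions for parameter summaries and model contrasts.

## Data screening

`screen_validity()` drops runs flagged invalid and any record outside the
survey-day window (default day of year 145–190; the window is configurable
since the protocol defines it verbally, not numerically). A stratum enters
the model only if it has at least three routes on which the species was
observed, at least one such route surveyed in five or more distinct years,
and at least one route with the species observed in three or more distinct
years. "Observed" means at least one positive count within the modeled year
range, and years are distinct, not consecutive. The criteria are evaluated
within whichever year range is being modeled, so a stratum can qualify for a
long-term analysis and fail a short-term one. `apply_inclusion_filters()`
reports which criterion failed for every dropped stratum, and filtering is
idempotent and order-invariant (tested properties).

## The synthetic-data generator

`simulate_dataset()` emulates the survey's structure with known ground truth:
strata of roadside routes, one survey per route-year on a uniform random day
inside the window, counts summed over stops, observer turnover (default
probability 0.1/year) with first-year flags, and the same effect structure
the model assumes — per-stratum intercepts (sd 0.3 around the configured mean
log abundance), a geometric annual trend, year effects (sd 0.1), observer
effects (sd 0.2), a first-year effect (−0.1), and lognormal overdispersion
(sd 0.15). Defaults are on the log scale and were chosen once as
representative of route-level survey data: year-to-year fluctuations of
~10%, between-observer differences of ~20%, novice undercounting of ~10%.

The optional seasonal term is a Gaussian bump on the log mean,
`peak_height * exp(-(day - peak_day)^2 / (2 peak_width_sd^2))`, with the peak
day stepping by decade; `simulate_phenology_shift()` drifts it by a fixed
number of days per decade. The bump is a modeling choice — no survey protocol
specifies the true within-season detectability curve — and the true
trajectory is log-linear plus year effects, which suffices for
parameter-recovery testing and keeps closed-form oracles available
(`expected_mean_count()`).

What the generator does *not* emulate — and hence what passing recovery tests
cannot certify about real data: spatial structure among routes, non-geometric
(curved) true trajectories, weather-driven validity patterns, stop-level
detail, and any correlation between observer quality and route quality.
Recovery tests show the estimator answers the model's own question correctly;
they cannot validate the model against field reality.

## Numerical and scale choices

* MCMC uses JAGS through rjags, behind a seeded draws-in/draws-out contract
  (`mcmc_options()`); chain c runs on RNG seed `seed + c`, so runs are exactly
  reproducible for a fixed engine version. At least two chains are required.
* Convergence is summarized by split-R-hat (each chain halved, so
  within-chain drift inflates the statistic) and an autocorrelation-based
  effective sample size with Geyer initial-monotone truncation. A fit passes
  at max split-R-hat ≤ 1.05; failing fits are returned with a warning and
  `converged = FALSE`, and the pipeline refuses to proceed on them unless
  explicitly told to. Constant-chain parameters have undefined R-hat and are
  flagged degenerate rather than passed.
* The test-suite and example problem sizes (two to four strata, six to twelve
  routes per stratum, 15–50 years, 2 chains × 500–600 retained draws) were
  chosen so the full suite runs on a single CPU in minutes; they are
  deliberately at the small end of what the model is designed for, and the
  recovery tolerances used in tests (±1.5 %/yr on a −4 %/yr trend, ±3 days
  on decade peaks) reflect that scale.
* Trend periods default to the full modeled range plus the final decade,
  mirroring the long-term/short-term reporting convention; arbitrary periods
  are accepted and validated against the modeled years.

## Known limitations

* The overdispersion family is Poisson-lognormal only; heavy-tailed
  (t-distributed) overdispersion and spatial (iCAR) smoothing between strata
  are out of scope.
* Single-stratum datasets collapse the hierarchy onto its mean; they fit, but
  the shrinkage sds are then prior-dominated.
* The phenology term is survey-wide; a species whose breeding-date shift
  differs sharply between regions would violate this.
* JAGS's componentwise samplers mix slowly for strongly confounded terms
  (e.g. `sd_alpha` when there is no date signal); short runs can flag
  non-convergence on such nuisance parameters even when trend summaries are
  stable. The diagnostics table says which parameters are at fault.
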