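---
title: "Simulating month-of-birth misreporting and its artifacts in HAZ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating month-of-birth misreporting and its artifacts in HAZ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Height-for-age z-scores (HAZ) standardize a child's measured height by the
median and SD of a healthy reference population at the same age, so an error
in the recorded age moves the z-score even when the height measurement is
perfect. In household surveys in low-registration settings the month of birth
(MOB) is often elicited from a caregiver's recollection, and two stylized
error mechanisms leave recognizable fingerprints in the pooled data:

* **Calendar-year artifact.** If a fraction `p` of children report a random
  month within their true birth year, children *reported* born early in the
  year are on average younger than their record says (hence short for their
  reported age) and children reported born late are older (hence tall).
  Because height grows monotonically with true age -- a biological clock --
  this produces a linear upward gradient in mean HAZ across reported birth
  months and a discrete drop from the last month of the calendar year to the
  first (the "December--January gap" on a Gregorian calendar). The gap is
  proportional to `p`, which is what makes it usable as a calibration target:
  `mobhaz` inverts an observed gap into an estimated misreporting share.
* **Round-age artifact.** When interviews anchor on age in completed years
  and then add months, added months are skewed toward zero; ages are rounded
  *down*. Reported ages heap at 12, 24, 36, 48 months with quasi-linearly
  declining shoulders, and mean HAZ steps *up* at round ages (understated age
  makes a child look tall). Unlike the calendar artifact this diagnostic is
  confounded with genuine growth faltering: mean HAZ declines with age over
  the first two years, so the round-age gap is positive even with perfect
  reporting.

The package simulates a survey population in which both mechanisms can be
switched on with known intensity, provides the diagnostics (monthly HAZ
profiles, gaps with standard errors, age histograms, a Myers blended index
adapted to months, and the dummy-variable regressions with cluster-robust
errors), calibrates `p` from a target gap, and traces the bias that MOB
misclassification induces in estimated effects of early-life shocks.

## The growth reference and the benchmark population

The shipped table `growth_standard_girls.csv` is a daily-resolution
reconstruction of the WHO girls' length/height-for-age standard: the
published monthly medians and coefficients of variation (L = 1, so
SD = CV x median) are splined to days with a monotone Hermite interpolant.
Two deliberate departures from the verbatim WHO tables:

* **One continuous curve.** The recumbent-length/standing-height transition
  at 24 months (a 0.7 cm protocol discontinuity) is removed by shifting
  standing values up 0.7 cm. Every statistic in the package compares heights
  drawn from this standard against the same standard, so internal consistency
  matters and the discontinuity would only inject a spurious kink.
* **Extension to 72 months.** True ages run to 71 months so that children
  truly older than 59 months can be mis-aged *into* an under-five sample;
  months 61--72 are extrapolated by continuing the late velocity and CV
  trends.

`build_benchmark()` turns the healthy reference into a faltering,
DHS-like "benchmark" population:

* growth velocity reduced by 7% on 0--6 months, 21% on 6--24 months and 10%
  from 24 months on (daily increments scaled, so birth length is preserved);
* dispersion transformed as `sigma_b = (SD + 2 cm) x 0.85`.

The velocity reductions reproduce observed growth faltering; the SD
inflation stands in for measurement noise and nutritional heterogeneity,
and the 0.85 multiplier flattens the growth of the SD with age. The additive
and multiplicative SD adjustments are stated without an order; we default to
adding first (`sigma_b = (SD + 2) * 0.85`) and expose the alternative
(`sd_order = "mult_first"`, `sigma_b = SD * 0.85 + 2`). Against the
untransformed standard the default benchmark yields about 35% stunting
(HAZ < -2) and 13-15% severe stunting (HAZ < -3) for ages 0--59 months,
the intended DHS-like level; the alternative order gives slightly higher
rates and is retained as a sensitivity switch. Note the SD transform affects
stunting rates but not the December--January gap, which is a property of
cell means.

## The synthetic survey

`simulate_children()` draws, per child: a true age uniform in days over the
configured range (default 0--71 months), a survey date uniform over one
calendar year, the birth date by subtraction (so the true birth day is
uniform within each month's actual length and the true MOB is independent of
age up to month-length differences), survey and cluster labels with sizes as
equal as possible, two household covariates (standard-normal wealth, a rural
flag) with configurable -- default zero -- additive height effects, an
optional cluster-level height shift for intra-cluster correlation, and a
height Normal(mu_b(age), sigma_b(age)). Heights are cross-sectional draws;
no within-child trajectory is modelled because no statistic in scope needs
one.

What the generator deliberately does **not** emulate: genuine seasonality of
health or births (so any MOB gradient is attributable to injected error by
construction), survey weights and two-stage sampling, household rosters and
nonresponse, boys (the reference is a female population), and gestational
length (shock exposure is by birth month alone). Passing tests therefore
demonstrate the mechanics of the error processes, not the size of these
phenomena in any particular real survey.

## The error operators

`apply_random_mob()` gives a Bernoulli(`p`) subset a reported month uniform
over the 12 months of the local calendar year containing the true birth date
(`year_start_month` relocates the year boundary, e.g. 4 for a Nepali-style
April calendar) and a reported day uniform within that month. Three
decisions:

* The random month **includes the true month**, so the effective
  displacement probability is `11/12 p`. This convention makes the
  closed-form oracle exact: with constant velocity `v` and constant SD
  `sigma`, the expected gap is `-11 p v / sigma`. Shares estimated by the
  calibration are defined under this convention; a convention that excludes
  the true month relabels the same mixture with `p' = 11/12 p`.
* A random month can postdate the survey for children surveyed in their
  birth year; the draw is kept, the reported age goes negative and the
  record is removed by `apply_age_selection()`, mimicking
  implausible-record exclusion. `redraw_future = TRUE` resamples instead
  (falling back to the truth for children surveyed so close to New Year
  that almost no draw is valid), and `use_day_15 = TRUE` reproduces the
  survey convention of assigning day 15.
* Each child carries at most one error: an operator draws among
  still-truthful records, rescaled so its *marginal* share is exact. The two
  operators therefore compose into a clean mixture and neither artifact
  dilutes the other.

`apply_round_age_rounding()` gives a Bernoulli(`q`) subset a reported age of
`12 x completed years + k` months with `k` drawn from non-increasing weights
(default linearly declining, `(12 - k)/78`), the simplest shape consistent
with the observed quasi-linear decline of the age histogram after each round
age. The reported birth date is moved to match (days = `ceiling(months x
30.4375)`, which keeps the reported completed months exact). This operator is
an extension used for the round-age diagnostics; the calendar-year
calibration deliberately omits it, because the round-age gap is confounded
with real faltering.

`apply_age_selection()` keeps `0 <= reported age < 60` months -- selection on
the *reported* age, as in survey practice, which is why the population must
extend beyond 59 months of true age.

## Diagnostics and regressions

Gaps are reported as `mean(first calendar month) - mean(last month)` (so a
misreporting artifact is negative) with pooled two-sample standard errors.
`fit_haz_regression()` estimates the artifact dummies -- 11 MOB dummies with
the last calendar month as reference and/or 11 months-past-round dummies with
the round age as reference -- with no controls (Model 1, whose coefficients
equal raw cell-mean differences exactly), adding age, age squared, a sex term
when one varies, and survey fixed effects (Model 2), and household covariates
(Model 3). Standard errors are clustered at the enumeration-area level with
the CR1 small-sample correction (`sandwich::vcovCL`), the standard choice for
survey OLS; estimation is unweighted. The simulated population is girls-only,
so the sex control enters only for user-supplied tables that carry a varying
`sex` column.

The Myers blended index is adapted from its demographic use on ages in years
to the terminal digit of age in months over 0--59 (windows 0--49 and 10--59
with the classic blending weights). It is flagged undefined below 10
observations; note that on a 0--59 month support a single terminal digit
spans at most 6 distinct ages, so the theoretical maximum of 90 is attainable.

## Calibration

`estimate_random_mob_share()` inverts the monotone, almost exactly linear map
`p -> gap(p)` by bisection on Monte-Carlo evaluations (each evaluation
averages the full simulate-inject-select-measure pipeline over `reps`
populations). The search stops when the simulated gap matches the target
within `tolerance` (default 0.005 HAZ) or the iteration budget is exhausted;
the confidence interval maps the Monte-Carlo SE of the gap through the local
slope of `gap(p)` fitted to the search trace (anchored at the exactly known
`gap(0) = 0`). Targets outside `[gap(1), 0]` raise an out-of-range error.
Defaults per evaluation are 10^6 children and 3 replications; with those
sizes the gap's Monte-Carlo SE (~0.004) is comparable to the tolerance, so
the estimated share is resolved to roughly +-0.2 percentage points before
fixture and convention uncertainty.

## Shock-bias experiments

`shock_scenario()` defines a two-month in-utero event harmful only to
children *born* in those months. Exposed children lose `0.03 x reference
birth length` (about 1.47 cm) from attained height at every age before HAZ is
computed -- the fixed-deduction reading, which yields a true average
treatment effect near -0.5 HAZ; a proportional-to-current-height variant is
exposed behind `proportional = TRUE` for sensitivity analysis, but it implies
an effect that grows with age and a much larger ATE, so it is not the
default. Test scores are Normal(50, 10) raw, 3% lower for exposed children,
standardized by the overall sample mean and SD.

`estimate_exposure_effect()` regresses the outcome on the *reported*-MOB
exposure classification (plain bivariate OLS; for a binary regressor the
slope is the difference in group means). `bias_sweep()` traces the estimate
over a grid of misreporting shares, optionally with common random numbers
across grid points, and `reversal_threshold()` locates the sign change of a
late-year shock estimate by a local linear fit around the first positive
grid point (grid step 0.01 by default). The geometry of the bias is the
point of the exercise: children reported born early in the year carry
downward HAZ bias and children reported born late carry upward bias, so an
early-year (January--February) shock is overstated, a midyear (June--July)
shock is purely attenuated, and a late-year (November--December) shock is
offset and eventually sign-reversed as the misreporting share grows. For
outcomes that do not embed age -- the test score -- misclassification can
only attenuate, whatever the shock timing.

## Numerical conventions and problem sizes

* Months convert to days at 30.4375 days/month everywhere; age bands for the
  velocity reductions sit at 6 and 24 months on that scale.
* Reference queries interpolate linearly on the daily grid; ages outside the
  grid raise an error in `compute_haz()` and yield `NA` (then removal by
  selection) inside the error operators.
* Stunting cutoffs are strict: HAZ < -2 and HAZ < -3.
* All randomness flows through R's global RNG; `sim_config(seed = )` pins a
  population, replication r of a Monte-Carlo evaluation uses `seed + r - 1`,
  and identical configurations reproduce byte-identical outputs.
* The test suite runs its property checks at 10^5 to 10^6 children --
  sizes at which Monte-Carlo error is small against every asserted effect --
  and the study-scale checks (gap at p = 0.11, calibration, stunting rates,
  shock effects) at 10^6 children, with 2.5 x 10^5 children per grid point
  for the reversal sweep.

## Known limitations

* The growth reference is a reconstruction from published monthly values,
  not the verbatim WHO daily tables; medians match to interpolation accuracy
  but the SD curve above 24 months is piecewise-linear in the CV between
  published anchors, and ages 61--72 months are an extrapolation. Statistics
  that average 1/SD or tail probabilities (shock ATEs, severe stunting)
  inherit a percent-level uncertainty from this.
* The calibrated share is convention-dependent (see the random-month
  inclusion note above): a study that displaces every misreporter will
  report a share 11/12 as large for the same observed gap.
* The December--January gap estimates a *lower bound* of age misreporting:
  it is blind to round-age rounding, symmetric heaping, and errors in the
  birth year.
* Real surveys confound the round-age artifact with genuine faltering; the
  package reproduces that confound but cannot separate it without the age
  controls of the Model 2/3 regressions.
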