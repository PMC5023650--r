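---
title: "Validating the APPS: models, conventions and design choices"
author: "appsval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the APPS: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appsval)
```

## The score and the validation problem

The APPS is an additive prognostic score for hospital mortality in
moderate or severe ARDS (PaO~2~/FiO~2~ ≤ 200 mmHg).  Three routinely
available variables — **A**ge (years), **P**aO~2~/FiO~2~ (mmHg) and
**P**ressure (plateau pressure, here the maximal airway pressure under
pressure-controlled ventilation, cmH~2~O) — are each banded into three
ordered categories worth 1, 2 or 3 points, so the total score `S` lies
in 3–9.  Risk direction is physiological: older age and higher airway
pressure score more points; a *lower* P/F ratio scores more points.

External validation of such a score asks two separate questions:

* **Discrimination** — does the score rank decedents above survivors?
  Summarised by the AUC-ROC, i.e. the tie-corrected concordance
  probability `P(S_death > S_surv) + ½ P(equal)`, with a DeLong
  structural-components confidence interval, a Youden-optimal operating
  point (maximising `sens + spec − 1`) and its likelihood ratios
  `LR+ = sens/(1−spec)`, `LR− = (1−sens)/spec`.
* **Calibration** — do observed death rates per score level agree with
  the expected ones?  Assessed by a Hosmer–Lemeshow chi-square over
  score levels, and repaired, when broken, by *recalibration*: moving
  band cutoffs while keeping the 1/2/3 point weights fixed.

The package implements both, plus the per-category association tables
(odds ratios with Wald intervals and a trend test) and Kaplan–Meier
survival stratified by score categories, behind one reproducible
pipeline (`run_validation()`, or the `inst/cli/appsval.R` command-line
tool).

## Cutoff sets and boundary conventions

Two cutoff sets ship as built-ins:

| variable | original | recalibrated |
|---|---|---|
| age (y) | <47 / 47–66 / >66 | <47 / 47–59 / >59 |
| P/F (mmHg) | >158 / 105–158 / <105 | unchanged |
| Pmax (cmH~2~O) | <27 / 27–30 / >30 | <30 / 30–33 / >33 |

Printed dash-ranges such as "47–66" are read as closed intervals
`[47, 66]`, with "<47" as `(−∞, 47)` and ">66" as `(66, ∞)` (the
`"closed"` boundary convention).  Published tables rarely state
boundary membership, so the convention is stored in the definition
file and an `"open"` alternative (boundary values assigned to the
lower-points band) is available.  Ages are banded as given; whether a
study rounded age to whole years first is typically unknowable, and
both behaviours are representable through the convention.

One published wrinkle is reproduced rather than corrected: stratum
tables for the *original* score sometimes print the Pmax bands as
<27 / 27–30 / >33, leaving 30–33 cmH~2~O unassigned — and indeed the
shipped worked-example tables (`apps_published_strata()`) have Pmax
strata summing to 415 of 439 patients.  Score bands must be
exhaustive, so the built-in `"original_printed"` variant absorbs the
gap into the middle band (`[27, 33]`), keeping the outer bands as
tabulated; the as-printed counts are shipped verbatim in the CSV.

## The synthetic cohort generator

No patient-level data accompany published validation studies, so every
pipeline stage is exercised on seeded synthetic cohorts
(`cohort_spec()` / `generate_cohort()`).  The generator emulates the
*study conditions*, not any particular patient:

* **Predictor marginals.**  Independent truncated normals: age pooled
  from the per-outcome-arm moments 58.5 ± 15.4 (survivors) and
  63.1 ± 12.7 y (non-survivors), weighted by the 43 % mortality
  anchor; P/F 127 ± 40 mmHg; Pmax 27 ± 8.5 cmH~2~O.  Truncation
  bounds are the Berlin moderate/severe entry criterion and
  physiological plausibility: age 18–100 y, P/F 30–200 mmHg,
  Pmax 10–50 cmH~2~O.  Independence is the simplest mechanism that
  reproduces stratum margins; mortality is induced *only through the
  score*.
* **Mortality mechanism.**  Logistic:
  `logit P(death) = a + b_age[age_pts] + b_pf[pf_pts] + b_pmax[pmax_pts]`.
  The simple form (`mortality_model(a, slope)`) uses `b_v[c] = slope·c`,
  collapsing to `a + slope·S`.  The default slope is 0.4 per point
  (odds ratio ≈ 1.5/point, the magnitude of the published per-category
  odds ratios); the intercept is solved so expected mortality equals
  the 43 % target, exactly, via the 27-cell band-occupancy expansion.
* **Follow-up.**  Deaths occur uniformly on `(0, horizon]` (default
  60 days); survivors are censored at a log-normal discharge time
  (median 15 days, σ~log~ = 0.5) capped at the horizon.  This supports
  Kaplan–Meier analysis and is a modelling convention, not a claim
  about any study's follow-up.
* **Comparators.**  APACHE IV (85.5 ± 27 vs 102.7 ± 30.7 by arm), PEEP
  and FiO~2~ are drawn conditional on the simulated outcome so the
  comparator AUC and the sensitivity filter (PEEP ≥ 10 cmH~2~O,
  FiO~2~ ≥ 50 %) behave realistically; they feed back into nothing.
* **Determinism.**  One seed controls everything; the draw order (age,
  P/F, Pmax, death uniform, death time, discharge time, APACHE, PEEP,
  FiO~2~, each as a full vector) is fixed and documented in
  `generate_cohort()`, so a spec file reproduces a cohort
  byte-for-byte.

What the generator does *not* emulate: correlation between predictors,
correlation between APACHE IV and the score's components beyond the
outcome arm, cause-of-ARDS structure, or time-varying physiology.
Passing tests therefore demonstrate the *statistical machinery* on
cohorts with the study's margins — not that the score performs any
particular way on real patients.

## Calibrating the generator to published stratum rates

`calibrate_spec_to_margins()` finds a mechanism whose large-sample
stratum death rates match given per-band triples.  Under independent
predictors the rate in band `c` of variable `v` is an *exact*
probability-weighted average of `plogis` over the other two variables'
nine band cells, so the search needs no simulation: a shared intercept
plus per-band offsets (reference band = 0) is fitted by least squares
on these analytic rates.  A single targeted variable is solved in
closed form; all-three-variables is a 7-parameter fit to 9 targets.

The per-band offsets exist because published rate triples are generally
*not* linear in the band index on the log-odds scale — a linear
per-point slope cannot pass within 3 percentage points of the
published age triple (0.264, 0.439, 0.480), while offsets solve it
exactly.

A structural caveat the function enforces: with the predictor
marginals fixed, each variable's triple, weighted by its band
occupancies, implies an overall mortality, and all targeted variables
must imply the *same* one.  The three published triples jointly imply
0.42 (age), 0.48 (P/F) and 0.40 (Pmax) under the baseline marginals —
the published P/F band sizes put 54 % of patients above 158 mmHg,
which no N(127, 40) marginal can do (plausibly because scoring used
P/F measured 24 h after diagnosis rather than the baseline value).
Joint 9-target calibration therefore raises an explicit infeasibility
error; worked examples calibrate the age and Pmax triples (best fit
within 1.6 percentage points, simulated rates within ±3).

## Calibration assessment: what "expected" means

Hosmer–Lemeshow needs expected probabilities, and an integer score has
none by itself.  The package fits a univariate logistic regression of
death on the score to the *same cohort* and takes
`E_g = n_g · plogis(â + b̂·s_g)` per score level; the statistic is
`Σ (O−E)²/(E(1−E/n))` with `df = groups − 2` (two fitted parameters)
and an upper-tail chi-square p.  This choice is the single most
consequential convention in the calibration module — any other
expected-probability model changes the statistic — so it is stated in
the result object, and a deciles-of-risk grouping is available as an
option.  Score-level grouping is the default because per-score
calibration bars are what validation studies plot.  With only two
score levels the fit is saturated (statistic 0); the result is flagged
and p set to 1.  Complete separation aborts with a diagnostic rather
than returning a meaningless fit.

Under the generator's own logistic mechanism this test should reject
at its nominal rate; the acceptance suite verifies an empirical type-I
error within 0.05 ± 0.02 over 500 cohorts of n = 10⁴, and ≥80 % power
at n = 439 against an injected gross non-monotone disturbance (death
probability at scores 4–5 raised by 0.45·(1−p), pushing those levels
above score 6 — the kind of kink that yields highly significant
miscalibration at cohort sizes of a few hundred).

## Recalibration: objective design

`recalibrate()` automates the manual cutoff-moving step: for each
tuned variable (default age and Pmax; P/F is left alone by default) it
evaluates every ordered cutoff pair on a 1-unit grid (5 mmHg for P/F)
between the empirical 5th and 95th percentiles, plus the current pair.
Pairs are *feasible* if every band holds ≥5 % of the cohort and
stratum mortality is non-decreasing in points.

Selection is deliberately **not** "maximise the Hosmer–Lemeshow p".
Once calibration is adequate, the HL p-value is approximately uniform,
so its argmax over a 1000-pair grid is sampling noise and carries no
information about where the bands should sit — in simulation it lands
anywhere from 40/51 to 62/83 when the data were generated from bands
at 47/59.  Instead selection is lexicographic:

1. *adequacy*: HL p at least 0.05 (`alpha_cal`) **and** no lower than
   the starting pair's, so the returned definition is never worse
   calibrated than its base (if nothing clears the bar, the best
   available HL p — which includes the starting pair — is taken);
2. *discrimination*: maximise the AUC of the resulting total score,
   which peaks where the bands carry the mortality signal;
3. *parsimony*: ties go to the cutoffs closest (L1) to the start.

With this rule, cohorts of n = 10⁴ generated from bands at 47/59 with
a strong per-point effect (slope 0.9, OR ≈ 2.5/point) return the
planted cutoffs within one grid step in the large majority of seeds,
and starting *from* the generating definition returns it unchanged.
When several variables are tuned they are searched sequentially in the
order given — a joint grid over two variables (~10⁶ pairs) adds cost
but no benefit for three-band scores — and because each pass includes
its current pair, the HL p can only improve across passes.

## Discrimination conventions

Candidate cutoffs are the midpoints between adjacent distinct score
values; "positive" means score *strictly above* the cutoff, so the
integer-score cutoff 5.5 calls scores ≥6 positive — the only reading
consistent with midpoint cutoffs on an integer score.  Youden ties
break toward the lower cutoff.  Concordance uses half-credit for tied
scores (the Mann–Whitney identity underlying the DeLong variance).
The DeLong interval is computed on the probability scale and clipped
to [0, 1] — published intervals are printed as plain bounds — with a
stratified bootstrap percentile interval as an alternative.  Paired
score comparison uses the DeLong covariance of placement values; two
scores that rank patients identically have difference and variance
both zero, and p is 1 by convention.

## Survival conventions

Kaplan–Meier curves use the product-limit estimator with the standard
events-before-censorings convention at tied times, time measured in
days from diagnosis, censoring at discharge.  Score categories 3–4 /
5–7 / 8–9 are the original grouping; 3 / 4–7 / 8–9 is the regrouping
under which survival separates after recalibration.  Category edges
must partition {3, …, 9}; empty categories are kept and flagged.  The
log-rank test is the standard unweighted chi-square with
`df = strata − 1`.  Estimation is delegated to the `survival` package;
the test suite pins it against hand-computed product-limit values on a
mixed-ties fixture and against label-permutation oracles.

## Numerical and degenerate-input choices

* Stratum counts are reconstructed from published (N, mortality %)
  pairs with half-away-from-zero rounding — the convention that
  reproduces every checkable published odds ratio, where banker's
  rounding does not.
* Odds ratios with any zero cell use the Haldane–Anscombe +0.5
  correction and are flagged rather than silently corrected.
* The trend test is a binomial-GLM Wald test on the band index coded
  1, 2, 3 (Cochran–Armitage available); published "P for trend" values
  are treated as order-of-magnitude checks since the test used is
  never stated.
* FiO~2~ units (percent vs fraction) must be declared for the
  sensitivity filter; the package refuses to guess.
* All-tied scores, one-class outcomes, empty strata and empty
  sensitivity subsets degrade gracefully with flags or documented
  failure entries rather than errors, except where a number would be
  meaningless (single-class AUC, zero-subject log-rank stratum).

## Problem sizes

The test and acceptance suites size their simulations to be decisive
yet quick on a single CPU: marginal checks at n = 10⁵ (binomial SE
≈ 0.15 percentage points per stratum), mechanism-recovery and
recalibration experiments at n = 10⁴, HL null calibration over 500
cohorts of n = 10⁴, power checks at the study-scale n = 439 (200
replicates) and n = 500–2000 where a larger signal is needed.  The
whole suite runs in about a minute.

## Known limitations

* The AUCs, DeLong comparison p, HL p-values and log-rank p published
  for the real cohort are not reproducible without the patient-level
  data; the package validates its machinery against oracles and
  simulation instead, and reproduces every quantity that *is*
  derivable from printed tables (odds ratios, intervals, trend orders
  of magnitude, likelihood ratios, overall mortality).
* Score-level Hosmer–Lemeshow behaviour depends on the expected-
  probability model; conclusions about "good" or "poor" calibration
  transfer across software only when that model matches.
* The recalibration search moves cutoffs only; re-estimating the
  1/2/3 point weights is out of scope by design.
* Synthetic cohorts carry independent predictors; any analysis
  sensitive to predictor correlation will behave differently on real
  data.
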