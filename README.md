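# appsval

External validation toolkit for the **APPS**, a 3–9 point prognostic
score for hospital mortality in moderate or severe ARDS
(PaO₂/FiO₂ ≤ 200 mmHg). The score sums 1–3 points each for **A**ge,
**P**aO₂/FiO₂ ratio and airway **P**ressure (maximal airway pressure
standing in for plateau pressure under pressure-controlled
ventilation):

| points | age (y) | PaO₂/FiO₂ (mmHg) | Pmax (cmH₂O) |
|---|---|---|---|
| 1 | <47 | >158 | <27 |
| 2 | 47–66 | 105–158 | 27–30 |
| 3 | >66 | <105 | >30 |

plus a *recalibrated* cutoff set (age 47–59/>59, Pmax 30–33/>33) that
repairs calibration in cohorts where the original banding is off.

The package is for biostatisticians validating such a score on a new
cohort. It implements the full pipeline as reusable pieces:

* **score engine** — general cutoff-table scores; both cutoff sets as
  built-ins (`builtin_definition()`), YAML serialization, configurable
  boundary conventions;
* **discrimination** — AUC as tie-corrected concordance with DeLong
  (or bootstrap) 95 % CI, paired DeLong comparison against a
  competitor score, Youden-optimal cutoff with sensitivity,
  specificity, LR+ and LR− (`roc_analysis()`, `compare_auc_paired()`);
* **calibration & recalibration** — score-level Hosmer–Lemeshow
  against a logistic expected-probability model, and an automated
  cutoff-grid recalibration with explicit feasibility constraints
  (`calibration_table()`, `recalibrate()`);
* **association** — per-category stratum tables, count reconstruction
  from published (N, mortality %) rows, Wald odds-ratio intervals and
  a trend test (`stratify_cohort()`, `reconstruct_counts()`,
  `odds_ratio()`, `trend_test()`);
* **survival** — Kaplan–Meier curves and log-rank test across score
  categories (`km_by_category()`);
* **synthetic cohorts** — seeded generator whose marginals and stratum
  mortalities emulate the published validation cohort, with a
  calibration search that hits target stratum death rates analytically
  (`cohort_spec()`, `generate_cohort()`,
  `calibrate_spec_to_margins()`);
* **cohort I/O and reporting** — validated CSV round-trip, the
  PEEP ≥ 10 / FiO₂ ≥ 50 % sensitivity subset, an assembled report
  (`run_validation()`, `report_json()`), and a command-line tool
  (`inst/cli/appsval.R`: `simulate`, `score`, `validate`,
  `recalibrate`).

## Worked example

Simulate a 439-patient cohort whose age and Pmax stratum mortalities
match the published tables, then run the full validation:

```r
library(appsval)

targets <- published_margin_targets("original")[c("age", "pmax")]
spec    <- calibrate_spec_to_margins(targets,
             cohort_spec(n_patients = 439, seed = 11))
cohort  <- generate_cohort(spec)
report  <- run_validation(cohort, seed = 11)
print(report)
```

```
APPS validation report: n = 439, deaths = 175 (40%)

== Definition: original ==
ROC: AUC 0.63 (95% CI 0.57-0.68, delong)
Youden cutoff 6.5: sens 0.49, spec 0.69, LR+ 1.60, LR- 0.73
vs APACHE IV: AUC 0.63 vs 0.64, DeLong p = 0.695
Hosmer-Lemeshow (score groups): chi-square 4.399, df 5, p 0.4936
 score   n observed expected observed_pct expected_pct
     3   9        1      1.5         11.1         16.5
     4  28        8      6.3         28.6         22.4
     ...
Stratum table: age   (P for trend = 0.0009175)
 range category   n deaths mortality_pct flagged   or or_lo or_hi
   <47        1  71     15          21.1   FALSE 1.00    NA    NA
 47-66        2 225     93          41.3   FALSE 2.63   1.4  4.93
   >66        3 143     67          46.9   FALSE 3.29   1.7  6.35
 ...
Log-rank: chi-square 1.537, df 2, p 0.4637
```

Reading it: the cohort's mortality (40 %) and age-stratum gradient
(21 → 41 → 47 %, OR 2.63 and 3.29 against the youngest band, trend
p < 0.001) mirror the published margins it was calibrated to; the
score discriminates moderately (AUC 0.63, indistinguishable from the
simulated APACHE IV comparator) and is well calibrated here
(HL p 0.49), as expected for a cohort generated from a logistic
mechanism on the score itself.

Worked examples against the *published* tables need no simulation:

```r
o <- odds_ratio(reconstruct_counts(196, 43.9),   # age 47-66
                reconstruct_counts(72, 26.4))    # age <47 (reference)
round(c(o$point, o$lower, o$upper), 2)
#> [1] 2.18 1.20 3.95

unlist(likelihood_ratios(sens = 0.63, spec = 0.56))
#>   lr_pos   lr_neg
#> 1.431818 0.6607143
```

## Further reading

The methods vignette (`vignettes/apps-validation.Rmd`) documents the
models and conventions in detail: the synthetic generator's draw order
and truncation bounds, why stratum-rate calibration is solved
analytically (and when it is infeasible), the expected-probability
model behind the Hosmer–Lemeshow test, the recalibration objective,
boundary conventions, and known limitations.
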