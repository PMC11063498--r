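# ipreface

Intrapartum fetal-acidemia scoring from cardiotocography (CTG)
decelerations, with the diagnostic-accuracy machinery to evaluate the score
and a seeded synthetic labor-cohort generator so the whole pipeline runs
without patient data.

## Who this is for

Perinatal researchers and biostatisticians who want to (re)implement,
stress-test, or extend deceleration-accumulation scoring of intrapartum
CTG: the score itself, the five-tier (JSOG) level table it depends on, and
the ROC/cutoff/group-comparison analysis used to judge it against
umbilical-artery blood-gas outcomes.

## The score

A tracing's decelerations are graded 1–5 by the five-tier fetal heart-rate
classification (level 1 normal … level 5 severe; levels 3–5 =
non-reassuring fetal status). Over a 30-minute CTG window ending at a
clinical anchor, the iPREFACE score is

```
score = Σ level(d)                        over non-prolonged decelerations d
      + Σ level(p) × round(minutes(p))    over prolonged decelerations p
```

with prolonged = lasting ≥ 2 min, and minutes rounded half-up. Two
anchors: **DCS** (window ends at the decision for emergency cesarean) and
**RCT** (window ends at CTG transducer removal). The score is evaluated
against fetal acidemia, umbilical-artery pH < 7.2 (secondary thresholds
7.1, 7.0), via ROC curves, DeLong confidence intervals, and the Youden
index J = sensitivity + specificity − 1 for cutoff selection.

## Worked example

```r
library(ipreface)

cohort <- generate_cohort(synthetic_config(n_cases = 113, seed = 7))
cohort
#> Synthetic labor cohort: 113 cases, 1413 decelerations, pH<7.2 in 10 (8.8%)

events <- classify_level(cohort$events)           # five-tier levels from the shipped table
report <- run_full_analysis(run_config(), cohort$cases, events)
report
#> ipreface report: 113 cases, outcome pH < 7.2
#>   DCS: AUC 0.925 (95% CI 0.797-1.000), Youden cutoff 21 (sens 0.90, spec 0.93)
#>   RCT: AUC 0.958 (95% CI 0.914-1.000), Youden cutoff 17 (sens 1.00, spec 0.83)
```

The generator's deceleration burden drives a respiratory-then-metabolic
acidosis, so the window nearer delivery (RCT) discriminates better than the
earlier one (DCS) — the ordering the score is designed around. The
cutoff-stratified comparison shows the acid-base contrast between groups:

```r
cmp <- report$group_comparison
cmp[cmp$variable %in% c("ph", "be", "lactate", "ph_lt_7.2"), ]
#>   variable group_score_ge_17 group_score_lt_17           test      p_value
#>         ph  7.23 (6.99–7.39)   7.3 (7.21–7.43) Mann-Whitney U 9.110826e-08
#>         be          -4.5±2.3          -2.6±1.7 t test (Welch) 3.539669e-04
#>    lactate           3.9±1.7           3.1±1.3 t test (Welch) 1.967037e-02
#>  ph_lt_7.2      35.7 (10/28)        0.0 (0/85)   Fisher exact 2.113611e-07
```

High scorers sit lower on pH and base excess (BE) and higher on lactate —
mixed respiratory/metabolic acidemia — and carry essentially all the
pH < 7.2 outcomes. The study-design helper reproduces the classic AUC
sample-size arithmetic:

```r
auc_sample_size(auc_alt = 0.80, power = 0.90, alpha_one_sided = 0.05,
                ratio_neg_per_pos = 9)
#> $n_pos   [1] 8
#> $n_neg   [1] 72
#> $n_total [1] 80
```

i.e. detecting AUC 0.80 against 0.5 with 90% power at one-sided α = 0.05
under a 1:9 positive:negative allocation needs ≈ 8 positives and 72
negatives, 80 participants in total.

See `vignettes/ipreface-methods.Rmd` for the model, every scoring
convention, the generator's mechanism and calibration, and known
limitations.

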