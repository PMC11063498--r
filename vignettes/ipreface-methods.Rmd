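---
title: "Scoring intrapartum decelerations and evaluating the score: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring intrapartum decelerations and evaluating the score: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipreface)
```

## The problem and the score

Cardiotocography (CTG) during labor records the fetal heart rate (FHR) and
uterine activity. Guideline systems grade a tracing into risk tiers — in the
five-tier scheme used here, level 1 (normal) through level 5 (severe
abnormality), integrating baseline rate, baseline variability and the
deceleration pattern; levels 3–5 define non-reassuring fetal status (NRFS).
Single-waveform grading, however, predicts umbilical-artery acidemia poorly:
what injures the fetus is the *accumulation* of repeated decelerations, not
any one of them.

The iPREFACE score quantifies that accumulation over a 30-minute CTG window:

* each non-prolonged deceleration contributes its five-tier level;
* each prolonged deceleration (a fall lasting ≥ 2 minutes) contributes its
  level × its duration rounded to the nearest whole minute.

Two anchors matter clinically for an emergency cesarean: the **DCS** variant
scores the 30 minutes ending at the *decision* for surgery, the **RCT**
variant the 30 minutes ending at *removal of the CTG transducer* (the last
recorded signal before delivery). The RCT window sits closer to birth and
should therefore track the neonate's acid-base state more closely.

The outcome against which the score is evaluated is fetal acidemia,
umbilical-artery pH < 7.2, with 7.1 and 7.0 as severity thresholds.

## The five-tier table as data

The five-tier chart is published as a figure, not a formula, and local
dialects differ. We therefore ship the level assignment as *data*
(`default_rule_table()`, editable and file-loadable via
`read_rule_table()`): one level per combination of baseline-rate category,
variability category, deceleration type, and severity. The default table is
an additive transcription — risk points for the deceleration pattern (early
or mild variable +1; severe variable, mild late, mild prolonged +2; severe
late, severe prolonged +3), degraded variability (minimal or marked +1,
absent +3), abnormal baseline (tachycardia +1, bradycardia +2) — clamped to
1–5. This construction guarantees the properties any transcription must
have: a normal tracing maps to level 1, severity never lowers a level, and
absent variability never scores below moderate. Individual cells of a
published chart may differ from this reconstruction by one level; every
downstream computation is table-agnostic, and clinician-annotated levels
(`level_override`) take precedence over any table.

We assign one level per deceleration (not one per 30-minute epoch): the
score's definition sums "the levels for all detected decelerations", which
reads most naturally as per-event grading, and it is what makes the score an
accumulation measure.

## Scoring conventions

Several choices the score's verbal definition leaves open are fixed here,
explicitly and configurably:

* **Time base.** Seconds from recording start; windows are half-open
  `(end − 1800, end]`. A finer base than minutes avoids rounding ambiguity
  before the one place rounding is defined: the whole-minute duration of a
  prolonged deceleration.
* **Rounding.** "Nearest whole minute" is round-half-up: 4.5 min → 5.
  An in-window overlap under 30 s rounds to zero and contributes nothing.
* **Window membership.** A non-prolonged deceleration belongs to the window
  containing its nadir (onset + duration/2 when the nadir is not
  annotated). A prolonged deceleration contributes only its in-window
  overlap, so adjacent windows never double-count minutes.
* **Degenerate events.** A "prolonged" fall of ≥ 10 minutes is a baseline
  change, not a deceleration: it is flagged at validation and excluded from
  scoring with a warning. A prolonged event without a level is an error —
  defaulting a level would silently bias the score.
* **Coverage.** By default a window must be fully recorded
  (`strict_coverage = TRUE`), mirroring the exclusion of tracings that
  cannot be read continuously for 30 minutes; exploratory trajectories may
  relax this with a logged warning.

## Diagnostic evaluation

`roc_analysis()` builds the empirical ROC from every distinct score
threshold (positivity: score ≥ threshold). Its trapezoidal area equals the
Mann–Whitney probability with ties counted ½ — the suite verifies the
identity against an O(n²) pair-counting oracle. The AUC confidence interval
uses the DeLong placement-value variance with a normal approximation
clipped to [0, 1]; the method label travels in the report. We chose DeLong
because it is assumption-light and standard; with ~11 positives the normal
approximation undercovers, the more so the higher the true AUC — the
suite's coverage simulation at n = 113, prevalence 0.1 measures about 93%
at true AUC 0.70 and about 87% at 0.85 against the nominal 95%, matching
the independent pROC implementation exactly. Intervals around strong
discrimination estimated from few positives should be read with that
deficit in mind.

`youden_cutoff()` maximizes J = sensitivity + specificity − 1 over observed
score values and breaks ties toward the *smallest* cutoff — the
sensitivity-favoring choice, appropriate when the score's purpose is not to
miss an acidemic fetus. All six metrics (sensitivity, specificity, PPV,
NPV, FPR, FNR) are reported explicitly labeled.

Group comparisons (`compare_groups()`) follow a documented selection rule
the source tables name only by test: continuous variables pass a
Shapiro–Wilk screen in every group (α = 0.05, configurable) and use the
Welch t test / one-way ANOVA when it passes, the Mann–Whitney U /
Kruskal–Wallis test otherwise; proportions use Pearson's chi-square unless
any expected cell is below 5, then the Fisher exact test. P-values are
two-sided and raw: descriptive clinical tables of this kind apply no
multiplicity correction, and neither do we — the documentation says so
rather than hiding it.

`auc_sample_size()` solves the Hanley–McNeil one-sample power equation
(Q1 = A/(2−A), Q2 = 2A²/(1+A)) for the continuous number of positives,
rounds to the *nearest* integer, and scales by the negative:positive
allocation ratio. Nearest-integer rounding (not ceiling) is what reproduces
the "approximately 8 / 72 / 80" arithmetic of the standard 0.80-AUC,
0.90-power, one-sided-5%, 1:9 design. The one-sided α here is the single
deliberate departure from the two-sided convention used everywhere else,
because the design question ("is the AUC above 0.5?") is one-sided.

## The synthetic cohort generator

No patient-level data accompany the score's published evaluation, so the
package ships a generator (`synthetic_config()` / `generate_cohort()`)
whose *mechanism* is the clinical narrative made quantitative: repeated
decelerations cause hypoxemia and respiratory acidosis, and their continued
repetition gradually adds metabolic acidosis.

Per case:

1. a latent severity class (low / mid / high burden) is drawn;
2. a timeline is drawn — decision-to-delivery log-normal with median 69 min
   (truncated 20–242 min), removal-to-delivery a Beta-distributed fraction
   of it (median ≈ 45 min), at least 30 min of recording before the
   decision so the DCS window always exists; the recording ends at
   transducer removal, since no CTG exists after the transducer is off;
3. decelerations arrive as an inhomogeneous Poisson stream whose intensity
   rises linearly toward delivery (rate doubling over the recording by
   default; class rates 2.5 / 3.2 / 7 events per 30 min), with
   class-conditional mixes of type, severity, variability and baseline
   context; levels come from the shipped table, so the whole pipeline is
   exercised;
4. the cumulative burden `B_total` (score contribution over the whole
   recording) and recent burden `B_recent` (last 30 recorded minutes)
   drive the blood gas:
   PCO₂ = 45 + 0.4·`B_recent` + noise (respiratory component),
   target BE = −1 − 0.06·`B_total` + noise (metabolic component);
   pH then solves the Van Slyke base-excess relation
   BE = 0.02786·PCO₂·10^(pH−6.1) + 13.77·pH − 124.58, and bicarbonate
   follows from Henderson–Hasselbalch, HCO₃⁻ = 0.03·PCO₂·10^(pH−6.1), so
   every panel satisfies pH = 6.1 + log₁₀(HCO₃⁻/(0.03·PCO₂)) by
   construction;
5. lactate rises in −BE; Apgar scores and NICU admission are thresholded
   on pH with noise — the pH↔Apgar coupling strength has no empirical
   anchor and is documented as arbitrary and configurable.

The gains and class mixes were calibrated once so that the class means
resemble the anchors a cohort of this kind prints — a low-burden case near
pH 7.30 / PCO₂ 50 / BE −2.6, a high-burden case near pH 7.07 / PCO₂ 69 /
BE −9.0 — and frozen. The class mix is then *solved*, not tuned: given the
frozen per-class acidemia rates (0.019 / 0.138 / 0.918) the high-class
share is the root of the mixture equation at the requested
`target_prevalence` (default 0.10); an unreachable prevalence is a
generation error, reported as such.

Randomness policy: one integer seed; each case uses a deterministic
substream derived from (seed, case index), so cohorts are bit-reproducible
and the first *k* cases are invariant when `n_cases` grows. All noise is
drawn *before* the gain coupling is applied, which makes the
monotone-mechanism property (higher gains never raise pH, same seed) a
deterministic fact rather than a statistical one.

**What the generator does and does not emulate.** It reproduces the
statistical skeleton the evaluation needs — burden-driven mixed acidosis,
realistic timelines, ~10% prevalence, stronger discrimination for the
RCT than the DCS window (because burden accrues between decision and
removal). It does **not** model fetal cardiovascular physiology, real
inter-annotator noise in level assignment, covariate correlations beyond
the anchored marginals, or recording artifacts. Tests passing on synthetic
cohorts therefore validate the *software* and the *statistical pipeline*,
not the clinical performance of the score on real tracings.

The signal layer (`render_trace()` at 4 Hz, `detect_decelerations()`)
closes the loop at trace level: rendered dips are trapezoids (abrupt 5 s
ramps for variable decelerations, gradual 20 s ramps for early/late), the
detector uses the standard criteria (≥ 15 bpm below a 10-minute running
median for ≥ 15 s; prolonged at ≥ 2 min; late vs variable by nadir lag
behind the contraction peak, early by gradual descent). The running-median
baseline is robust to decelerations occupying less than half its window;
very long prolonged decelerations approach that limit, which is a
documented detector limitation.

## Problem sizes and numerical choices

The suite's simulation sizes are chosen to estimate each property with
useful precision at interactive cost: 100 cohorts of n = 113 for prevalence
and AUC recovery (binomial/sampling SEs ≈ 0.003 and 0.005 on the respective
means), 1000 replicates for type-I error and DeLong coverage (SE ≈ 0.7
percentage points), one n = 5000 cohort as the discrimination reference,
and the exhaustive Fisher sweep over all 135,750 tables with N ≤ 40. The
cutoff-recovery check uses binomial score distributions
(positives ~ Bin(90, 0.55), negatives ~ Bin(90, 0.35), n = 800) because
their Youden optimum is analytically known and sharply identified; very
strong separation would flatten the J curve across the class gap and make
"±1 score unit" meaningless rather than harder.

Ties in the Youden maximizer break to the smallest cutoff; ROC thresholds
carry ±∞ sentinels; the Fisher two-sided p sums hypergeometric point
probabilities ≤ the observed one (with the customary 1 + 10⁻⁷ relative
guard for floating-point ties); uniroot tolerances are 10⁻¹⁰. Empty windows
score 0; an empty events table is valid everywhere.

## Known limitations

* The default five-tier table is a reconstruction; users with the official
  chart should load it as data and revalidate.
* DeLong intervals at ~11 positives run measurably below nominal coverage
  (≈87–93% against 95%, depending on the true AUC).
* The generator's Apgar/NICU couplings are placeholders with sensible
  signs, not fitted quantities.
* `compare_groups()` screens normality per variable; with many variables
  the screen itself is multiple testing, which we accept as the cost of a
  reproducible, documented rule.
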