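---
title: "Methods: responder analysis, dual prediction levels, and the synthetic GORD cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: responder analysis, dual prediction levels, and the synthetic GORD cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refluxr)
```

`refluxr` analyses symptomatic response to acid-suppressive therapy in
gastro-oesophageal reflux disease (GORD) from daily patient-reported
scores. This vignette is the package's account of the underlying models,
the choices that were genuinely open, and what the synthetic cohort can
and cannot show.

## Instruments and scoring

The ReQuest™ short form assesses seven symptom dimensions, each by a
0–100 mm intensity VAS and (except general well-being) a 7-point (0–6)
frequency Likert item. The dimensions group into the GI sub-scale (acid,
upper abdominal, lower abdominal, nausea; range 0–30.77) and the WSO
sub-scale (well-being, sleep, other; range 0–15.51); the total spans
0–46.28. The proprietary item-to-score algorithm is not public, so
`score_request_day()` uses a documented stand-in: each dimension
contributes `weight × (intensity/100) × (frequency/6)` (well-being:
`weight × intensity/100`), with each sub-scale maximum split equally
across its dimensions by default. The stand-in preserves the published
ranges exactly — the all-maximal response attains 30.77 / 15.51 / 46.28
and nothing below it does — and is monotone in every item. The weights
are configurable; the simulator bypasses the item level and emits
dimension-aggregated scores directly.

HADS is scored conventionally: two 7-item subscales (0–21), items 0–3,
bands normal 0–7, suggestive 8–10, probable ≥11; the default
item-to-subscale map alternates items (odd → anxiety), and is
configurable because instrument layouts differ between printings.
GERDyzer™ (10 quality-of-life VAS dimensions, higher = worse) is
aggregated by the mean, which keeps the 0–100 interpretation; the
alternative (sum) is a linear rescaling and changes no comparison.

## Responder rule

A patient responds when the daily GI score is below 1.6 on 3 consecutive
calendar days (`responder_rule()`: threshold 1.6, run length 3, strict
`<`). Decisions that the rule's verbal form leaves open:

- **Day 0 never counts.** It is the pre-treatment day; runs live in days
  1 … horizon.
- **"Response at Week 4/8"** means the qualifying run *completes on or
  before* day 28/56, matching the cumulative phrasing of rising response
  rates — not a symptom state at the visit itself.
- **Missing days break runs** (conservative default): a run is three
  consecutive *calendar* days each with a qualifying observed score. A
  `skip_missing` variant that collapses missing days out of the calendar
  is available but not used by the pipeline.
- **Strictness.** "Below 1.6" is read as `<`. The prediction-level
  search independently uses `≤` for its predicted-response groups; the
  two rules are deliberately separate configuration points.

Patients who stop recording are classified on their available days; runs
cannot occur after the last observed day. The classifier is tested
against a brute-force enumeration of every 3-day window on 1000 random
series, and satisfies the monotonicity properties one would demand of
such a rule (in horizon, in threshold, and under lowering any single
day's score).

## Dual prediction levels

For a candidate day and score kind, levels run from 0 to the score
maximum in steps of 0.01. Level arithmetic uses integer grid indices
(`level = k × step`) with a `step × 1e-6` comparison tolerance so that
boundary scores land deterministically. For each level, the
predicted-response group is `score ≤ level` and its prediction rate the
observed week-8 responder share; symmetrically above for non-response.
Empty groups yield `NA` rates, never fabricated values.

The optimal response level maximises the response prediction rate, the
non-response level the non-response rate — but this is degenerate
without a support constraint (a single extreme patient trivially attains
rate 1), so `optimize_day()` requires at least `min_group` patients in a
predicted group. The default of 30 is a conventional stability floor,
configurable and reported. Tie-breaks: the *largest* qualifying response
level (maximises how many patients get a prediction) and the *smallest*
qualifying non-response level. If the two levels cross (possible only
when an empty score gap separates the classes perfectly), the day is
flagged rather than reported with an inverted grey zone. The best day
among days 1–10 minimises the indeterminate width `U − L`, ties going to
the earliest day; day 0 is always reported separately as the baseline
prediction. The optimiser is tested against an exhaustive level-grid
search on cohorts up to 200 patients.

## Logistic factor screening

`fit_logistic()` wraps maximum-likelihood logistic regression (IRLS via
`stats::glm`, deviance tolerance 1e-10) with Wald standard errors and
p-values. Coding follows the trial's reporting conventions: NERD, female,
Western Europe, *H. pylori*-negative and IBS-"no" are reference levels;
BMI, age and HADS scores enter untransformed (per-unit odds ratios).
*H. pylori* "intermediate" is kept as its own level and "missing" dropped
(complete case, with the dropped count reported); IBS "I do not know" is
kept as a genuine third level. Oesophagitis grade is fitted within the
ERD subgroup only, since the grade is undefined for NERD. The global
multivariate model enters ERD/NERD only by presence and HADS only as the
total score. Complete separation and non-convergence are flagged, never
silently estimated. No multiplicity adjustment is applied — the p-values
are explorative, and the report says so. The machinery is validated
against the closed-form 2×2 log odds ratio and its standard error
(`sqrt(1/a + 1/b + 1/c + 1/d)`) to 1e-6, by a parameter-recovery harness
(coefficient coverage of 2-SE intervals across 50 simulated cohorts),
and by its Wald type-I error under the null (nominal 0.05, accepted
within [0.03, 0.07] over 200 replicates).

## The synthetic cohort

No patient-level data from the motivating trial are public, so the
package ships a generator whose defaults *are* the study conditions.

**Covariates.** Gender, geography, smoking, *H. pylori* and
oesophagitis category are drawn from the published marginals of the
1888-patient cohort; age ~ N(47.0, 14.3²) years (truncated at 18),
BMI ~ N(26.4, 4.8²) kg/m². Three covariates differ by gender in a way
that preserves the marginals exactly: NERD prevalence (female +0.30
against male, matching the higher NERD share in women), IBS-symptom
prevalence (+0.18) and baseline HADS anxiety (+1.6 points). These
deltas, with a small direct male effect (+0.10 logit), reproduce the
trial's signature pattern: gender is clearly significant univariately
yet non-significant in the multivariate model, because the signal is
carried by confounding.

**Latent response.** Each patient's responder propensity is
`logit⁻¹(β·x)` with the packaged coefficients (+0.55 for ERD, −0.045 per
HADS total point, −0.45 for IBS, +0.15 per BMI standard deviation,
geography contrasts ordered South Africa > Western Europe ≈ South
America ≈ Canada > Australia ≈ Asia, age and *H. pylori* zero). Age and
*H. pylori* are deliberately null so the pipeline's "no effect found"
results are testable as true negatives.

**Trajectories.** The daily GI score follows
`s(t) = b·(f + (1−f)·e^(−t/τ)) + ε`, truncated to [0, 30.77]: `b` is the
baseline severity (gamma; responders mean 6.0, sd 3.2; non-responders
mean 8.8, sd 4.4), `f` the asymptote fraction (responders 0.04,
non-responders 0.5 — non-responders improve but plateau above the 1.6
threshold), `τ` the decay time constant (responders log-normal, median
9.2 days, σ 0.67; non-responders median 30 days, σ 0.3) and `ε` daily
Gaussian noise (sd 0.8 score points). WSO is a per-patient ratio of the
GI mean (0.504 × a log-normal factor, σ 0.25) with its own noise (sd
0.5), truncated to [0, 15.51]; the total is their sum wherever both are
present. Each post-baseline day is missing completely at random with
probability 0.03; day 0 is never missing. The exponential-decay form is
the simplest mechanism that links covariates to time-to-response; a
low-baseline tail of non-responders whose plateau sits below 1.6
provides a small, realistic false-positive rate for the run-rule
classifier.

**Calibration.** The intercept, the responder τ distribution and the
ERD coefficient were tuned by grid search over 20 seeds until the
simulated week-4, week-8 and ERD-subgroup week-8 response rates (under
the 1.6/3-day rule) matched 58.9%, 71.2% and 75.5% to within a fraction
of a point in expectation; they were then frozen. At n = 1888 a single
cohort's rate still carries binomial noise of roughly ±1 point (1 sd).

**Assessments.** Satisfaction ('very/fairly/not satisfied') and the
investigator's judgement ('well/fairly/not controlled') are drawn from
2×3 misclassification matrices conditioned on the *classifier* outcome
at the corresponding visit, with probabilities chosen to reproduce the
published discordances (≈14% of 'very satisfied' patients are
non-responders; ≈0.8% of responders 'not satisfied'; investigators
over-optimistic, with ≈21% of 'well-controlled' patients
non-responders). HADS follow-ups decline linearly by class (responders'
anxiety mean crosses into the normal band, below 7, by week 8;
non-responders' stays above); GERDyzer means start higher in
non-responders and fall further in responders.

**What the simulator does not emulate.** Within-patient day-to-day
autocorrelation beyond the smooth decay, informative dropout (missing
days are MCAR), item-level ReQuest or GERDyzer responses, adverse
events, and any endoscopy workflow. The separation between responder and
non-responder score distributions is cleaner than in real trial data, so
the in-sample prediction rates attained on simulated cohorts (often
near 100% at the optimum) exceed the published ones (≈87% / 70%); tests
of the prediction module therefore assert its *search semantics* against
exhaustive oracles and the published worked ratios from printed group
counts, not the simulator's in-sample rates. Passing tests demonstrate
the pipeline computes the published quantities correctly under the
published structure — not that the simulator is a substitute for the
trial's raw data.

## Problem sizes and reproducibility

All randomness flows from a single integer seed (`set.seed` at the top
of `generate_cohort()`), making cohorts bit-reproducible. The test suite
uses cohorts of 1888 (calibration, regression structure), 150–500
(pipeline, null-model simulations at 20 seeds) and toys of 3–200
(oracle equivalence, hand arithmetic); the parameter-recovery harness
uses 50 cohorts of 1888 and the type-I error check 200 replicates. The
analysis drivers under `analysis/` use one 1888-patient cohort at seed
20110511.

## Known limitations

- The ReQuest item-to-score stand-in is not the proprietary algorithm;
  only its range and monotonicity are guaranteed to match.
- The dual-level search is an in-sample procedure by design (no
  cross-validation or ROC machinery), reproducing the original method.
- Geography effects are qualitative contrasts reproducing the published
  ordering, not estimates of regional biology.
- `min_group = 30` is this package's explicit stand-in for an unstated
  support constraint in the original level search; results that depend
  on it flag the fact.
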