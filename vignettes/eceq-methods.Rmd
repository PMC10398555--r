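---
title: "Methods: screening-rule scoring, diagnostic validation and calibrated cohort simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening-rule scoring, diagnostic validation and calibrated cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eceq)
```

## The screening problem

Infantile atopic dermatitis (AD) — chronic, relapsing eczema in
children younger than 2 years — is common (around 30% in young Chinese
children) but frequently undiagnosed, because caregivers do not bring
mild skin findings to a doctor. A seven-item caregiver questionnaire
(the eCEQ) lets web-based surveys identify probable AD without a
clinician present. This package implements the instrument's scoring
rules and everything needed to validate and deploy them: accuracy
statistics against a reference diagnosis, sample-size planning,
survey-export cleaning, awareness reporting, and synthetic cohorts for
testing.

## Rules as data

The three boolean rules are AND/OR expressions over the question atoms
Q1–Q7; the fourth is a logistic risk score. We store rules as
expression trees (`{"q":n}`, `{"and":[...]}`, `{"or":[...]}`) rather
than hard-coded branches so that variants are first-class: they
round-trip through JSON, can be parsed from the field's notation
(`parse_rule("(Q2&(Q4|(Q1&Q3))&Q6)|Q7")`), and validate their
structure at construction time — an atom outside 1..7 fails when the
rule is built, never during evaluation. Because the built-in rules use
only AND/OR (no negation) and the logistic coefficients are all
positive, classification is monotone: switching any answer from no to
yes can never turn a positive into a negative. The test suite checks
this property, plus exact equivalence between pointwise evaluation and
the exhaustive 128-pattern truth table, for every built-in rule.

### The two published intercepts

The logistic equation is published twice with different intercepts:
−4.483 in the full-precision equation and −4.84 in the
coefficient table. Both are consistent with the rounded odds ratio
printed for the constant (exp(−4.483) = 0.011, exp(−4.84) = 0.008,
both print as 0.01), so the discrepancy cannot be resolved from the
published material. We default to −4.483 because it matches the
precision of the other equation coefficients, and ship −4.84 as the
named variant `rule4_alt`. Exactly one answer pattern in common use,
{Q2, Q3, Q4}, is classified differently by the two (predictive
probability 0.886 vs 0.844 around the 0.849 cutoff); a regression test
pins this divergence.

### Cutoff strictness

The cutoff comparison is strict (`probability > 0.849`), following the
published rule statement. Whether a probability exactly equal to the
cutoff counts as positive is not stated anywhere; since answer
patterns can land near (and in principle on) the cutoff, the
`logistic_rule()` constructor exposes `strict` as a flag, defaulting
to strict.

## Diagnostic accuracy and table reconstruction

`diagnostic_report()` computes Se = tp/(tp+fn), Sp = tn/(tn+fp),
PPV = tp/(tp+fp), NPV = tn/(tn+fn), Cohen's κ from the 2×2 margins
(two-category, unweighted), and — for a binary rule — AUC =
(Se+Sp)/2. A degenerate margin (e.g. PPV with no positive
predictions) yields an explicit `NA` with a warning, never a silent
0/0. PPV and NPV satisfy Bayes' rule at the table's own prevalence
exactly, a property the tests assert as an identity.

The raw respondent-level data behind the validation cohort are not
deposited, but its 2×2 tables are fully recoverable:
`reconstruct_confusion(n, d, se, sp)` sets `tp = round(se·d)` and
`tn = round(sp·(n−d))` with half-up rounding. Half-up is our choice —
the source never states its rounding — but it reproduces all eight
published Se/Sp cells as integers consistently, and the recomputed
Se/Sp then agree with the inputs within the 0.5/n quantization bound
(a round-trip property tested over random tables). One reconstructed
statistic disagrees with its printed value in the last digit: the
rule-1 κ computed from the forced cells (119, 7, 29, 40) is 0.565,
which rounds to 0.56 against a printed 0.57; the cells themselves are
pinned by the printed Se/Sp, so we report the recomputed value.

`roc_cutoff()` enumerates candidate cutoffs at midpoints between
consecutive distinct scores (plus sentinels beyond both extremes),
classifies positive on `score > cutoff`, and maximizes the Youden
index Se + Sp − 1. Ties break toward the lowest qualifying cutoff,
favoring sensitivity — appropriate for a screening instrument, and
unstated in the source. AUC is the trapezoid area, which the tests
verify equals the Mann–Whitney rank statistic (with the ½-tie
convention) and matches `pROC` on continuous scores.

## Sample-size planning

Validation-phase sizes use the accuracy-driven one-proportion
formulas: `n = z²·Se(1−Se)/(d²·p)` for sensitivity (only the diseased
fraction `p` of recruits informs Se) and the mirror form with
`Sp(1−Sp)` and `1−p` for specificity. Survey-phase size uses
`n = D·z²·p(1−p)/d²` with a scalar design effect `D ≥ 1`.
`z` is the two-sided normal quantile (1.96 at 95%). All sizes round
**up**: with the planning inputs (Se 0.82, Sp 0.89, p 0.3048,
d 0.10/0.05, D 2) the unrounded values 186.0, 54.1 and 651.3 become
187, 55 and 652, matching the published plan only under ceiling.

`recruitment_target()` inflates for expected losses multiplicatively:
`n / ((1−unqualified)·(1−nonresponse))`. Dividing the rounded 652 by
0.95·0.50 gives 1372.6 → 1373; dividing the unrounded 651.3 gives
1370.9. The published target "more than 1371" is consistent with
either; we inflate the rounded requirement (the more conservative
reading) and note the variant here.

## Cleaning: staged, ordered, accounted

`clean_cohort()` applies exclusions in a fixed order — unparseable →
duplicates → reliability → age → disease conditions — so every
removed record lands in exactly one bucket and the report always
balances (`received − removed = retained`). Decisions the source
leaves open, resolved here:

* **Duplicates** require device id, network address *and* basic
  demographics (age, sex) to all match; the first occurrence is kept.
  Partial matches (device + address only) are flagged in the report
  but retained.
* **Age** is strict `< 24` months: exactly 24.0 months is excluded
  ("younger than 2 years" with the boundary resolved conservatively).
* **Missing answers** fail the reliability stage, alongside
  repeated-question mismatches and self-evaluated low quality: the
  original web form enforced completeness, but a file-based pipeline
  cannot, so incomplete answer vectors are treated as unreliable
  responses rather than a separate class.

Cleaning is idempotent (re-cleaning retained records removes nothing),
which the tests assert directly.

## The synthetic cohort generator

Real respondent data are not available, so every cohort-level test
runs on generated data. A `cohort_model()` couples a latent disease
state (Bernoulli at the model prevalence) with an answer model, in one
of two forms.

**Conditional independence (generative default).** Each question is
drawn independently given the disease state, except that Q5 (sites
affected within 1 week) is drawn only when Q6 (within 6 months) is
yes — the implication a logically consistent respondent would satisfy.
This form is transparent and easy to parameterize but cannot represent
arbitrary dependence.

**Pattern tables (calibration mode).** A probability vector over the
128 answer patterns per disease state. Rule-level sensitivity and
specificity, and the per-question marginals, are *linear* in these
probabilities, so `model_accuracy()` and `model_marginals()` are exact
— no simulation — and the tests verify them against brute-force
truth-table enumeration.

`calibrate_cohort_model()` finds pattern tables matching target
rule-level Se/Sp (and optionally overall answer marginals at a given
prevalence) by least squares over the two simplexes, using a softmax
parameterization and L-BFGS-B with an analytic gradient; feasibility
tolerance is 0.01 per target. Notably, calibration searches the *full*
simplex, including Q5-yes/Q6-no patterns: the observed validation
cohort has identical Q5 and Q6 marginals (83.1% each) yet different
rule-1 and rule-2 operating characteristics, which is impossible if
Q5 ⇒ Q6 held exactly — real caregivers answer the two recall windows
inconsistently. Restricting the support makes the published targets
jointly infeasible; freeing it reproduces all six rule-level targets
and all seven marginals to residuals below 10⁻⁴. Genuinely
conflicting targets (e.g. rule-2 sensitivity 1 with an overall Q2
marginal below the prevalence) are reported as infeasible with the
best-found residuals, never silently absorbed.

The default phase-1-style model (`phase1_cohort_model()`) is
calibrated to the published validation targets: rules 1–3 Se/Sp,
the seven answer marginals, prevalence 148/195. Demographics are
filled plausibly: ages uniform on [0, 24) months (floored to 0.1 so no
record lands on the exclusive bound), balanced sex, unique device and
network identifiers, consistent reliability fields. The awareness flag
is drawn at 6.1% among diseased respondents, the survey-phase rate
among identified-but-undiagnosed children, since no other estimate
exists. `inject_survey_noise()` overlays field losses — nonresponse
dropouts, corrupted reliability fields, cloned device/address records
— at configurable rates, deterministically per seed.

**What the generator does not emulate:** inter-question dependence
beyond what calibration forces (the true joint distribution is
unknowable from published marginals and rule-level summaries),
age- or sex-dependent answer patterns, free-text fields, timestamps,
and any survey-platform behavior. Passing tests therefore demonstrate
correctness of the statistical machinery under the published operating
characteristics, not robustness to every real-world answer pattern.

## Numerical choices and problem sizes

* Half-up rounding in table reconstruction; ceiling in sample sizes.
* Youden ties break to the lowest cutoff; cutoff comparison strict.
* Calibration: L-BFGS-B, `factr = 10`, analytic gradient; residual
  tolerance 0.01 per target.
* Reported precision follows the field's convention: percentages to
  1 decimal, κ and AUC to 2.
* Test problem sizes: truth tables are exhaustive (128 patterns);
  empirical rule-recovery checks use 10,000-respondent calibrated
  cohorts (sampling error well below the 2-point check tolerance);
  marginal-convergence checks use 100,000 respondents against a
  3-standard-error band. The whole suite runs in a few seconds.

## Known limitations

* The 0.849 cutoff cannot be re-derived without the original
  respondent-level scores; it is shipped as a constant, and
  `roc_cutoff()` exists for users fitting their own scores.
* Confidence intervals for Se/Sp/PPV/NPV are not provided (none were
  published to compare against).
* Reconstructed κ/AUC inherit the integer-cell quantization of the
  2×2 reconstruction; they are exact for the cells, not for the
  unobserved raw data.
* The instrument itself was developed on a Chinese population;
  nothing in this package addresses cross-cultural revalidation.
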