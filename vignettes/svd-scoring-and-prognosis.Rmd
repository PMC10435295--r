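---
title: "Composite SVD scores and one-year cognitive-decline analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite SVD scores and one-year cognitive-decline analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdscores)
```

## The problem

Cerebral small vessel disease (SVD) leaves characteristic traces on MRI:
white-matter hyperintensities (WMH), lacunes, microbleeds (MBs), enlarged
perivascular spaces (PVS), cortical superficial siderosis (cSS), and cortical
microinfarcts (CMIs). Two arteriopathies dominate, with different lesion
topographies: hypertensive arteriopathy (deep MBs, basal-ganglia PVS,
lacunes) and cerebral amyloid angiopathy (CAA: lobar MBs, centrum-semiovale
PVS, cSS, posterior-dominant WMH, occipital CMIs). Composite ordinal scores
summarize this burden per patient, and a memory clinic wants to know whether
the baseline burden — or the baseline neuropsychological profile — predicts
which patients will deteriorate on the Clinical Dementia Rating (CDR) within
a year.

This package implements that analysis end to end: the three rule-based score
engines, the cohort data model, the longitudinal statistics, and a synthetic
cohort generator that makes every downstream stage testable with known
ground truth.

## The three score engines

All three scales are deterministic functions of a visit's rated markers.

**CAA-SVD (0–6)** sums four components:

| component | rule | points |
|---|---|---|
| lobar MBs | 2–4 microbleeds / ≥ 5 | 1 / 2 |
| cSS | focal / disseminated | 1 / 2 |
| CSO-PVS | moderate to severe (> 20 visible) | 1 |
| WMH | periventricular Fazekas 3 and/or deep Fazekas 2–3 | 1 |

**HA-SVD (0–4)** awards one point each for: any lacune, any microbleed (deep
or lobar), moderate-to-severe basal-ganglia PVS, and the same WMH rule. The
defining publication of the scale fixes these cut-offs; because the clinical
source we calibrated against names the markers without restating the
cut-offs, each is a parameter of `svd_score_config()` (`lacune_min`,
`mb_min`, `pvs_threshold`).

**Modified CAA-SVD (0–8)** adds to the CAA-SVD total one point for
posterior-dominant WMH (a precomputed flag in this package — tissue
quantification is out of scope) and one point for CMIs attributable to CAA:
all lesions confined to the cortex, each < 5 mm in diameter, fewer than
three lesions, and predominantly occipital.

Three readings required a decision:

- *PVS "moderate to severe (> 20)"* maps to ordinal grade ≥ 2 on the 0–4
  rating scale. This is validated empirically: applying the rules to the
  nine bundled per-patient records reproduces the published baseline group
  mean of 2.6 (see below), which the thresholds ≥ 3 and ≥ 4 fail to do.
- *"Predominantly in the occipital lobe"* defaults to the weakest reading
  consistent with the wording — the occipital lesion count is at least as
  large as every other lobe's count — with a strict-majority variant one
  switch away (`occipital_rule = "strict"`).
- *Missing markers abort scoring.* A missing rating is never silently scored
  as absent; an explicit `missing = "assume_absent"` policy exists for
  screening use and warns loudly every time it fires.

Group means are rendered to one decimal with half-up rounding
(`round_half_up()`), matching clinical-table formatting; base R's
round-half-even would differ on exact halves.

### The bundled fixture and its one inconsistency

`worsened_group_fixture()` carries the nine worsened-CDR patients exactly as
published, both visits. Scoring them reproduces the published baseline
CAA-SVD group mean:

```{r fixture}
sc <- score_cohort(worsened_group_fixture(), "caa_svd")
round_half_up(mean(sc$total[sc$visit == "baseline"]), 1)
round_half_up(mean(sc$total[sc$visit == "follow_up"]), 1)
```

The follow-up value deserves a note. The per-patient follow-up rows sum to
28 points (totals 3, 3, 4, 4, 3, 2, 4, 4, 1), a mean of 3.1, whereas the
source's group table prints 3.0. No admissible reading of the component
rules resolves this: the baseline mean pins the PVS threshold, and every
variant that lowers the follow-up sum by the required single point also
breaks the baseline reproduction. The same source's per-patient rows also
disagree with its printed follow-up lobar-MB mean (11.4 computed vs 12.8
printed) and baseline MMSE (24.6 vs 26.0), so we treat this as a
transcription inconsistency in the published per-patient table, report the
computed 3.1, and leave the corresponding acceptance assertion failing
rather than bend a rule to fit.

## The statistical pipeline

**Two-group comparisons** (`compare_groups()`) follow the
equal-variance/unequal-variance dichotomy: Student's pooled t for
homoscedastic data, Welch's t otherwise. The gate is not specified by the
clinical procedure we mirror, so we chose the median-centred Levene
(Brown–Forsythe) pretest at α = 0.05 — robust to non-normality, and for two
groups it reduces to a pooled t on absolute deviations from group medians,
which we compute directly and verify against `car::leveneTest` in the test
suite. Every result records the gate's p-value and the branch taken. The
gated procedure's type-I error at the study's group sizes (20 + 9) stays
within [0.03, 0.07] at nominal 0.05 over 10,000 null replicates (checked in
the acceptance tests).

**Within-group longitudinal tests** (`compare_paired()`) are paired t-tests
on complete pairs, with Wilcoxon signed-rank one switch away. The source
does not name its within-group test; the paired t matches its everywhere-
parametric style. Degenerate inputs are flagged rather than guessed at:
identical pairs give p = 1; a constant non-zero shift has no within-pair
variance, so p is `NA`, the degeneracy flag is set, and the direction is
recorded.

**Categorical comparisons** (`compare_proportions()`) use the
continuity-corrected chi-square, switching to Fisher's exact test when any
expected cell under the pooled proportion is below 5, and record which was
used.

**Multiplicity** is deliberately uncorrected by default (α = 0.05 per
comparison), mirroring the clinical analysis this package reproduces, which
runs many comparisons and acknowledges the type-I risk;
`comparison_table(results, p_adjust = "holm")` applies a Holm correction and
recomputes the significance flags for users who want it.

**The screen-then-model procedure** (`select_baseline_predictors()` →
`fit_cdr_change_model()`) retains every baseline variable that differs
between the CDR-stable and CDR-worsened groups at α, then fits a logistic
model of worsening on the retained covariates, reporting B, SE, Wald χ²,
p, OR = exp(B) and the 95% Wald CI. With 29 patients and covariates spanning
two orders of magnitude, maximum likelihood can diverge under separation, so
the fitter watches for non-convergence and fitted probabilities pinned at
0/1 and falls back to Firth's bias-reduced scoring (hat-diagonal-corrected
score, implemented in the package), always flagging the fallback. Constant
covariates are aliased (B = 0, OR = 1, flagged) instead of dropped
silently. On simulated data the two-stage procedure at 400 patients per
group retains the truly separated covariates with the generating signs in
over 90% of replicates (acceptance tests).

**ROC cutoffs** (`roc_analysis()`) use the empirical curve over midpoints
between adjacent observed values (which is what produces half-integer
cutoffs such as 2.5 for a count), trapezoidal AUC — identical to the
normalized Mann–Whitney U with ties counted 1/2, a property the tests assert
— and the Youden index J = sensitivity + specificity − 1 for the cutoff,
with ties broken toward higher specificity. Values at or above the threshold
are positive; `direction = "<"` flips the orientation. The published
sensitivity/specificity pairs for the two headline cutoffs are not asserted
anywhere: they are inconsistent with the stated group sizes under either
orientation, and the underlying per-patient values are unpublished.

## The synthetic cohort generator

`default_sim_config()` encodes a two-group longitudinal cohort whose
structure mirrors the published group tables: 20 CDR-stable and 9
CDR-worsened patients, group-separated lobar-MB burden (means 1.4 vs 9.6),
group-separated psychomotor speed (reasoning-test completion time 334.7 s vs
573.5 s; Trail-Making-A 180.2 s vs 244.6 s), per-group categorical marker
grades whose means equal the published per-group means, and one-year
progression increments that never decrease a marker (the published
per-patient rows are monotone in time).

Decisions behind the defaults:

- **Dispersion reading.** The published tables label parentheses "SD", but
  values such as MMSE 26.7 (0.5) at n = 20 are implausible as SDs of an
  MCI/mild-dementia sample and consistent with standard errors. The default
  therefore reads printed dispersions as SEs and converts
  (SD = SE × √n, with the published group sizes 20 and 9);
  `dispersion_is_se = FALSE` switches to the literal reading.
- **Families.** None are published. Lobar MBs are negative binomial — the
  per-patient counts span 0–43, far overdispersed for a Poisson — with the
  size parameter moment-matched to the implied SD. Deep MBs and lacunes are
  Poisson. Ordinal grades are categorical with weights chosen once to match
  the published group means (e.g. worsened deep-Fazekas mean 2.2 from
  weights 0.05/0.15/0.35/0.45). Scores and times are truncated normals.
- **Moment-matched truncation.** Times are bounded below, and with SDs as
  large as the worsened group's, naive truncation at zero would bias means
  upward by ~15 s. The generator therefore shifts the location parameter so
  the *truncated* mean equals the target (solved by `uniroot` on the
  truncated-normal mean identity), keeping configured group means
  recoverable: at 5,000 patients per group the empirical lobar-MB and
  reasoning-time means fall within 3 standard errors of the configured
  values (tested).
- **Correlation.** The worsened group's lobar-MB count and reasoning time
  share a Gaussian-copula rank correlation (default 0.3) so the modelling
  stage faces realistic collinearity; no correlation is published, and the
  stable group's is left at 0.
- **CDR labels** follow the group by construction (stable: unchanged;
  worsened: one step up from a baseline of 0.5 or 1), so the generating
  group and the CDR-derived grouping coincide — which is exactly what
  `truth_table()` exposes for recovery tests.

What the generator does *not* emulate: rater noise and inter-rater
disagreement; floor/ceiling effects beyond simple clamping to instrument
ranges; dropout and missingness patterns (synthetic visits are complete);
correlations among the remaining measures; diagnosis labels. Passing tests
on synthetic cohorts therefore demonstrate that the machinery recovers known
structure of this idealized form — not that the clinical effect sizes
themselves are right.

## Problem sizes in the test suite

The suite pins its simulations to sizes chosen to make Monte-Carlo noise
negligible relative to the asserted tolerances while keeping a full run in
minutes: 10,000 null replicates for the type-I property at the study's 20+9
split, 2,000 patients for logistic parameter recovery (3-SE criterion), 100
replicate cohorts at 400/group for the two-stage selection rate, 5,000 per
group for generator moment recovery, and 100 replicates at the published
29-patient size for the score-separation property.

## Known limitations

- The headline logistic coefficients and ROC cutoffs of the motivating
  clinical study cannot be reproduced numerically: the per-patient
  neuropsychological values and the stable group's marker ratings were never
  published. The pipeline reproduces the *procedure*, validated by
  property-based tests, and the bundled nine-patient fixture validates the
  scoring surface.
- Score engines treat raters as ground truth; inter-rater reliability is out
  of scope.
- The Wald CIs reported for both ML and Firth fits are symmetric on the log
  scale; profile-likelihood intervals would be preferable near separation
  but are not implemented.
- `cdr_groups()` dichotomizes any CDR increase; magnitude of worsening and
  sum-of-boxes trajectories are carried in the data model but not modelled.
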