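# svdscores

Composite cerebral small-vessel-disease (SVD) MRI scores and the
longitudinal analysis built on them, for memory-clinic cohorts followed over
one year.

Cerebral small vessel disease shows up on MRI as white-matter
hyperintensities (WMH, Fazekas-graded), lacunes, deep and lobar microbleeds
(MBs), enlarged perivascular spaces (PVS), cortical superficial siderosis
(cSS) and cortical microinfarcts (CMIs). Clinicians compress this burden
into ordinal composite scores:

- **HA-SVD (0–4)** — one point per hypertensive-arteriopathy marker:
  any lacune, any MB, moderate-to-severe basal-ganglia PVS, and
  WMH (periventricular Fazekas 3 and/or deep Fazekas 2–3);
- **CAA-SVD (0–6)** — lobar MBs (1 point for 2–4, 2 for ≥ 5) + cSS
  (1 focal, 2 disseminated) + centrum-semiovale PVS (1 point if
  moderate-to-severe) + the same WMH point;
- **modified CAA-SVD (0–8)** — CAA-SVD + 1 point for posterior-dominant WMH
  + 1 point for CAA-attributable CMIs (cortical, < 5 mm, fewer than three,
  occipital-predominant).

The package provides these three rule engines as pure functions, a validated
cohort data model (CSV/JSON I/O, a bundled nine-patient longitudinal
fixture), a synthetic two-group cohort generator with known ground truth,
and the statistical pipeline used to relate baseline markers and
neuropsychological scores to one-year Clinical Dementia Rating (CDR)
worsening: variance-gated Student/Welch comparisons, paired within-group
tests, chi-square/Fisher proportion tests, a baseline screen feeding a
logistic model of worsening (with a flagged Firth fallback under
separation), and empirical ROC curves with Youden-index cutoffs.

It is written for methodologists and clinical researchers who want the
scoring rules and the analysis chain as tested, scriptable building blocks
rather than as spreadsheet arithmetic.

## Worked example

Score the bundled nine worsened-CDR patients (both visits) on the CAA-SVD
scale:

```r
library(svdscores)
sc <- score_cohort(worsened_group_fixture(), "caa_svd")
round_half_up(mean(sc$total[sc$visit == "baseline"]), 1)
#> [1] 2.6
sc$total[sc$visit == "follow_up"]
#> [1] 3 3 4 4 3 2 4 4 1
```

The baseline group mean 2.6 reproduces the published group table. Each
per-visit breakdown is available component by component:

```r
caa_svd_score(list(
  lobar_mb_count = 23, css_extent = "none", cso_pvs_grade = 3,
  wmh_deep_fazekas = 3, wmh_pv_fazekas = 2
))
#> CAA-SVD score: 4 / 6
#>   lobar_mb 2
#>   css      0
#>   cso_pvs  1
#>   wmh      1
```

A variance-gated comparison records its decision trail:

```r
r <- compare_groups(c(1, 2, 3), c(4, 5, 6), gate = "student")
round(c(statistic = r$statistic, p = r$p_value), 3)
#> statistic         p
#>    -3.674     0.021
```

And the full chain runs on a synthetic cohort with known truth:

```r
run_pipeline(list(input = "simulate", seed = 0, out_dir = "results/pipeline"))
```

which writes the scored cohort, the per-group summary, all comparison
tables, the logistic fit and ROC curves as CSV, plus a markdown report and a
log of every gate decision.

The numbered scripts under `analysis/` tell the same story as a workflow:
`01_fixture_scores.R` (fixture scoring and diagnosis transitions; four
amnestic-MCI patients convert to probable AD), `02_simulate_cohort.R`
(default synthetic cohort, seed 0), `03_group_comparisons.R`
(cross-sectional and longitudinal comparisons) and `04_screen_model_roc.R`
(screen → logistic model → ROC). Each writes its tables under `results/`.

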