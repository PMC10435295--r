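#!/usr/bin/env Rscript

# The predictive chain on the synthetic cohort: screen baseline variables for
# group differences, fit the logistic model of 1-year CDR worsening on the
# retained covariates, and derive ROC cutoffs (Youden index) for each.

suppressPackageStartupMessages(library(svdscores))
dir.create("results", showWarnings = FALSE)

cohort <- if (file.exists("results/synthetic_cohort.csv")) {
  read_cohort("results/synthetic_cohort.csv")
} else {
  generate_cohort(default_sim_config(seed = 0))
}
groups <- cdr_groups(cohort)

candidates <- c("rcpm_time_s", "tmt_a_s", "lobar_mb_count", "mmse", "rcpm_score")
selected <- select_baseline_predictors(cohort, candidates)
readr::write_csv(attr(selected, "screen"), "results/baseline_screen.csv")
cat("selected baseline predictors:",
  if (length(selected) == 0) "(none)" else paste(selected, collapse = ", "), "\n")

if (length(selected) > 0) {
  base <- cohort[cohort$visit == "baseline", ]
  base <- base[match(groups$patient_id, base$patient_id), ]
  outcome <- as.integer(groups$group == "worsened")

  fit <- fit_cdr_change_model(base[, selected, drop = FALSE], outcome)
  print(fit)
  readr::write_csv(fit$coefficients, "results/logistic_fit.csv")

  for (var in selected) {
    r <- roc_analysis(base[[var]], outcome)
    print(r)
    readr::write_csv(roc_table(r), sprintf("results/roc_%s.csv", var))
  }
}
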