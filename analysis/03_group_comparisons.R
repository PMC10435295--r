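#!/usr/bin/env Rscript

# Cross-sectional (stable vs worsened, per visit) and longitudinal (baseline
# vs follow-up, per group) comparisons on the synthetic cohort from
# 02_simulate_cohort.R, with the variance-gated t/Welch machinery.

suppressPackageStartupMessages(library(svdscores))
dir.create("results", showWarnings = FALSE)

cohort <- if (file.exists("results/synthetic_cohort.csv")) {
  read_cohort("results/synthetic_cohort.csv")
} else {
  generate_cohort(default_sim_config(seed = 0))
}
groups <- cdr_groups(cohort)

vars <- c(
  "mmse", "rcpm_score", "rcpm_time_s", "rbmt_sps", "rbmt_ss",
  "tmt_a_s", "tmt_b_s", "wf_animal", "wf_letters", "mcas_score",
  "mcas_time_s", "lobar_mb_count", "deep_mb_count", "lacune_count"
)

for (v in c("baseline", "follow_up")) {
  visit_rows <- cohort[cohort$visit == v, ]
  visit_rows$group <- groups$group[match(visit_rows$patient_id, groups$patient_id)]
  res <- lapply(vars, function(var) {
    compare_groups(
      visit_rows[[var]][visit_rows$group == "stable"],
      visit_rows[[var]][visit_rows$group == "worsened"],
      variable = var
    )
  })
  tab <- comparison_table(res)
  readr::write_csv(tab, sprintf("results/comparisons_%s.csv", v))
  sig <- tab$variable[tab$significant]
  cat(sprintf(
    "%s: %d/%d variables significant at 0.05: %s\n",
    v, length(sig), nrow(tab),
    if (length(sig) == 0) "(none)" else paste(sig, collapse = ", ")
  ))
}

for (g in c("stable", "worsened")) {
  ids <- groups$patient_id[groups$group == g]
  b <- cohort[cohort$visit == "baseline" & cohort$patient_id %in% ids, ]
  f <- cohort[cohort$visit == "follow_up" & cohort$patient_id %in% ids, ]
  f <- f[match(b$patient_id, f$patient_id), ]
  res <- lapply(vars, function(var) {
    compare_paired(b[[var]], f[[var]], variable = var)
  })
  tab <- comparison_table(res)
  readr::write_csv(tab, sprintf("results/longitudinal_%s.csv", g))
  sig <- tab$variable[tab$significant]
  cat(sprintf(
    "longitudinal %s: significant 1-year changes: %s\n",
    g, if (length(sig) == 0) "(none)" else paste(sig, collapse = ", ")
  ))
}
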