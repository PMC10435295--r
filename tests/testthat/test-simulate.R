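test_that("default configuration encodes the published group structure", {
  cfg <- default_sim_config()
  expect_equal(cfg$n_stable, 20L)
  expect_equal(cfg$n_worsened, 9L)
  expect_equal(cfg$groups$worsened$markers$lobar_mb_mean, 9.6)
  expect_equal(cfg$groups$stable$markers$lobar_mb_mean, 1.4)
  expect_equal(cfg$groups$stable$neuropsych$rcpm_time_s[["base_mean"]], 334.7)
  expect_equal(cfg$groups$worsened$neuropsych$rcpm_time_s[["base_mean"]], 573.5)
  expect_equal(cfg$groups$stable$neuropsych$tmt_a_s[["base_mean"]], 180.2)
  expect_equal(cfg$groups$worsened$neuropsych$tmt_a_s[["base_mean"]], 244.6)
  # every categorical weight vector sums to one
  for (g in c("stable", "worsened")) {
    mk <- cfg$groups[[g]]$markers
    for (nm in c("faz_deep_probs", "faz_pv_probs", "bg_pvs_probs",
      "cso_pvs_probs", "css_probs", "cmi_lobe_probs")) {
      expect_equal(sum(mk[[nm]]), 1)
    }
  }
  # invalid configs are rejected with aggregated messages
  bad <- cfg
  bad$groups$stable$markers$posterior_p <- 1.5
  bad$groups$worsened$markers$css_probs <- c(none = 0.5, focal = 0.2, disseminated = 0.2)
  cnd <- rlang::catch_cnd(validate_sim_config(bad), "svdscores_validation_error")
  expect_true(length(cnd$problems) >= 2)
})

test_that("generated cohorts have the requested shape and are seed-deterministic", {
  cfg <- default_sim_config(seed = 1)
  co <- generate_cohort(cfg)
  expect_equal(length(unique(co$patient_id)), 29)
  expect_equal(nrow(co), 58)
  expect_silent(validate_cohort(co))
  co2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(co), as.data.frame(co2))
  # a different seed changes the draw
  co3 <- generate_cohort(cfg, seed = 2)
  expect_false(identical(as.data.frame(co), as.data.frame(co3)))
})

test_that("markers never regress between baseline and follow-up", {
  co <- generate_cohort(default_sim_config(n_stable = 150, n_worsened = 150, seed = 5))
  b <- co[co$visit == "baseline", ]
  f <- co[co$visit == "follow_up", ]
  f <- f[match(b$patient_id, f$patient_id), ]
  for (nm in c("lacune_count", "deep_mb_count", "lobar_mb_count",
    "wmh_deep_fazekas", "wmh_pv_fazekas", "bg_pvs_grade", "cso_pvs_grade")) {
    expect_true(all(f[[nm]] >= b[[nm]]), info = nm)
  }
  css_rank <- function(x) match(x, c("none", "focal", "disseminated"))
  expect_true(all(css_rank(f$css_extent) >= css_rank(b$css_extent)))
  expect_true(all(f$posterior_wmh_dominant >= b$posterior_wmh_dominant))
})

test_that("zero progression makes follow-up markers equal baseline", {
  cfg <- default_sim_config(n_stable = 40, n_worsened = 20, seed = 11)
  for (g in c("stable", "worsened")) {
    cfg$groups[[g]]$progression <- list(
      lobar_mb_inc_mean = 0, deep_mb_inc_mean = 0, lacune_inc_mean = 0,
      faz_deep_step_p = 0, faz_pv_step_p = 0, cso_step_p = 0, bg_step_p = 0,
      css_step_p = 0, posterior_onset_p = 0
    )
  }
  co <- generate_cohort(cfg)
  b <- co[co$visit == "baseline", ]
  f <- co[co$visit == "follow_up", ]
  f <- f[match(b$patient_id, f$patient_id), ]
  for (nm in c("lacune_count", "deep_mb_count", "lobar_mb_count",
    "wmh_deep_fazekas", "wmh_pv_fazekas", "bg_pvs_grade", "cso_pvs_grade",
    "css_extent", "posterior_wmh_dominant")) {
    expect_identical(f[[nm]], b[[nm]], info = nm)
  }
})

test_that("truth table exposes ground truth, matches config counts, is order-invariant", {
  cfg <- default_sim_config(seed = 9)
  co <- generate_cohort(cfg)
  tt <- truth_table(co)
  expect_equal(nrow(tt), 29)
  expect_equal(sum(tt$group == "stable"), cfg$n_stable)
  expect_equal(sum(tt$group == "worsened"), cfg$n_worsened)
  # truth agrees with the CDR-derived grouping
  g <- cdr_groups(co)
  expect_equal(
    as.character(g$group[match(tt$patient_id, g$patient_id)]),
    tt$group
  )
  # shuffling visit order leaves the truth content identical
  shuffled <- co[sample(nrow(co)), ]
  attr(shuffled, "truth") <- attr(co, "truth")
  attr(shuffled, "svd_synthetic") <- TRUE
  tt2 <- truth_table(shuffled)
  expect_identical(tt2[order(tt2$patient_id), ], tt[order(tt$patient_id), ])
  # a cohort not produced by the generator has no truth
  expect_error(truth_table(worsened_group_fixture()), class = "svdscores_truth_error")
})

test_that("empirical group means recover the configured means at large n", {
  n <- 5000L
  cfg <- default_sim_config(n_stable = n, n_worsened = n, seed = 13)
  co <- generate_cohort(cfg)
  tt <- truth_table(co)
  b <- co[co$visit == "baseline", ]
  b$group <- tt$group[match(b$patient_id, tt$patient_id)]
  for (g in c("stable", "worsened")) {
    mk <- cfg$groups[[g]]$markers
    np <- cfg$groups[[g]]$neuropsych
    lob <- b$lobar_mb_count[b$group == g]
    expect_lt(
      abs(mean(lob) - mk$lobar_mb_mean), 3 * stats::sd(lob) / sqrt(n)
    )
    rt <- b$rcpm_time_s[b$group == g]
    expect_lt(
      abs(mean(rt) - np$rcpm_time_s[["base_mean"]]), 3 * stats::sd(rt) / sqrt(n)
    )
  }
})

test_that("the configured rank correlation appears between microbleeds and reasoning time", {
  cfg <- default_sim_config(n_stable = 4000, n_worsened = 4000, seed = 17)
  co <- generate_cohort(cfg)
  tt <- truth_table(co)
  b <- co[co$visit == "baseline", ]
  b$group <- tt$group[match(b$patient_id, tt$patient_id)]
  w <- b[b$group == "worsened", ]
  rho <- suppressWarnings(
    stats::cor(w$lobar_mb_count, w$rcpm_time_s, method = "spearman")
  )
  expect_gt(rho, 0.15)
  expect_lt(rho, 0.45)
  s <- b[b$group == "stable", ]
  rho0 <- suppressWarnings(
    stats::cor(s$lobar_mb_count, s$rcpm_time_s, method = "spearman")
  )
  expect_lt(abs(rho0), 0.06)
})

test_that("worsened cohorts carry the higher mean CAA-SVD score at the published size", {
  set.seed(19)
  seeds <- sample.int(1e6, 100)
  higher <- vapply(seeds, function(s) {
    co <- generate_cohort(default_sim_config(seed = s))
    tt <- truth_table(co)
    sc <- score_cohort(co, "caa_svd")
    sc <- sc[sc$visit == "baseline", ]
    sc$group <- tt$group[match(sc$patient_id, tt$patient_id)]
    mean(sc$total[sc$group == "worsened"]) > mean(sc$total[sc$group == "stable"])
  }, logical(1))
  expect_gte(mean(higher), 0.95)
})
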