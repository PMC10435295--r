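# Shared helpers: random admissible marker profiles and an independently
# coded decision-table oracle for the three composite scores.

random_marker_profile <- function(max_count = 6L) {
  lesions <- if (stats::runif(1) < 0.3) {
    k <- sample(0:3, 1)
    if (k == 0) {
      data.frame(diameter_mm = double(), cortical_only = logical(),
        lobe = character())
    } else {
      data.frame(
        diameter_mm = stats::runif(k, 0.5, 8),
        cortical_only = stats::runif(k) < 0.8,
        lobe = sample(c("frontal", "parietal", "temporal", "occipital", "other"),
          k, replace = TRUE)
      )
    }
  } else {
    data.frame(diameter_mm = double(), cortical_only = logical(),
      lobe = character())
  }
  list(
    lacune_count = sample(0:max_count, 1),
    deep_mb_count = sample(0:max_count, 1),
    lobar_mb_count = sample(0:(3 * max_count), 1),
    wmh_deep_fazekas = sample(0:3, 1),
    wmh_pv_fazekas = sample(0:3, 1),
    bg_pvs_grade = sample(0:4, 1),
    cso_pvs_grade = sample(0:4, 1),
    css_extent = sample(c("none", "focal", "disseminated"), 1),
    posterior_wmh_dominant = stats::runif(1) < 0.5,
    cmi_lesions = lesions
  )
}

# Decision-table oracle, written against the published rules without reusing
# the package's point functions: every component is a table lookup.
oracle_caa_total <- function(m) {
  lob <- cut(m$lobar_mb_count, c(-1, 1, 4, Inf), labels = FALSE) - 1L
  css <- c(none = 0L, focal = 1L, disseminated = 2L)[[m$css_extent]]
  cso <- if (m$cso_pvs_grade %in% 2:4) 1L else 0L
  wmh_table <- outer(0:3, 0:3, function(deep, pv) (deep >= 2) | (pv == 3))
  wmh <- as.integer(wmh_table[m$wmh_deep_fazekas + 1, m$wmh_pv_fazekas + 1])
  lob + css + cso + wmh
}

oracle_ha_total <- function(m) {
  lac <- if (m$lacune_count >= 1) 1L else 0L
  mb <- if ((m$deep_mb_count + m$lobar_mb_count) >= 1) 1L else 0L
  bg <- if (m$bg_pvs_grade %in% 2:4) 1L else 0L
  wmh_table <- outer(0:3, 0:3, function(deep, pv) (deep >= 2) | (pv == 3))
  wmh <- as.integer(wmh_table[m$wmh_deep_fazekas + 1, m$wmh_pv_fazekas + 1])
  lac + mb + bg + wmh
}

oracle_cmi_flag <- function(les) {
  if (nrow(les) == 0 || nrow(les) >= 3) {
    return(FALSE)
  }
  if (any(!les$cortical_only) || any(les$diameter_mm >= 5)) {
    return(FALSE)
  }
  tab <- table(factor(les$lobe,
    levels = c("frontal", "parietal", "temporal", "occipital", "other")))
  tab[["occipital"]] >= max(tab[names(tab) != "occipital"])
}

oracle_modified_total <- function(m) {
  oracle_caa_total(m) + as.integer(isTRUE(m$posterior_wmh_dominant)) +
    as.integer(oracle_cmi_flag(m$cmi_lesions))
}

# Minimal valid cohort wrapping arbitrary baseline value columns, with the
# CDR-change dichotomy fixed by `group`; used to drive the screening stage
# with known signal structure.
cohort_with_values <- function(vals, group) {
  n <- nrow(vals)
  ids <- sprintf("p%04d", seq_len(n))
  blank <- data.frame(
    lacune_count = 0L, deep_mb_count = 0L, lobar_mb_count = 0L,
    wmh_deep_fazekas = 0L, wmh_pv_fazekas = 0L,
    bg_pvs_grade = 0L, cso_pvs_grade = 0L, css_extent = "none"
  )
  base <- cbind(
    data.frame(patient_id = ids, visit = "baseline", cdr_global = 0.5),
    blank, vals
  )
  fu <- cbind(
    data.frame(
      patient_id = ids, visit = "follow_up",
      cdr_global = ifelse(group == "worsened", 1, 0.5)
    ),
    blank, vals[rep(NA_integer_, n), , drop = FALSE]
  )
  svdscores::as_cohort(rbind(base, fu))
}

# Hard, independent copy of the nine published patients (both visits) used to
# cross-check the bundled fixture cell by cell.
fixture_reference <- function() {
  list(
    mmse_base = c(23, 22, 27, 21, 23, 27, 25, 27, 26),
    mmse_fu = c(16, 15, 21, 10, 19, 27, 22, 26, 26),
    lacune_base = c(0, 0, 1, 0, 2, 0, 0, 0, 0),
    lacune_fu = c(0, 0, 1, 0, 2, 0, 0, 0, 0),
    lobar_base = c(0, 3, 23, 43, 3, 0, 12, 0, 1),
    lobar_fu = c(2, 6, 26, 47, 3, 0, 12, 6, 1),
    deep_base = c(0, 0, 3, 3, 0, 0, 0, 0, 0),
    deep_fu = c(0, 0, 3, 3, 0, 0, 0, 0, 0),
    faz_deep_base = c(3, 1, 3, 2, 3, 2, 2, 2, 1),
    faz_deep_fu = c(3, 1, 3, 2, 3, 2, 2, 2, 1),
    faz_pv_base = c(3, 1, 2, 3, 3, 3, 2, 1, 1),
    faz_pv_fu = c(3, 1, 3, 3, 3, 3, 3, 2, 1),
    cso_base = c(4, 1, 3, 4, 3, 3, 4, 4, 3),
    cso_fu = c(4, 3, 3, 4, 3, 3, 4, 4, 3),
    bg_base = c(1, 1, 3, 2, 2, 3, 3, 1, 1),
    bg_fu = c(2, 1, 3, 2, 2, 3, 3, 1, 1),
    diag_base = c("probable AD", "aMCI", "probable AD", "aMCI", "aMCI",
      "naMCI", "probable AD", "aMCI", "aMCI"),
    diag_fu = c("probable AD", "probable AD", "probable AD", "probable AD",
      "vascular dementia", "probable AD", "probable AD", "probable AD",
      "probable AD")
  )
}
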