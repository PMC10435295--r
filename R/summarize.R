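.summary_vars <- c(
  "mmse", "rcpm_score", "rcpm_time_s", "rbmt_sps", "rbmt_ss",
  "tmt_a_s", "tmt_b_s", "wf_animal", "wf_letters", "mcas_score",
  "mcas_time_s",
  "lacune_count", "deep_mb_count", "lobar_mb_count",
  "wmh_deep_fazekas", "wmh_pv_fazekas", "cso_pvs_grade", "bg_pvs_grade"
)

#' Per-group, per-visit summary of a cohort
#'
#' Produces the mean/dispersion summary the group tables of a longitudinal
#' memory-clinic report are built from: for every numeric variable (the
#' neuropsychological battery, marker counts and grades, and — when
#' `scores = TRUE` — the composite SVD score totals), the per-group,
#' per-visit effective n, mean, SD and SE, with a rendering to one decimal
#' (half-up). Because a single printed dispersion can be read either way,
#' both `mean (SD)` and `mean (SE)` renderings are returned. Binary markers
#' (any cSS, posterior-WMH dominance, CAA-attributed microinfarcts) are
#' summarized as counts and percentages.
#'
#' @param cohort A validated cohort tibble.
#' @param group Optional factor/character vector of group labels, one per
#'   patient, named by `patient_id`; when `NULL`, groups are derived from the
#'   CDR change via [cdr_groups()] if both visits are present, else a single
#'   `"all"` group is used.
#' @param scores Also score the cohort with the HA-SVD and CAA-SVD scales
#'   (and the modified scale when the posterior flag is known) and include
#'   the totals (default `TRUE`).
#' @param config Scoring configuration for the score totals.
#' @return A tibble with columns `variable`, `group`, `visit`, `n`, `mean`,
#'   `sd`, `se`, `fmt_sd` (`"mean (SD)"`), `fmt_se` (`"mean (SE)"`); binary
#'   markers carry `n`, `count` and `percent` with `fmt_sd = "count (pct%)"`.
#' @examples
#' s <- summarize_cohort(worsened_group_fixture())
#' subset(s, variable == "caa_svd" & visit == "baseline")$fmt_sd
#' @export
summarize_cohort <- function(cohort, group = NULL, scores = TRUE,
                             config = svd_score_config()) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0) {
    return(tibble::tibble(
      variable = character(), group = character(), visit = character(),
      n = integer(), mean = double(), sd = double(), se = double(),
      fmt_sd = character(), fmt_se = character()
    ))
  }
  if (is.null(group)) {
    has_both <- all(.visit_levels %in% cohort$visit) &&
      !anyNA(cohort$cdr_global)
    group <- if (has_both) {
      g <- cdr_groups(cohort)
      stats::setNames(as.character(g$group), g$patient_id)
    } else {
      stats::setNames(
        rep("all", length(unique(cohort$patient_id))),
        unique(cohort$patient_id)
      )
    }
  }
  df <- cohort
  df$group <- unname(group[df$patient_id])

  num <- df[, c("patient_id", "group", "visit",
    intersect(.summary_vars, names(df)))]
  if (scores) {
    for (scale in c("ha_svd", "caa_svd")) {
      sc <- score_cohort(cohort, scale, config)
      num[[scale]] <- sc$total[match(
        paste(num$patient_id, num$visit),
        paste(sc$patient_id, sc$visit)
      )]
    }
    if (!anyNA(cohort$posterior_wmh_dominant)) {
      sc <- score_cohort(cohort, "modified_caa_svd", config)
      num$modified_caa_svd <- sc$total[match(
        paste(num$patient_id, num$visit),
        paste(sc$patient_id, sc$visit)
      )]
    }
  }
  long <- tidyr::pivot_longer(num, -c("patient_id", "group", "visit"),
    names_to = "variable", values_to = "value"
  )
  cont <- dplyr::summarise(
    dplyr::group_by(long, .data$variable, .data$group, .data$visit),
    n = sum(!is.na(.data$value)),
    mean = if (n > 0) mean(.data$value, na.rm = TRUE) else NA_real_,
    sd = stats::sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  cont$se <- cont$sd / sqrt(cont$n)
  cont$fmt_sd <- ifelse(
    cont$n == 0, "",
    paste0(fmt1(cont$mean), " (", fmt1(cont$sd), ")")
  )
  cont$fmt_se <- ifelse(
    cont$n == 0, "",
    paste0(fmt1(cont$mean), " (", fmt1(cont$se), ")")
  )

  bin <- tibble::tibble(
    patient_id = df$patient_id, group = df$group, visit = df$visit,
    any_css = df$css_extent != "none",
    posterior_wmh = df$posterior_wmh_dominant,
    cmi_due_to_caa = vapply(df$cmi_lesions, cmi_due_to_caa, logical(1),
      occipital_rule = config$occipital_rule
    )
  )
  binl <- tidyr::pivot_longer(bin, -c("patient_id", "group", "visit"),
    names_to = "variable", values_to = "value"
  )
  binc <- dplyr::summarise(
    dplyr::group_by(binl, .data$variable, .data$group, .data$visit),
    n = sum(!is.na(.data$value)),
    count = sum(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  binc$percent <- ifelse(binc$n > 0, 100 * binc$count / binc$n, NA_real_)
  binc$mean <- ifelse(binc$n > 0, binc$count / binc$n, NA_real_)
  binc$sd <- NA_real_
  binc$se <- NA_real_
  binc$fmt_sd <- ifelse(
    binc$n == 0, "",
    paste0(binc$count, " (", fmt1(binc$percent), "%)")
  )
  binc$fmt_se <- binc$fmt_sd

  out <- dplyr::bind_rows(
    cont,
    binc[, c("variable", "group", "visit", "n", "mean", "sd", "se",
      "fmt_sd", "fmt_se", "count", "percent")]
  )
  dplyr::arrange(out, .data$variable, .data$group, .data$visit)
}
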