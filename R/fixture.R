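#' The nine worsened-CDR patients (bundled fixture)
#'
#' Returns the published per-patient record of the nine memory-clinic patients
#' whose global CDR worsened over one year: diagnoses before and after
#' aggravation, MMSE, lacune count, lobar and deep microbleed counts, deep and
#' periventricular Fazekas grades, and centrum-semiovale / basal-ganglia
#' perivascular-space grades at both visits.
#'
#' Cortical superficial siderosis is `"none"` and the microinfarct lesion list
#' empty for every visit (the group's published cSS and CAA-attributed-CMI
#' counts are both zero). Per-patient posterior-WMH dominance is not published
#' and is left `NA`, so the modified CAA-SVD score cannot be computed for this
#' fixture. Global CDR at baseline is 1 for the three patients already carrying
#' a probable-AD diagnosis and 0.5 (MCI) for the remaining six; follow-up CDR
#' is one step worse, which is what defines the group. CDR sum-of-boxes is not
#' published per patient (`NA`). Neuropsychological columns other than MMSE are
#' `NA`.
#'
#' @return A validated cohort tibble of 9 patients x 2 visits = 18 rows.
#' @examples
#' fx <- worsened_group_fixture()
#' subset(fx, patient_id == "4" & visit == "baseline")$lobar_mb_count # 43
#' @export
worsened_group_fixture <- function() {
  diag_base <- c(
    "probable AD", "aMCI", "probable AD", "aMCI", "aMCI",
    "naMCI", "probable AD", "aMCI", "aMCI"
  )
  diag_fu <- c(
    "probable AD", "probable AD", "probable AD", "probable AD",
    "vascular dementia", "probable AD", "probable AD", "probable AD",
    "probable AD"
  )
  base <- tibble::tibble(
    patient_id = as.character(1:9),
    visit = "baseline",
    diagnosis = diag_base,
    cdr_global = ifelse(diag_base == "probable AD", 1, 0.5),
    mmse = c(23L, 22L, 27L, 21L, 23L, 27L, 25L, 27L, 26L),
    lacune_count = c(0L, 0L, 1L, 0L, 2L, 0L, 0L, 0L, 0L),
    lobar_mb_count = c(0L, 3L, 23L, 43L, 3L, 0L, 12L, 0L, 1L),
    deep_mb_count = c(0L, 0L, 3L, 3L, 0L, 0L, 0L, 0L, 0L),
    wmh_deep_fazekas = c(3L, 1L, 3L, 2L, 3L, 2L, 2L, 2L, 1L),
    wmh_pv_fazekas = c(3L, 1L, 2L, 3L, 3L, 3L, 2L, 1L, 1L),
    cso_pvs_grade = c(4L, 1L, 3L, 4L, 3L, 3L, 4L, 4L, 3L),
    bg_pvs_grade = c(1L, 1L, 3L, 2L, 2L, 3L, 3L, 1L, 1L)
  )
  fu <- tibble::tibble(
    patient_id = as.character(1:9),
    visit = "follow_up",
    diagnosis = diag_fu,
    cdr_global = base$cdr_global + ifelse(base$cdr_global == 0.5, 0.5, 1),
    mmse = c(16L, 15L, 21L, 10L, 19L, 27L, 22L, 26L, 26L),
    lacune_count = c(0L, 0L, 1L, 0L, 2L, 0L, 0L, 0L, 0L),
    lobar_mb_count = c(2L, 6L, 26L, 47L, 3L, 0L, 12L, 6L, 1L),
    deep_mb_count = c(0L, 0L, 3L, 3L, 0L, 0L, 0L, 0L, 0L),
    wmh_deep_fazekas = c(3L, 1L, 3L, 2L, 3L, 2L, 2L, 2L, 1L),
    wmh_pv_fazekas = c(3L, 1L, 3L, 3L, 3L, 3L, 3L, 2L, 1L),
    cso_pvs_grade = c(4L, 3L, 3L, 4L, 3L, 3L, 4L, 4L, 3L),
    bg_pvs_grade = c(2L, 1L, 3L, 2L, 2L, 3L, 3L, 1L, 1L)
  )
  both <- dplyr::bind_rows(base, fu)
  both$css_extent <- "none"
  both$posterior_wmh_dominant <- NA
  as_cohort(both)
}
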