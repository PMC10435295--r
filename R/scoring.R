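#' Scoring configuration for the composite SVD scales
#'
#' The published component rules fix the CAA-SVD point functions exactly;
#' the HA-SVD component cut-offs follow the scale's standard published
#' definitions and are exposed here so a user can depart from them.
#'
#' @param pvs_threshold Ordinal perivascular-space grade mapped to
#'   "moderate to severe (>20)". Grades at or above this threshold earn the
#'   PVS point. Default 2.
#' @param lacune_min Minimum lacune count earning the HA-SVD lacune point.
#'   Default 1.
#' @param mb_min Minimum total microbleed count (deep + lobar, any location)
#'   earning the HA-SVD microbleed point. Default 1.
#' @param occipital_rule How "predominantly in the occipital lobe" is read for
#'   CAA-attributed cortical microinfarcts: `"weak"` (occipital lesion count at
#'   least as large as every other lobe's count — the weakest reading
#'   consistent with the wording) or `"strict"` (strictly larger than every
#'   other lobe). Default `"weak"`.
#' @param missing Policy for missing required marker fields: `"error"` (abort
#'   with a missing-data error; the default — a missing rating is never
#'   silently scored as absent) or `"assume_absent"` (treat the missing marker
#'   as absent/zero and emit a loud warning, for screening use only).
#' @return A list of class `svd_score_config`.
#' @export
svd_score_config <- function(pvs_threshold = 2L, lacune_min = 1L, mb_min = 1L,
                             occipital_rule = c("weak", "strict"),
                             missing = c("error", "assume_absent")) {
  occipital_rule <- match.arg(occipital_rule)
  missing <- match.arg(missing)
  if (pvs_threshold < 0 || pvs_threshold > 4) {
    abort_domain("pvs_threshold must lie in 0..4")
  }
  structure(
    list(
      pvs_threshold = as.integer(pvs_threshold),
      lacune_min = as.integer(lacune_min),
      mb_min = as.integer(mb_min),
      occipital_rule = occipital_rule,
      missing = missing
    ),
    class = "svd_score_config"
  )
}

#' Lobar microbleed points (CAA-SVD component)
#'
#' 0 points for fewer than two lobar microbleeds, 1 point for two to four,
#' 2 points for five or more.
#'
#' @param count Non-negative integer vector of lobar microbleed counts.
#' @return Integer vector in `{0, 1, 2}`.
#' @examples
#' lobar_mb_points(c(0, 3, 43)) # 0 1 2
#' @export
lobar_mb_points <- function(count) {
  if (anyNA(count)) abort_missing_data("lobar microbleed count is missing")
  if (any(count < 0) || any(count != floor(count))) {
    abort_domain("lobar microbleed count must be a non-negative integer")
  }
  ifelse(count >= 5, 2L, ifelse(count >= 2, 1L, 0L))
}

#' Cortical superficial siderosis points (CAA-SVD component)
#'
#' 0 points when absent, 1 point for focal cSS, 2 points for disseminated cSS.
#'
#' @param extent Character vector over `"none"`, `"focal"`, `"disseminated"`.
#' @return Integer vector in `{0, 1, 2}`.
#' @export
css_points <- function(extent) {
  if (anyNA(extent)) abort_missing_data("cSS extent is missing")
  if (!all(extent %in% .css_levels)) {
    abort_domain("cSS extent must be one of none/focal/disseminated")
  }
  c(none = 0L, focal = 1L, disseminated = 2L)[extent]
}

#' Perivascular-space point
#'
#' 1 point when the ordinal PVS grade reaches the "moderate to severe (>20)"
#' band, operationalized as grade >= `threshold` (default 2); 0 otherwise.
#' Applied to the centrum semiovale in the CAA-SVD score and to the basal
#' ganglia in the HA-SVD score.
#'
#' @param grade Integer vector of ordinal PVS grades 0–4.
#' @param threshold Grade at which the point is awarded (default 2).
#' @return Integer vector in `{0, 1}`.
#' @export
pvs_point <- function(grade, threshold = 2L) {
  if (anyNA(grade)) abort_missing_data("PVS grade is missing")
  if (any(grade < 0 | grade > 4)) abort_domain("PVS grade must lie in 0..4")
  as.integer(grade >= threshold)
}

#' White-matter hyperintensity point (shared by all three scales)
#'
#' 1 point when the periventricular Fazekas grade is 3 and/or the deep
#' Fazekas grade is 2 or 3; 0 otherwise.
#'
#' @param deep,pv Integer vectors of Fazekas grades 0–3 (deep and
#'   periventricular white matter).
#' @return Integer vector in `{0, 1}`.
#' @examples
#' wmh_points(deep = c(1, 3, 0), pv = c(1, 3, 3)) # 0 1 1
#' @export
wmh_points <- function(deep, pv) {
  if (anyNA(deep) || anyNA(pv)) abort_missing_data("Fazekas grade is missing")
  if (any(deep < 0 | deep > 3) || any(pv < 0 | pv > 3)) {
    abort_domain("Fazekas grades must lie in 0..3")
  }
  as.integer(pv == 3 | deep >= 2)
}

#' Are cortical microinfarcts attributable to CAA?
#'
#' The add-on point of the modified CAA-SVD score requires microinfarcts that
#' are confined to the cortex, each smaller than 5 mm in diameter, fewer than
#' three in number, and predominantly occipital. An empty lesion list never
#' qualifies.
#'
#' @param lesions A data frame of lesions with columns `diameter_mm`,
#'   `cortical_only`, `lobe` (see [cohort-format]); may have zero rows.
#' @param occipital_rule `"weak"` (occipital count >= every other lobe's
#'   count) or `"strict"` (strictly greater).
#' @return `TRUE` or `FALSE`.
#' @export
cmi_due_to_caa <- function(lesions, occipital_rule = c("weak", "strict")) {
  occipital_rule <- match.arg(occipital_rule)
  lesions <- normalize_cmi(lesions)
  n <- nrow(lesions)
  if (n == 0) {
    return(FALSE)
  }
  if (n >= 3) {
    return(FALSE)
  }
  if (!all(lesions$cortical_only) || !all(lesions$diameter_mm < 5)) {
    return(FALSE)
  }
  counts <- table(factor(lesions$lobe, levels = .lobe_levels))
  occ <- counts[["occipital"]]
  others <- counts[setdiff(.lobe_levels, "occipital")]
  if (occipital_rule == "weak") occ >= max(others) else occ > max(others)
}

# --- score assembly ---------------------------------------------------------

score_breakdown <- function(components, scale, max_possible) {
  total <- as.integer(sum(components))
  stopifnot(total >= 0, total <= max_possible)
  structure(
    list(
      total = total,
      components = components,
      scale = scale,
      max_possible = as.integer(max_possible)
    ),
    class = "svd_score_breakdown"
  )
}

#' @export
print.svd_score_breakdown <- function(x, ...) {
  cat(sprintf(
    "%s score: %d / %d\n", toupper(gsub("_", "-", x$scale)),
    x$total, x$max_possible
  ))
  comp <- paste0("  ", format(names(x$components)), " ", x$components)
  cat(comp, sep = "\n")
  invisible(x)
}

as_marker_list <- function(m) {
  if (is.data.frame(m)) {
    if (nrow(m) != 1) abort_domain("expected a single marker profile (one row)")
    m <- as.list(m)
    if (is.list(m$cmi_lesions) && !is.data.frame(m$cmi_lesions)) {
      m$cmi_lesions <- m$cmi_lesions[[1]]
    }
  }
  m
}

require_markers <- function(m, fields, config) {
  vals <- m[fields]
  missing <- fields[vapply(vals, function(v) is.null(v) || anyNA(v), logical(1))]
  if (length(missing) == 0) {
    return(m)
  }
  if (config$missing == "error") {
    abort_missing_data(paste0(
      "cannot score: missing marker field(s) ", paste(missing, collapse = ", "),
      " (use svd_score_config(missing = 'assume_absent') to score them as absent)"
    ))
  }
  rlang::warn(paste0(
    "assume-absent scoring policy: treating missing marker field(s) ",
    paste(missing, collapse = ", "), " as absent"
  ), class = "svdscores_assume_absent_warning")
  defaults <- list(
    lacune_count = 0L, deep_mb_count = 0L, lobar_mb_count = 0L,
    wmh_deep_fazekas = 0L, wmh_pv_fazekas = 0L,
    bg_pvs_grade = 0L, cso_pvs_grade = 0L,
    css_extent = "none", posterior_wmh_dominant = FALSE,
    cmi_lesions = empty_cmi()
  )
  for (f in missing) m[[f]] <- defaults[[f]]
  m
}

#' CAA-SVD composite score (0–6)
#'
#' Sum of severity points over the four amyloid-angiopathy markers: lobar
#' microbleeds (0–2), cortical superficial siderosis (0–2), centrum-semiovale
#' perivascular spaces (0–1), and white-matter hyperintensity (0–1).
#'
#' @param m A marker profile: a named list or a one-row cohort slice with the
#'   marker columns of [cohort-format].
#' @param config A [svd_score_config()].
#' @return An `svd_score_breakdown` with `total`, per-component points,
#'   `scale = "caa_svd"` and `max_possible = 6`.
#' @examples
#' caa_svd_score(list(
#'   lobar_mb_count = 23, css_extent = "none", cso_pvs_grade = 3,
#'   wmh_deep_fazekas = 3, wmh_pv_fazekas = 2
#' ))$total # 4
#' @export
caa_svd_score <- function(m, config = svd_score_config()) {
  m <- as_marker_list(m)
  m <- require_markers(m, c(
    "lobar_mb_count", "css_extent", "cso_pvs_grade",
    "wmh_deep_fazekas", "wmh_pv_fazekas"
  ), config)
  comp <- c(
    lobar_mb = lobar_mb_points(m$lobar_mb_count),
    css = unname(css_points(m$css_extent)),
    cso_pvs = pvs_point(m$cso_pvs_grade, config$pvs_threshold),
    wmh = wmh_points(m$wmh_deep_fazekas, m$wmh_pv_fazekas)
  )
  score_breakdown(comp, "caa_svd", 6L)
}

#' HA-SVD composite score (0–4)
#'
#' One point for the presence/severity of each hypertensive-arteriopathy
#' marker: any lacune, any microbleed (deep or lobar), moderate-to-severe
#' basal-ganglia perivascular spaces, and the shared white-matter
#' hyperintensity rule. Component cut-offs are the scale's standard published
#' definitions, adjustable via [svd_score_config()].
#'
#' @inheritParams caa_svd_score
#' @return An `svd_score_breakdown` with `scale = "ha_svd"`,
#'   `max_possible = 4`.
#' @export
ha_svd_score <- function(m, config = svd_score_config()) {
  m <- as_marker_list(m)
  m <- require_markers(m, c(
    "lacune_count", "deep_mb_count", "lobar_mb_count",
    "bg_pvs_grade", "wmh_deep_fazekas", "wmh_pv_fazekas"
  ), config)
  if (m$lacune_count < 0 || m$deep_mb_count < 0 || m$lobar_mb_count < 0) {
    abort_domain("marker counts must be non-negative")
  }
  comp <- c(
    lacune = as.integer(m$lacune_count >= config$lacune_min),
    mb = as.integer(m$deep_mb_count + m$lobar_mb_count >= config$mb_min),
    bg_pvs = pvs_point(m$bg_pvs_grade, config$pvs_threshold),
    wmh = wmh_points(m$wmh_deep_fazekas, m$wmh_pv_fazekas)
  )
  score_breakdown(comp, "ha_svd", 4L)
}

#' Modified CAA-SVD composite score (0–8)
#'
#' The CAA-SVD score plus one point for posterior-dominant white-matter
#' hyperintensity and one point for cortical microinfarcts attributable to
#' CAA (see [cmi_due_to_caa()]).
#'
#' @inheritParams caa_svd_score
#' @return An `svd_score_breakdown` with `scale = "modified_caa_svd"`,
#'   `max_possible = 8`.
#' @export
modified_caa_svd_score <- function(m, config = svd_score_config()) {
  m <- as_marker_list(m)
  m <- require_markers(m, "posterior_wmh_dominant", config)
  base <- caa_svd_score(m, config)
  lesions <- m$cmi_lesions %||% empty_cmi()
  comp <- c(
    base$components,
    posterior_wmh = as.integer(isTRUE(m$posterior_wmh_dominant)),
    cmi_caa = as.integer(cmi_due_to_caa(lesions, config$occipital_rule))
  )
  score_breakdown(comp, "modified_caa_svd", 8L)
}

.scale_funs <- list(
  ha_svd = function(m, config) ha_svd_score(m, config),
  caa_svd = function(m, config) caa_svd_score(m, config),
  modified_caa_svd = function(m, config) modified_caa_svd_score(m, config)
)

#' Score every visit of a cohort
#'
#' Applies one of the three composite scales to every patient visit and
#' returns a tidy table with one row per visit: the component points and the
#' total. Deterministic; per-visit missing-data errors are re-raised with the
#' offending `patient_id` and `visit` named.
#'
#' @param cohort A validated cohort tibble.
#' @param scale `"caa_svd"`, `"ha_svd"` or `"modified_caa_svd"`.
#' @param config A [svd_score_config()].
#' @return A tibble with `patient_id`, `visit`, `scale`, one column per
#'   component, and `total`.
#' @examples
#' scores <- score_cohort(worsened_group_fixture(), "caa_svd")
#' round_half_up(mean(scores$total[scores$visit == "baseline"]), 1) # 2.6
#' @export
score_cohort <- function(cohort, scale = c("caa_svd", "ha_svd", "modified_caa_svd"),
                         config = svd_score_config()) {
  scale <- match.arg(scale)
  validate_cohort(cohort)
  fun <- .scale_funs[[scale]]
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    bd <- tryCatch(
      fun(cohort[i, ], config),
      svdscores_missing_data_error = function(e) {
        abort_missing_data(paste0(
          "patient ", cohort$patient_id[i], " (", cohort$visit[i], "): ",
          conditionMessage(e)
        ))
      }
    )
    tibble::as_tibble(c(
      list(patient_id = cohort$patient_id[i], visit = cohort$visit[i],
        scale = scale),
      as.list(bd$components),
      list(total = bd$total)
    ))
  })
  if (length(rows) == 0) {
    return(tibble::tibble(
      patient_id = character(), visit = character(), scale = character(),
      total = integer()
    ))
  }
  dplyr::bind_rows(rows)
}
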