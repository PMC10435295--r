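#' @title Cohort tables of rated SVD markers and neuropsychological results
#'
#' @description
#' A *cohort* is a tibble with one row per patient visit (at most one
#' `baseline` and one `follow_up` row per `patient_id`) holding the rated MRI
#' small-vessel-disease markers, the neuropsychological battery, and the
#' Clinical Dementia Rating (CDR) labels. All scoring and statistical
#' functions in the package consume this layout.
#'
#' @details
#' Required marker columns (per visit):
#' \describe{
#'   \item{lacune_count, deep_mb_count, lobar_mb_count}{non-negative integer
#'     counts; deep microbleeds are those in the basal ganglia, thalamus or
#'     brainstem, lobar microbleeds those in the cortical/subcortical
#'     compartment.}
#'   \item{wmh_deep_fazekas, wmh_pv_fazekas}{Fazekas grades 0–3 for deep and
#'     periventricular white-matter hyperintensity.}
#'   \item{bg_pvs_grade, cso_pvs_grade}{ordinal perivascular-space grades 0–4
#'     for basal ganglia and centrum semiovale.}
#'   \item{css_extent}{cortical superficial siderosis: one of `"none"`,
#'     `"focal"`, `"disseminated"`.}
#'   \item{posterior_wmh_dominant}{logical flag (may be `NA` when the
#'     posterior-dominance assessment is unavailable; the modified CAA-SVD
#'     score then cannot be computed).}
#'   \item{cmi_lesions}{list column; each element a data frame of cortical
#'     microinfarct lesions with columns `diameter_mm` (> 0, millimetres),
#'     `cortical_only` (logical) and `lobe` (one of `"frontal"`, `"parietal"`,
#'     `"temporal"`, `"occipital"`, `"other"`). Empty for visits without
#'     microinfarcts.}
#' }
#'
#' Neuropsychological columns are optional per visit and explicitly `NA` when
#' a test was not administered (never silently zero): `mmse` (0–30),
#' `rcpm_score` (0–36), `rcpm_time_s`, `rbmt_sps` (0–24), `rbmt_ss` (0–12),
#' `tmt_a_s`, `tmt_b_s`, `wf_animal`, `wf_letters`, `mcas_score`,
#' `mcas_time_s`. All times are seconds; word-fluency values are words per
#' minute (`wf_letters` the mean over four phonemes).
#'
#' Identification and outcome columns: `patient_id` (opaque string), `visit`
#' (`"baseline"` or `"follow_up"`), `diagnosis` (free label such as `"aMCI"`
#' or `"probable AD"`), `cdr_global` (0, 0.5, 1, 2 or 3) and `cdr_sb`
#' (CDR sum of boxes, >= 0).
#'
#' Unknown extra columns are preserved untouched as annotations.
#'
#' @name cohort-format
NULL

.visit_levels <- c("baseline", "follow_up")
.css_levels <- c("none", "focal", "disseminated")
.lobe_levels <- c("frontal", "parietal", "temporal", "occipital", "other")
.cdr_levels <- c(0, 0.5, 1, 2, 3)

.count_cols <- c("lacune_count", "deep_mb_count", "lobar_mb_count")
.grade_cols <- c(
  wmh_deep_fazekas = 3L, wmh_pv_fazekas = 3L,
  bg_pvs_grade = 4L, cso_pvs_grade = 4L
)
.neuro_int_cols <- c(mmse = 30L, rcpm_score = 36L, rbmt_sps = 24L, rbmt_ss = 12L)
.neuro_pos_cols <- c("rcpm_time_s", "tmt_a_s", "tmt_b_s", "mcas_time_s")
.neuro_nonneg_cols <- c("wf_animal", "wf_letters", "mcas_score")

.cohort_cols <- c(
  "patient_id", "visit", "diagnosis", "cdr_global", "cdr_sb",
  .count_cols, names(.grade_cols), "css_extent", "posterior_wmh_dominant",
  "cmi_lesions",
  "mmse", "rcpm_score", "rcpm_time_s", "rbmt_sps", "rbmt_ss",
  "tmt_a_s", "tmt_b_s", "wf_animal", "wf_letters",
  "mcas_score", "mcas_time_s"
)

empty_cmi <- function() {
  tibble::tibble(
    diameter_mm = double(), cortical_only = logical(), lobe = character()
  )
}

normalize_cmi <- function(x) {
  if (is.null(x) || (!is.data.frame(x) && length(x) == 0) ||
      (is.data.frame(x) && nrow(x) == 0)) {
    return(empty_cmi())
  }
  if (!is.data.frame(x)) {
    rlang::abort("cmi_lesions entries must be data frames",
      class = "svdscores_validation_error"
    )
  }
  tibble::tibble(
    diameter_mm = as.double(x$diameter_mm),
    cortical_only = as.logical(x$cortical_only),
    lobe = as.character(x$lobe)
  )
}

#' Coerce a data frame to the canonical cohort layout
#'
#' Fills absent optional columns with `NA`, coerces known columns to their
#' canonical types, normalizes the `cmi_lesions` list column, and validates.
#'
#' @param df A data frame with at least the identification and marker columns
#'   (see [cohort-format]).
#' @return A validated cohort tibble in canonical column order (annotations,
#'   i.e. unknown columns, appended at the end).
#' @seealso [validate_cohort()], [read_cohort()]
#' @export
as_cohort <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c(
    "patient_id", "visit", .count_cols, names(.grade_cols), "css_extent"
  )
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort_validation(c(
      "cohort is missing required columns",
      stats::setNames(miss, rep("x", length(miss)))
    ))
  }
  optional_na <- list(
    diagnosis = NA_character_, cdr_global = NA_real_, cdr_sb = NA_real_,
    posterior_wmh_dominant = NA,
    mmse = NA_integer_, rcpm_score = NA_integer_, rcpm_time_s = NA_real_,
    rbmt_sps = NA_integer_, rbmt_ss = NA_integer_,
    tmt_a_s = NA_real_, tmt_b_s = NA_real_,
    wf_animal = NA_real_, wf_letters = NA_real_,
    mcas_score = NA_real_, mcas_time_s = NA_real_
  )
  for (nm in names(optional_na)) {
    if (!nm %in% names(df)) df[[nm]] <- optional_na[[nm]]
  }
  if (!"cmi_lesions" %in% names(df)) {
    df$cmi_lesions <- rep(list(empty_cmi()), nrow(df))
  }

  df$patient_id <- as.character(df$patient_id)
  df$visit <- as.character(df$visit)
  df$diagnosis <- as.character(df$diagnosis)
  df$cdr_global <- as.double(df$cdr_global)
  df$cdr_sb <- as.double(df$cdr_sb)
  for (nm in c(.count_cols, names(.grade_cols), names(.neuro_int_cols))) {
    df[[nm]] <- as.integer(df[[nm]])
  }
  for (nm in c(.neuro_pos_cols, .neuro_nonneg_cols)) {
    df[[nm]] <- as.double(df[[nm]])
  }
  df$css_extent <- as.character(df$css_extent)
  df$posterior_wmh_dominant <- as.logical(df$posterior_wmh_dominant)
  if (is.character(df$cmi_lesions)) {
    df$cmi_lesions <- lapply(df$cmi_lesions, cmi_from_json)
  } else {
    df$cmi_lesions <- lapply(df$cmi_lesions, normalize_cmi)
  }

  extra <- setdiff(names(df), .cohort_cols)
  df <- df[, c(.cohort_cols, extra)]
  validate_cohort(df)
  df
}

#' Validate a cohort table
#'
#' Checks every invariant of the cohort layout: column presence and types,
#' count non-negativity, ordinal grade ranges, category membership, positive
#' lesion diameters, neuropsychological ranges, and uniqueness of
#' `(patient_id, visit)` pairs. Validation is total: any violation raises a
#' single classed error listing every offending row and field, and no
#' partially checked cohort is ever returned.
#'
#' @param cohort A cohort tibble (see [cohort-format]).
#' @return `cohort`, invisibly, when valid.
#' @export
validate_cohort <- function(cohort) {
  problems <- character()
  note <- function(rows, msg) {
    if (length(rows) > 0) {
      ids <- paste0(
        "row ", rows, " (patient ", cohort$patient_id[rows], ", ",
        cohort$visit[rows], ")"
      )
      problems <<- c(problems, paste0(ids, ": ", msg))
    }
  }
  bad <- function(x) !is.na(x) & x # helper for logical vectors with NA

  if (nrow(cohort) == 0) {
    return(invisible(cohort))
  }
  note(which(is.na(cohort$patient_id) | cohort$patient_id == ""), "missing patient_id")
  note(which(!cohort$visit %in% .visit_levels),
    "visit must be 'baseline' or 'follow_up'")
  for (nm in .count_cols) {
    note(which(bad(cohort[[nm]] < 0L)), paste0(nm, " must be >= 0"))
    note(which(is.na(cohort[[nm]])), paste0(nm, " is missing"))
  }
  for (nm in names(.grade_cols)) {
    hi <- .grade_cols[[nm]]
    note(
      which(is.na(cohort[[nm]]) | cohort[[nm]] < 0L | cohort[[nm]] > hi),
      paste0(nm, " must be an integer in 0..", hi)
    )
  }
  note(which(!cohort$css_extent %in% .css_levels),
    "css_extent must be one of none/focal/disseminated")
  note(which(bad(!cohort$cdr_global %in% .cdr_levels)),
    "cdr_global must be one of 0, 0.5, 1, 2, 3")
  note(which(bad(cohort$cdr_sb < 0)), "cdr_sb must be >= 0")
  for (nm in names(.neuro_int_cols)) {
    hi <- .neuro_int_cols[[nm]]
    note(which(bad(cohort[[nm]] < 0L | cohort[[nm]] > hi)),
      paste0(nm, " must be in 0..", hi))
  }
  for (nm in .neuro_pos_cols) {
    note(which(bad(cohort[[nm]] <= 0)), paste0(nm, " must be > 0 seconds"))
  }
  for (nm in .neuro_nonneg_cols) {
    note(which(bad(cohort[[nm]] < 0)), paste0(nm, " must be >= 0"))
  }
  cmi_ok <- vapply(cohort$cmi_lesions, function(les) {
    is.data.frame(les) &&
      all(c("diameter_mm", "cortical_only", "lobe") %in% names(les)) &&
      all(!is.na(les$diameter_mm) & les$diameter_mm > 0) &&
      all(les$lobe %in% .lobe_levels) &&
      all(!is.na(les$cortical_only))
  }, logical(1))
  note(which(!cmi_ok),
    "cmi_lesions must have diameter_mm > 0, valid lobe, and non-missing cortical_only")

  dup <- duplicated(cohort[, c("patient_id", "visit")])
  note(which(dup), "duplicate (patient_id, visit) pair")

  if (length(problems) > 0) {
    abort_validation(
      c(
        sprintf("cohort validation failed (%d problem%s)", length(problems),
          if (length(problems) == 1) "" else "s"),
        stats::setNames(problems, rep("x", length(problems)))
      ),
      problems = problems
    )
  }
  invisible(cohort)
}

#' An empty cohort in canonical layout
#' @return A zero-row cohort tibble with every documented column.
#' @export
empty_cohort <- function() {
  as_cohort(tibble::tibble(
    patient_id = character(), visit = character(),
    lacune_count = integer(), deep_mb_count = integer(),
    lobar_mb_count = integer(),
    wmh_deep_fazekas = integer(), wmh_pv_fazekas = integer(),
    bg_pvs_grade = integer(), cso_pvs_grade = integer(),
    css_extent = character(), cmi_lesions = list()
  ))
}

cmi_to_json <- function(les) {
  as.character(jsonlite::toJSON(les, dataframe = "rows", digits = NA))
}

cmi_from_json <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(empty_cmi())
  }
  normalize_cmi(jsonlite::fromJSON(s))
}

infer_format <- function(path, format = NULL) {
  if (!is.null(format)) {
    return(match.arg(format, c("csv", "json")))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else "csv"
}

#' Read a cohort file
#'
#' Reads a CSV or JSON cohort file in the documented schema (see
#' [cohort-format]) and returns a fully validated cohort tibble. In CSV files
#' the `cmi_lesions` column holds a JSON array per row (`"[]"` or empty for no
#' lesions); in JSON files lesions are nested records. The CSV dialect is
#' comma-separated, UTF-8, `"."` decimal, header required. Unknown columns are
#' preserved.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   `NULL`.
#' @return A validated cohort tibble.
#' @examples
#' f <- system.file("extdata", "worsened_group_cohort.csv", package = "svdscores")
#' nrow(read_cohort(f)) # 18 visits, 9 patients x 2
#' @export
read_cohort <- function(path, format = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("cohort file does not exist: ", path),
      class = "svdscores_io_error"
    )
  }
  format <- infer_format(path, format)
  if (format == "csv") {
    header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
    chr_cols <- intersect(
      c("patient_id", "visit", "diagnosis", "css_extent", "cmi_lesions"),
      gsub("\"", "", header)
    )
    col_types <- do.call(readr::cols, c(
      stats::setNames(
        replicate(length(chr_cols), readr::col_character(), simplify = FALSE),
        chr_cols
      ),
      list(.default = readr::col_guess())
    ))
    df <- tryCatch(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
        col_types = col_types
      ),
      error = function(e) {
        rlang::abort(paste0("malformed CSV cohort file: ", conditionMessage(e)),
          class = "svdscores_parse_error", parent = e
        )
      }
    )
    prob <- readr::problems(df)
    if (nrow(prob) > 0) {
      rlang::abort(
        paste0(
          "malformed CSV cohort file: ",
          paste0("row ", prob$row, " col ", prob$col, ": expected ",
            prob$expected, ", got ", prob$actual, collapse = "; ")
        ),
        class = "svdscores_parse_error"
      )
    }
  } else {
    df <- tryCatch(
      jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
      error = function(e) {
        rlang::abort(paste0("malformed JSON cohort file: ", conditionMessage(e)),
          class = "svdscores_parse_error", parent = e
        )
      }
    )
    df <- tibble::as_tibble(df)
    if (nrow(df) > 0 && "cmi_lesions" %in% names(df) &&
        is.list(df$cmi_lesions) && !is.data.frame(df$cmi_lesions)) {
      df$cmi_lesions <- lapply(df$cmi_lesions, normalize_cmi)
    }
  }
  if (nrow(df) == 0) {
    return(empty_cohort())
  }
  as_cohort(df)
}

#' Write a cohort file
#'
#' Writes a cohort to CSV or JSON such that [read_cohort()] recovers it
#' field-for-field (round-trip stable). Microinfarct lesion lists are
#' serialized as JSON strings in CSV and nested records in JSON.
#'
#' @param cohort A validated cohort tibble.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = NULL) {
  validate_cohort(cohort)
  format <- infer_format(path, format)
  if (format == "csv") {
    out <- cohort
    out$cmi_lesions <- vapply(out$cmi_lesions, cmi_to_json, character(1))
    tryCatch(
      readr::write_csv(out, path, na = "", progress = FALSE),
      error = function(e) {
        rlang::abort(paste0("cannot write cohort file: ", conditionMessage(e)),
          class = "svdscores_io_error", parent = e
        )
      }
    )
  } else {
    tryCatch(
      jsonlite::write_json(cohort, path, dataframe = "rows", digits = NA,
        na = "null", auto_unbox = TRUE, pretty = TRUE),
      error = function(e) {
        rlang::abort(paste0("cannot write cohort file: ", conditionMessage(e)),
          class = "svdscores_io_error", parent = e
        )
      }
    )
  }
  invisible(path)
}

#' Classify patients as CDR-stable or CDR-worsened
#'
#' Pairs each patient's baseline and follow-up global CDR and labels the
#' patient `"worsened"` when the follow-up global CDR exceeds baseline,
#' `"stable"` otherwise. This is the group dichotomy all longitudinal
#' comparisons condition on.
#'
#' @param cohort A cohort tibble with both visits per patient and non-missing
#'   `cdr_global`.
#' @return A tibble with columns `patient_id`, `cdr_baseline`,
#'   `cdr_follow_up`, `group` (factor `stable`/`worsened`).
#' @export
cdr_groups <- function(cohort) {
  validate_cohort(cohort)
  wide <- tidyr::pivot_wider(
    cohort[, c("patient_id", "visit", "cdr_global")],
    names_from = "visit", values_from = "cdr_global"
  )
  if (!all(c("baseline", "follow_up") %in% names(wide))) {
    abort_missing_data("cdr_groups() needs both baseline and follow_up visits")
  }
  if (anyNA(wide$baseline) || anyNA(wide$follow_up)) {
    bad <- wide$patient_id[is.na(wide$baseline) | is.na(wide$follow_up)]
    abort_missing_data(paste0(
      "missing cdr_global or missing visit for patient(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  tibble::tibble(
    patient_id = wide$patient_id,
    cdr_baseline = wide$baseline,
    cdr_follow_up = wide$follow_up,
    group = factor(
      ifelse(wide$follow_up > wide$baseline, "worsened", "stable"),
      levels = c("stable", "worsened")
    )
  )
}
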