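#' Validate and materialize a pipeline run configuration
#'
#' Accepts a configuration as a named list or as a path to a YAML/JSON file,
#' checks every field before any computation, fills documented defaults, and
#' returns the materialized configuration. Field errors are aggregated into a
#' single validation error. Unknown keys produce a warning by default and an
#' error under `strict = TRUE`.
#'
#' Recognized fields:
#' \describe{
#'   \item{input}{`"fixture"`, `"simulate"`, or a file path (exactly one
#'     source).}
#'   \item{sim}{optional list of overrides for [default_sim_config()]
#'     arguments (`n_stable`, `n_worsened`, `dispersion_is_se`,
#'     `mb_rcpm_rho`) when `input = "simulate"`.}
#'   \item{alpha}{significance level in (0, 1); default 0.05.}
#'   \item{gate}{variance gate for group comparisons; default `"auto"`.}
#'   \item{candidates}{baseline variables screened before the logistic model;
#'     default: the neuropsychological battery plus the marker counts.}
#'   \item{score_config}{list of overrides for [svd_score_config()].}
#'   \item{out_dir}{output directory (created if needed).}
#'   \item{seed}{integer seed; default 0.}
#'   \item{verbose}{logical; default `TRUE`.}
#' }
#'
#' @param config A named list or a path to a YAML/JSON file.
#' @param strict Treat unknown keys as errors instead of warnings.
#' @return A list of class `svd_run_config` with all defaults materialized.
#' @export
validate_run_config <- function(config, strict = FALSE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort_validation(paste0("config file does not exist: ", config))
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) {
    abort_validation("config must be a named list or a YAML/JSON file path")
  }
  known <- c(
    "input", "sim", "alpha", "gate", "candidates", "score_config",
    "out_dir", "seed", "verbose"
  )
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    msg <- paste0("unknown config key(s): ", paste(unknown, collapse = ", "))
    if (strict) abort_validation(msg) else rlang::warn(msg)
  }

  defaults <- list(
    input = "fixture",
    sim = list(),
    alpha = 0.05,
    gate = "auto",
    candidates = c(
      "mmse", "rcpm_score", "rcpm_time_s", "rbmt_sps", "rbmt_ss",
      "tmt_a_s", "tmt_b_s", "wf_animal", "wf_letters", "mcas_score",
      "mcas_time_s", "lacune_count", "deep_mb_count", "lobar_mb_count"
    ),
    score_config = list(),
    out_dir = "svdscores_run",
    seed = 0L,
    verbose = TRUE
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }

  problems <- character()
  if (!is.character(config$input) || length(config$input) != 1) {
    problems <- c(problems, "input must be a single string ('fixture', 'simulate', or a file path)")
  }
  if (!is.numeric(config$alpha) || length(config$alpha) != 1 ||
      is.na(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    problems <- c(problems, "alpha must be a number in (0, 1)")
  }
  if (!config$gate %in% c("auto", "student", "welch")) {
    problems <- c(problems, "gate must be one of auto/student/welch")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1 || is.na(config$seed)) {
    problems <- c(problems, "seed must be an integer")
  }
  if (!is.character(config$candidates)) {
    problems <- c(problems, "candidates must be a character vector")
  }
  sc <- tryCatch(
    do.call(svd_score_config, config$score_config),
    error = function(e) conditionMessage(e)
  )
  if (is.character(sc)) {
    problems <- c(problems, paste0("score_config: ", sc))
  }
  if (length(problems) > 0) {
    abort_validation(c(
      "invalid run config",
      stats::setNames(problems, rep("x", length(problems)))
    ), problems = problems)
  }
  config$seed <- as.integer(config$seed)
  config$score_config <- sc
  structure(config, class = "svd_run_config")
}

#' Run the full scoring and prognosis pipeline
#'
#' Loads the requested cohort (the bundled nine-patient fixture, a synthetic
#' cohort, or a file), scores every visit on all applicable scales, builds
#' the per-group summary, runs the cross-sectional group comparisons at both
#' visits and the paired longitudinal comparisons within each group, then —
#' when both CDR groups are present — the baseline screen, the logistic model
#' of CDR worsening, and the ROC cutoff derivation for each retained
#' covariate. All artifacts are written as CSV plus a human-readable
#' markdown report; every gate and threshold decision is appended to a run
#' log. The run is deterministic given the seed.
#'
#' @param config A list or file path accepted by [validate_run_config()].
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (isTRUE(config$verbose)) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(
        paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = "svdscores_pipeline_error", parent = e
      )
    })
  }
  artifacts <- list()
  save_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p, na = "", progress = FALSE)
    artifacts[[name]] <<- p
    p
  }

  say("run_pipeline: input=%s seed=%d alpha=%g gate=%s",
    config$input, config$seed, config$alpha, config$gate)

  cohort <- stage("input", {
    if (config$input == "fixture") {
      worsened_group_fixture()
    } else if (config$input == "simulate") {
      sim <- do.call(default_sim_config, c(config$sim, list(seed = config$seed)))
      generate_cohort(sim)
    } else {
      read_cohort(config$input)
    }
  })
  say("loaded cohort: %d visits, %d patients", nrow(cohort),
    length(unique(cohort$patient_id)))

  scored <- stage("scoring", {
    scales <- c("ha_svd", "caa_svd")
    if (!anyNA(cohort$posterior_wmh_dominant)) {
      scales <- c(scales, "modified_caa_svd")
    } else {
      say("posterior-WMH dominance missing for some visits: modified CAA-SVD skipped")
    }
    dplyr::bind_rows(lapply(scales, function(s) {
      score_cohort(cohort, s, config$score_config)
    }))
  })
  save_csv(scored, "scored_cohort.csv")

  summary_tbl <- stage("summary", summarize_cohort(cohort, config = config$score_config))
  save_csv(summary_tbl, "summary_by_group.csv")

  both_visits <- all(.visit_levels %in% cohort$visit) && !anyNA(cohort$cdr_global)
  groups <- NULL
  predictors <- character()
  fit <- NULL
  rocs <- list()
  if (both_visits) {
    groups <- cdr_groups(cohort)
    two_groups <- nlevels(droplevels(groups$group)) == 2

    comp_vars <- intersect(config$candidates, names(cohort))
    comp <- function(visit_name) {
      v <- dplyr::filter(cohort, .data$visit == visit_name)
      v <- dplyr::left_join(v, groups[, c("patient_id", "group")], by = "patient_id")
      res <- list()
      for (var in comp_vars) {
        a <- v[[var]][v$group == "stable"]
        b <- v[[var]][v$group == "worsened"]
        if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
          r <- compare_groups(a, b, alpha = config$alpha, gate = config$gate,
            variable = var)
          say("compare[%s/%s]: test=%s gate_p=%s p=%.4g", visit_name, var,
            r$test, fmt1(r$gate_p, 3), r$p_value)
          res[[var]] <- r
        }
      }
      comparison_table(res)
    }
    if (two_groups) {
      stage("group_comparisons", {
        save_csv(comp("baseline"), "comparisons_baseline.csv")
        save_csv(comp("follow_up"), "comparisons_followup.csv")
      })
    } else {
      say("single CDR group present: cross-sectional comparisons skipped")
    }

    stage("longitudinal", {
      for (g in levels(droplevels(groups$group))) {
        ids <- groups$patient_id[groups$group == g]
        sub <- cohort[cohort$patient_id %in% ids, ]
        wide_var <- function(var) {
          b <- sub[[var]][sub$visit == "baseline"][
            match(ids, sub$patient_id[sub$visit == "baseline"])]
          f <- sub[[var]][sub$visit == "follow_up"][
            match(ids, sub$patient_id[sub$visit == "follow_up"])]
          list(b = b, f = f)
        }
        res <- list()
        for (var in comp_vars) {
          w <- wide_var(var)
          if (sum(!is.na(w$b) & !is.na(w$f)) >= 2) {
            r <- tryCatch(
              compare_paired(w$b, w$f, alpha = config$alpha, variable = var),
              svdscores_insufficient_data_error = function(e) NULL
            )
            if (!is.null(r)) res[[var]] <- r
          }
        }
        if (length(res) > 0) {
          save_csv(comparison_table(res), paste0("longitudinal_", g, ".csv"))
        }
      }
    })

    if (two_groups) {
      stage("predict", {
        predictors <- select_baseline_predictors(
          cohort, comp_vars, alpha = config$alpha, gate = config$gate
        )
        save_csv(attr(predictors, "screen"), "baseline_screen.csv")
        say("baseline screen selected: %s",
          if (length(predictors) == 0) "(none)" else paste(predictors, collapse = ", "))
        if (length(predictors) > 0) {
          base <- dplyr::filter(cohort, .data$visit == "baseline")
          base <- base[match(groups$patient_id, base$patient_id), ]
          outcome <- as.integer(groups$group == "worsened")
          fit <- fit_cdr_change_model(
            base[, predictors, drop = FALSE], outcome
          )
          say("logistic model: method=%s converged=%s separation=%s fallback=%s",
            fit$method, fit$converged, fit$separation, fit$fallback)
          save_csv(fit$coefficients, "logistic_fit.csv")
          sig <- fit$coefficients$term[
            fit$coefficients$term != "(Intercept)" &
              !fit$coefficients$aliased &
              fit$coefficients$p_value < config$alpha
          ]
          roc_vars <- if (length(sig) > 0) sig else predictors
          for (var in roc_vars) {
            r <- roc_analysis(base[[var]], outcome)
            say("roc[%s]: auc=%.3f cutoff=%g sens=%.3f spec=%.3f", var,
              r$auc, r$cutoff, r$sens_at_cutoff, r$spec_at_cutoff)
            rocs[[var]] <- r
            save_csv(roc_table(r), paste0("roc_", var, ".csv"))
          }
        }
      })
    } else {
      say("single CDR group present: screen/model/ROC skipped")
    }
  } else {
    say("cohort lacks paired visits or CDR labels: longitudinal stages skipped")
  }

  stage("report", {
    p <- file.path(out_dir, "report.md")
    writeLines(render_report(cohort, summary_tbl, predictors, fit, rocs, config), p)
    artifacts[["report.md"]] <- p
  })
  logp <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, logp)
  artifacts[["run_log.txt"]] <- logp
  invisible(artifacts)
}

render_report <- function(cohort, summary_tbl, predictors, fit, rocs, config) {
  lines <- c(
    "# SVD scoring and prognosis report",
    "",
    sprintf("- visits: %d, patients: %d", nrow(cohort),
      length(unique(cohort$patient_id))),
    sprintf("- alpha: %g, gate: %s, seed: %d", config$alpha, config$gate,
      config$seed),
    "",
    "## Group summary (mean (SD); dispersion also available as SE in summary_by_group.csv)",
    ""
  )
  wide <- tidyr::pivot_wider(
    summary_tbl[, c("variable", "group", "visit", "fmt_sd")],
    names_from = c("group", "visit"), values_from = "fmt_sd"
  )
  header <- paste0("| ", paste(names(wide), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|")
  rows <- apply(wide, 1, function(r) {
    paste0("| ", paste(ifelse(is.na(r), "", r), collapse = " | "), " |")
  })
  lines <- c(lines, header, sep, rows, "")
  if (length(predictors) > 0 && !is.null(fit)) {
    lines <- c(
      lines,
      "## Baseline screen and logistic model of CDR worsening",
      "",
      sprintf("Selected covariates: %s", paste(predictors, collapse = ", ")),
      sprintf("Method: %s (converged: %s)", fit$method, fit$converged),
      "",
      "| term | B | SE | Wald chi2 | p | OR | 95% CI |",
      "|---|---|---|---|---|---|---|",
      apply(fit$coefficients, 1, function(r) {
        sprintf("| %s | %.3f | %.3f | %.3f | %.3g | %.3f | %.3f-%.3f |",
          r[["term"]], as.numeric(r[["estimate"]]),
          as.numeric(r[["std_error"]]), as.numeric(r[["wald_chisq"]]),
          as.numeric(r[["p_value"]]), as.numeric(r[["odds_ratio"]]),
          as.numeric(r[["or_lower"]]), as.numeric(r[["or_upper"]]))
      }),
      ""
    )
  }
  if (length(rocs) > 0) {
    lines <- c(lines, "## ROC cutoffs (Youden index)", "")
    for (var in names(rocs)) {
      r <- rocs[[var]]
      lines <- c(lines, sprintf(
        "- %s: AUC %.3f, cutoff %g, sensitivity %.1f%%, specificity %.1f%%",
        var, r$auc, r$cutoff, 100 * r$sens_at_cutoff, 100 * r$spec_at_cutoff
      ))
    }
    lines <- c(lines, "")
  }
  lines
}
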