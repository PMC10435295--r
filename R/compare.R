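comparison_result <- function(variable = NA_character_, test, n1, n2,
                              mean1, mean2, sd1, sd2,
                              statistic, df, p_value, alpha,
                              gate_used = NA_character_, gate_p = NA_real_,
                              degenerate = FALSE, note = NA_character_) {
  structure(
    list(
      variable = variable, test = test,
      n1 = n1, n2 = n2, mean1 = mean1, mean2 = mean2,
      sd1 = sd1, sd2 = sd2,
      se1 = sd1 / sqrt(n1), se2 = sd2 / sqrt(n2),
      statistic = statistic, df = df, p_value = p_value,
      alpha = alpha,
      significant = !is.na(p_value) && p_value < alpha,
      gate_used = gate_used, gate_p = gate_p,
      degenerate = degenerate, note = note
    ),
    class = "svd_comparison"
  )
}

#' @export
print.svd_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: %s, statistic %.3f, df %.1f, p = %.4g%s\n",
    x$variable %||% "comparison", x$test,
    x$statistic, x$df, x$p_value,
    if (isTRUE(x$significant)) " *" else ""
  ))
  invisible(x)
}

#' Turn comparison results into a tidy table
#'
#' Flattens comparison results into one row per variable. By default no
#' multiplicity correction is applied (each comparison keeps its own level,
#' mirroring the uncorrected clinical convention this package reproduces);
#' `p_adjust = "holm"` (or any [stats::p.adjust()] method) adds an adjusted
#' p-value column and recomputes the significance flags from it.
#'
#' @param results A single `svd_comparison` or a list of them.
#' @param p_adjust `NULL` (no correction, default) or a method name for
#'   [stats::p.adjust()].
#' @param alpha Level used to recompute `significant` when adjusting.
#' @return A tibble with one row per comparison (plus `p_adjusted` when a
#'   correction is requested).
#' @export
comparison_table <- function(results, p_adjust = NULL, alpha = 0.05) {
  if (inherits(results, "svd_comparison")) results <- list(results)
  tab <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::as_tibble(r[c(
      "variable", "test", "n1", "n2", "mean1", "mean2", "sd1", "sd2",
      "se1", "se2", "statistic", "df", "p_value", "significant",
      "gate_used", "gate_p", "degenerate"
    )])
  }))
  if (!is.null(p_adjust) && nrow(tab) > 0) {
    tab$p_adjusted <- stats::p.adjust(tab$p_value, method = p_adjust)
    tab$significant <- !is.na(tab$p_adjusted) & tab$p_adjusted < alpha
  }
  tab
}

# Median-centred Levene (Brown-Forsythe) equality-of-variances pretest for two
# groups: a pooled-variance t-test on |x - group median|, whose square is the
# Brown-Forsythe F(1, n - 2). Direct form, vectorisable inside simulations;
# agreement with car::leveneTest is checked in the test suite.
levene_bf <- function(a, b) {
  za <- abs(a - stats::median(a))
  zb <- abs(b - stats::median(b))
  n1 <- length(za)
  n2 <- length(zb)
  sp2 <- ((n1 - 1) * stats::var(za) + (n2 - 1) * stats::var(zb)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 == 0) {
    return(list(statistic = 0, p_value = 1)) # no dispersion evidence either way
  }
  f <- (mean(za) - mean(zb))^2 / (sp2 * (1 / n1 + 1 / n2))
  list(statistic = f, p_value = stats::pf(f, 1, n1 + n2 - 2, lower.tail = FALSE))
}

#' Two-group comparison with a variance-equality gate
#'
#' Compares two independent samples with a two-sample t-test, choosing the
#' pooled-variance (Student) form for equal-variance data and the Welch form
#' for unequal-variance data. Under `gate = "auto"` the choice is made by a
#' median-centred Levene pretest at `var_alpha`, and the pretest's p-value and
#' the decision are recorded in the result so the gate's trail is auditable.
#'
#' @param a,b Numeric vectors (missing values dropped; each group needs at
#'   least two non-missing values).
#' @param alpha Significance level for flagging the comparison (default 0.05).
#' @param gate `"auto"` (variance pretest decides), `"student"`, or
#'   `"welch"`.
#' @param var_alpha Level of the variance pretest under `gate = "auto"`.
#' @param variable Optional variable name carried into the result.
#' @return An `svd_comparison` with group means, SDs and SEs, the test used,
#'   statistic, degrees of freedom, p-value, and the gate decision trail.
#'   When both groups have zero variance and equal means the result is flagged
#'   degenerate with `p = 1`.
#' @examples
#' r <- compare_groups(c(1, 2, 3), c(4, 5, 6), gate = "student")
#' round(r$statistic, 3) # -3.674
#' @export
compare_groups <- function(a, b, alpha = 0.05, gate = c("auto", "student", "welch"),
                           var_alpha = 0.05, variable = NA_character_) {
  gate <- match.arg(gate)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort_insufficient("compare_groups() needs >= 2 non-missing values per group")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    equal <- mean(a) == mean(b)
    return(comparison_result(
      variable = variable, test = "student_t",
      n1 = length(a), n2 = length(b), mean1 = mean(a), mean2 = mean(b),
      sd1 = 0, sd2 = 0,
      statistic = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
      df = length(a) + length(b) - 2,
      p_value = if (equal) 1 else 0,
      alpha = alpha, degenerate = TRUE,
      note = "zero variance in both groups"
    ))
  }
  gate_p <- NA_real_
  if (gate == "auto") {
    lv <- levene_bf(a, b)
    gate_p <- lv$p_value
    test <- if (gate_p < var_alpha) "welch_t" else "student_t"
  } else {
    test <- paste0(gate, "_t")
  }
  ht <- stats::t.test(a, b, var.equal = (test == "student_t"))
  comparison_result(
    variable = variable, test = test,
    n1 = length(a), n2 = length(b), mean1 = mean(a), mean2 = mean(b),
    sd1 = stats::sd(a), sd2 = stats::sd(b),
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, alpha = alpha,
    gate_used = if (gate == "auto") "levene_bf" else "fixed", gate_p = gate_p
  )
}

#' Paired within-group comparison of baseline and follow-up
#'
#' Paired t-test (or Wilcoxon signed-rank) on within-patient differences,
#' using complete pairs only and reporting the effective n. When every
#' difference is identical the test is degenerate: identical visits give
#' `p = 1`; a constant non-zero shift has no within-pair variance to test
#' against, so `p` is `NA`, the result is flagged, and the direction of the
#' shift is recorded.
#'
#' @param baseline,follow Equal-length numeric vectors, paired by position.
#' @param alpha Significance level.
#' @param method `"paired_t"` (default) or `"wilcoxon"`.
#' @param variable Optional variable name.
#' @return An `svd_comparison`; `n1 = n2` = number of complete pairs.
#' @export
compare_paired <- function(baseline, follow, alpha = 0.05,
                           method = c("paired_t", "wilcoxon"),
                           variable = NA_character_) {
  method <- match.arg(method)
  if (length(baseline) != length(follow)) {
    abort_domain("compare_paired() needs equal-length paired vectors")
  }
  ok <- !is.na(baseline) & !is.na(follow)
  baseline <- baseline[ok]
  follow <- follow[ok]
  n <- length(baseline)
  if (n < 2) {
    abort_insufficient("compare_paired() needs >= 2 complete pairs")
  }
  d <- follow - baseline
  if (stats::sd(d) == 0) {
    shift <- d[1]
    return(comparison_result(
      variable = variable, test = method, n1 = n, n2 = n,
      mean1 = mean(baseline), mean2 = mean(follow),
      sd1 = stats::sd(baseline), sd2 = stats::sd(follow),
      statistic = 0, df = n - 1,
      p_value = if (shift == 0) 1 else NA_real_,
      alpha = alpha, degenerate = TRUE,
      note = if (shift == 0) {
        "identical pairs"
      } else {
        paste0(
          "constant within-pair shift of ", shift, " (direction: ",
          if (shift > 0) "increase" else "decrease",
          "); no within-pair variance to test against"
        )
      }
    ))
  }
  ht <- if (method == "paired_t") {
    stats::t.test(follow, baseline, paired = TRUE)
  } else {
    stats::wilcox.test(follow, baseline, paired = TRUE, exact = FALSE, correct = TRUE)
  }
  comparison_result(
    variable = variable, test = method, n1 = n, n2 = n,
    mean1 = mean(baseline), mean2 = mean(follow),
    sd1 = stats::sd(baseline), sd2 = stats::sd(follow),
    statistic = unname(ht$statistic),
    df = if (method == "paired_t") unname(ht$parameter) else NA_real_,
    p_value = ht$p.value, alpha = alpha
  )
}

#' Two-sample comparison of proportions
#'
#' Chi-square test with continuity correction, switching to Fisher's exact
#' test whenever any expected cell count (under the pooled proportion) is
#' below 5; the method actually used is recorded in the result.
#'
#' @param k1,n1,k2,n2 Successes and totals per group (`0 <= k <= n`,
#'   `n >= 1`).
#' @param alpha Significance level.
#' @param variable Optional variable name.
#' @return An `svd_comparison`; means are the group proportions.
#' @export
compare_proportions <- function(k1, n1, k2, n2, alpha = 0.05,
                                variable = NA_character_) {
  counts <- c(k1, n1, k2, n2)
  if (anyNA(counts) || any(counts != floor(counts)) ||
      n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    abort_domain("compare_proportions() needs integer counts with 0 <= k <= n, n >= 1")
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  pooled <- (k1 + k2) / (n1 + n2)
  expected <- outer(c(n1, n2), c(pooled, 1 - pooled))
  if (any(expected < 5)) {
    ht <- stats::fisher.test(tab)
    test <- "fisher_exact"
    statistic <- NA_real_
    df <- NA_real_
  } else {
    ht <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2), correct = TRUE))
    test <- "chisq_corrected"
    statistic <- unname(ht$statistic)
    df <- unname(ht$parameter)
  }
  comparison_result(
    variable = variable, test = test,
    n1 = n1, n2 = n2, mean1 = k1 / n1, mean2 = k2 / n2,
    sd1 = sqrt(k1 / n1 * (1 - k1 / n1)), sd2 = sqrt(k2 / n2 * (1 - k2 / n2)),
    statistic = statistic, df = df, p_value = ht$p.value, alpha = alpha
  )
}
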