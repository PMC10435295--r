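#' Empirical ROC curve with Youden-index cutoff
#'
#' Builds the empirical receiver-operating-characteristic curve of a
#' continuous (or count) predictor against a binary outcome, computes the
#' area under the curve by the trapezoidal rule, and derives the optimal
#' cutoff maximizing the Youden index J = sensitivity + specificity - 1.
#'
#' Conventions: values at or above a threshold are called positive; the
#' threshold grid consists of the midpoints between adjacent observed values
#' plus one threshold below the minimum (everything positive) and one above
#' the maximum (nothing positive). The midpoint convention is what yields
#' half-integer cutoffs (e.g. 2.5) for count predictors. Ties in J are broken
#' toward the higher specificity (the higher threshold). The trapezoidal AUC
#' over this grid equals the Mann–Whitney U statistic normalized by
#' `n_pos * n_neg`, with ties counted 1/2.
#'
#' @param values Numeric predictor, higher values indicating the positive
#'   class (use `direction = "<"` for the reverse orientation).
#' @param outcome Binary vector (0/1 or logical); both classes required.
#' @param direction `">="` (default) or `"<"`: side of the threshold called
#'   positive.
#' @return An object of class `svd_roc`: list with `thresholds`,
#'   `sensitivity`, `specificity` (per threshold), `auc`, `cutoff`,
#'   `sens_at_cutoff`, `spec_at_cutoff`, `youden`, `n_pos`, `n_neg`,
#'   `direction`.
#' @examples
#' r <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
#' r$auc # 1
#' r$cutoff # 6.5
#' @export
roc_analysis <- function(values, outcome, direction = c(">=", "<")) {
  direction <- match.arg(direction)
  outcome <- as.integer(as.logical(outcome))
  ok <- !is.na(values) & !is.na(outcome)
  values <- values[ok]
  outcome <- outcome[ok]
  if (length(unique(outcome)) < 2) {
    abort_domain("roc_analysis() needs both outcome classes")
  }
  if (direction == "<") values <- -values
  pos <- values[outcome == 1]
  neg <- values[outcome == 0]
  u <- sort(unique(values))
  thresholds <- c(
    u[1] - 1,
    if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
    u[length(u)] + 1
  )
  sens <- vapply(thresholds, function(t) mean(pos >= t), double(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), double(1))
  # trapezoid over (FPR, TPR); thresholds ascending => FPR descending
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])] # ties toward higher specificity
  if (direction == "<") {
    thresholds <- -thresholds
  }
  structure(
    list(
      thresholds = thresholds, sensitivity = sens, specificity = spec,
      auc = auc, cutoff = thresholds[best],
      sens_at_cutoff = sens[best], spec_at_cutoff = spec[best],
      youden = j[best],
      n_pos = length(pos), n_neg = length(neg), direction = direction
    ),
    class = "svd_roc"
  )
}

#' @export
print.svd_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (n_pos %d, n_neg %d); Youden cutoff %s %g -> sensitivity %.3f, specificity %.3f\n",
    x$auc, x$n_pos, x$n_neg, x$direction, x$cutoff,
    x$sens_at_cutoff, x$spec_at_cutoff
  ))
  invisible(x)
}

#' Export an ROC curve as a tidy table
#' @param roc An `svd_roc`.
#' @return Tibble with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
roc_table <- function(roc) {
  tibble::tibble(
    threshold = roc$thresholds,
    sensitivity = roc$sensitivity,
    specificity = roc$specificity,
    youden = roc$sensitivity + roc$specificity - 1
  )
}
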