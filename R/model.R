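# Firth bias-reduced logistic regression: Newton scoring on the modified
# score U*(b) = X'(y - p + h (1/2 - p)), h the hat diagonal. Needed because
# maximum likelihood diverges under (quasi-)separation, a live risk with
# n = 29 and counts spanning 0-47.
firth_logistic <- function(X, y, maxit = 200L, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(info_inv)) {
      break
    }
    h <- w * rowSums((X %*% info_inv) * X)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    delta <- drop(info_inv %*% score)
    # step-halving keeps the penalized log-likelihood finite
    step <- 1
    repeat {
      eta_new <- drop(X %*% (beta + step * delta))
      if (all(is.finite(eta_new)) && max(abs(eta_new)) < 30) break
      step <- step / 2
      if (step < 1e-6) break
    }
    beta <- beta + step * delta
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w)
  se <- sqrt(diag(solve(info)))
  list(coefficients = beta, se = se, converged = converged)
}

#' Logistic regression of one-year CDR worsening
#'
#' Fits a logistic model of the binary outcome "CDR worsened (1) vs stable
#' (0)" on the supplied covariates and reports, per covariate, the
#' coefficient B, its standard error, the Wald chi-square, the p-value, the
#' odds ratio `exp(B)`, and the 95% Wald confidence interval for the odds
#' ratio. Rows with any missing value are dropped (complete-case analysis).
#'
#' Maximum likelihood is the default; when the ML fit fails to converge or
#' shows separation (fitted probabilities numerically 0 or 1), the function
#' falls back to Firth's bias-reduced fit and flags the fallback — it never
#' silently reports a diverged fit. `method = "firth"` requests the penalized
#' fit directly. Covariates with zero variance are aliased: reported with
#' coefficient 0 and odds ratio 1 and flagged.
#'
#' @param covariates A data frame of numeric covariate columns (one row per
#'   patient).
#' @param outcome Binary vector (0/1 or logical) of the same length; both
#'   classes must be present.
#' @param method `"ml"` or `"firth"`.
#' @param conf_level Confidence level of the odds-ratio interval.
#' @return An object of class `svd_logistic_fit`: a list with `coefficients`
#'   (a tibble with `term`, `estimate`, `std_error`, `wald_chisq`, `p_value`,
#'   `odds_ratio`, `or_lower`, `or_upper`, `aliased`), `method` (the method
#'   actually used), `converged`, `separation`, `fallback`, and `n`.
#' @export
fit_cdr_change_model <- function(covariates, outcome,
                                 method = c("ml", "firth"),
                                 conf_level = 0.95) {
  method <- match.arg(method)
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 1) {
    abort_domain("fit_cdr_change_model() needs at least one covariate")
  }
  outcome <- as.integer(as.logical(outcome))
  if (length(outcome) != nrow(covariates)) {
    abort_domain("outcome length must match covariate rows")
  }
  keep <- stats::complete.cases(covariates) & !is.na(outcome)
  covariates <- covariates[keep, , drop = FALSE]
  y <- outcome[keep]
  if (length(unique(y)) < 2) {
    abort_domain("outcome must contain both classes after complete-case filtering")
  }

  terms <- names(covariates)
  aliased <- vapply(covariates, function(v) stats::var(v) == 0, logical(1))
  active <- terms[!aliased]
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates[, active, drop = FALSE]))

  separation <- FALSE
  fallback <- FALSE
  used <- method
  if (method == "ml") {
    warned <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial()),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    separation <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
    if (!fit$converged || separation || warned) {
      fallback <- TRUE
      used <- "firth"
    } else {
      est <- fit$coefficients
      cov_mat <- tryCatch(
        chol2inv(chol(crossprod(X, X * (fit$weights)))),
        error = function(e) NULL
      )
      if (is.null(cov_mat)) {
        fallback <- TRUE
        used <- "firth"
      } else {
        se <- sqrt(diag(cov_mat))
        converged <- TRUE
      }
    }
  }
  if (used == "firth") {
    ff <- firth_logistic(X, y)
    est <- ff$coefficients
    se <- ff$se
    converged <- ff$converged
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- tibble::tibble(
    term = c("(Intercept)", active),
    estimate = unname(est),
    std_error = unname(se),
    aliased = FALSE
  )
  if (any(aliased)) {
    tab <- dplyr::bind_rows(tab, tibble::tibble(
      term = terms[aliased], estimate = 0, std_error = NA_real_, aliased = TRUE
    ))
    tab <- tab[match(c("(Intercept)", terms), tab$term), ]
  }
  tab$wald_chisq <- (tab$estimate / tab$std_error)^2
  tab$p_value <- stats::pchisq(tab$wald_chisq, df = 1, lower.tail = FALSE)
  tab$odds_ratio <- exp(tab$estimate)
  tab$or_lower <- exp(tab$estimate - z * tab$std_error)
  tab$or_upper <- exp(tab$estimate + z * tab$std_error)
  tab <- tab[, c(
    "term", "estimate", "std_error", "wald_chisq", "p_value",
    "odds_ratio", "or_lower", "or_upper", "aliased"
  )]
  structure(
    list(
      coefficients = tab, method = used, converged = converged,
      separation = separation, fallback = fallback, n = length(y),
      conf_level = conf_level
    ),
    class = "svd_logistic_fit"
  )
}

#' @export
print.svd_logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic fit of CDR worsening (n = %d, method = %s%s%s)\n",
    x$n, x$method,
    if (x$fallback) ", ML fallback to Firth" else "",
    if (!x$converged) ", NOT CONVERGED" else ""
  ))
  print(x$coefficients)
  invisible(x)
}

#' Screen baseline variables for group differences
#'
#' First stage of the screen-then-model procedure: every candidate baseline
#' variable is compared between the CDR-stable and CDR-worsened groups with
#' [compare_groups()], and the variables significant at `alpha` are returned
#' as the covariate set for [fit_cdr_change_model()].
#'
#' @param cohort A cohort with both visits and CDR labels per patient.
#' @param candidates Character vector of cohort column names to screen
#'   (baseline values are used).
#' @param alpha Screening level (default 0.05).
#' @param gate Variance gate passed to [compare_groups()].
#' @return Character vector of selected variable names, with the full
#'   screening table (one row per candidate) as attribute `"screen"`.
#' @export
select_baseline_predictors <- function(cohort, candidates, alpha = 0.05,
                                       gate = "auto") {
  if (length(candidates) == 0) {
    out <- character()
    attr(out, "screen") <- comparison_table(list())
    return(out)
  }
  groups <- cdr_groups(cohort)
  base <- dplyr::filter(cohort, .data$visit == "baseline")
  base <- dplyr::left_join(base, groups[, c("patient_id", "group")], by = "patient_id")
  missing_cols <- setdiff(candidates, names(base))
  if (length(missing_cols) > 0) {
    abort_domain(paste0(
      "unknown candidate column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  results <- lapply(candidates, function(v) {
    compare_groups(
      base[[v]][base$group == "stable"],
      base[[v]][base$group == "worsened"],
      alpha = alpha, gate = gate, variable = v
    )
  })
  screen <- comparison_table(results)
  selected <- screen$variable[screen$significant]
  attr(selected, "screen") <- screen
  selected
}
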