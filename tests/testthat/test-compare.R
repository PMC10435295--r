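test_that("two-group comparison matches the closed-form pooled t on a hand case", {
  # a = {1,2,3}, b = {4,5,6}: pooled sd 1, se = sqrt(2/3), t = -3/se
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6), gate = "student")
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(round(r$statistic, 3), -3.674)
  expect_equal(r$p_value, 2 * stats::pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-10)
  expect_equal(round(r$p_value, 3), 0.021)
  expect_equal(r$df, 4)
  expect_equal(r$test, "student_t")
  expect_true(r$significant)
  # SE fields are SD / sqrt(n)
  expect_equal(r$se1, r$sd1 / sqrt(3))
})

test_that("identical groups give statistic 0 and p 1; degenerate data are flagged", {
  r <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  d <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  d2 <- compare_groups(c(2, 2, 2), c(5, 5, 5))
  expect_true(d2$degenerate)
  expect_equal(d2$p_value, 0)
  expect_error(compare_groups(1, c(1, 2)), class = "svdscores_insufficient_data_error")
})

test_that("the variance gate agrees with the reference Levene test and picks Welch under heteroscedasticity", {
  skip_if_not_installed("car")
  set.seed(101)
  for (i in 1:20) {
    a <- stats::rnorm(15)
    b <- stats::rnorm(12, sd = sample(c(1, 4), 1))
    r <- compare_groups(a, b)
    ref <- car::leveneTest(
      c(a, b), factor(rep(c("a", "b"), c(length(a), length(b)))),
      center = stats::median
    )
    expect_equal(r$gate_p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(r$test, if (ref$`Pr(>F)`[1] < 0.05) "welch_t" else "student_t")
  }
  # strongly unequal variances force the Welch branch
  set.seed(7)
  r <- compare_groups(stats::rnorm(50, sd = 1), stats::rnorm(50, sd = 10))
  expect_equal(r$test, "welch_t")
  expect_equal(r$gate_used, "levene_bf")
})

test_that("Student and Welch coincide for equal group sizes with equal sample variances", {
  a <- c(1, 2, 3, 4)
  b <- c(10, 11, 12, 13) # same spread, shifted
  s <- compare_groups(a, b, gate = "student")
  w <- compare_groups(a, b, gate = "welch")
  expect_equal(s$statistic, w$statistic, tolerance = 1e-12)
  expect_equal(s$df, w$df, tolerance = 1e-12)
})

test_that("paired comparison handles identity, constant shift, and a known power case", {
  r <- compare_paired(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)

  shift <- compare_paired(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_true(shift$degenerate)
  expect_true(is.na(shift$p_value))
  expect_match(shift$note, "increase")

  # analytic power oracle: diffs N(1, 1), n = 50; noncentral t with ncp sqrt(50)
  set.seed(202)
  n <- 50
  reps <- 2000
  rejected <- vapply(seq_len(reps), function(i) {
    b <- stats::rnorm(n)
    f <- b + stats::rnorm(n, mean = 1, sd = 1)
    compare_paired(b, f)$p_value < 0.05
  }, logical(1))
  crit <- stats::qt(0.975, df = n - 1)
  power <- 1 - stats::pt(crit, df = n - 1, ncp = sqrt(n)) +
    stats::pt(-crit, df = n - 1, ncp = sqrt(n))
  expect_equal(mean(rejected), power, tolerance = 0.02)

  # missing pairs are dropped and effective n reported
  r2 <- compare_paired(c(1, 2, NA, 4, 6), c(2, 1, 5, NA, 9))
  expect_equal(r2$n1, 3)
  expect_error(compare_paired(c(1, NA), c(NA, 2)),
    class = "svdscores_insufficient_data_error")
  expect_error(compare_paired(1:3, 1:4), class = "svdscores_domain_error")
})

test_that("proportion comparison switches to Fisher for small expected cells and matches enumeration", {
  # equal tables under Fisher give p = 1
  r <- compare_proportions(3, 10, 3, 10)
  expect_equal(r$test, "fisher_exact")
  expect_equal(r$p_value, 1)

  # 15/20 vs 6/9: direct hypergeometric enumeration of the two-sided Fisher p
  fisher_enum <- function(k1, n1, k2, n2) {
    k <- k1 + k2
    support <- max(0, k - n2):min(n1, k)
    probs <- stats::dhyper(support, n1, n2, k)
    p_obs <- stats::dhyper(k1, n1, n2, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  r2 <- compare_proportions(15, 20, 6, 9)
  expect_equal(r2$p_value, fisher_enum(15, 20, 6, 9), tolerance = 1e-9)
  expect_gt(r2$p_value, 0.05)

  # 0/10 vs 10/10: expected cells are exactly 5, so the corrected chi-square
  # branch applies and the difference is still overwhelming
  r3 <- compare_proportions(0, 10, 10, 10)
  expect_equal(r3$test, "chisq_corrected")
  expect_lt(r3$p_value, 0.001)

  # a genuinely sparse table (expected cells < 5) takes the Fisher branch
  r3b <- compare_proportions(1, 5, 4, 5)
  expect_equal(r3b$test, "fisher_exact")
  expect_equal(r3b$p_value, fisher_enum(1, 5, 4, 5), tolerance = 1e-9)

  # large balanced counts use the corrected chi-square
  r4 <- compare_proportions(40, 100, 60, 100)
  expect_equal(r4$test, "chisq_corrected")
  expect_equal(
    r4$p_value,
    suppressWarnings(stats::prop.test(c(40, 60), c(100, 100))$p.value)
  )
  expect_error(compare_proportions(5, 4, 1, 10), class = "svdscores_domain_error")
})

test_that("comparison_table flattens results into one row per comparison", {
  tab <- comparison_table(list(
    compare_groups(c(1, 2, 3), c(4, 5, 6), variable = "x"),
    compare_proportions(3, 10, 5, 10, variable = "y")
  ))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$variable, c("x", "y"))
  expect_true(all(c("statistic", "p_value", "significant", "gate_p") %in% names(tab)))

  # optional Holm adjustment recomputes the flags from adjusted p-values
  res <- lapply(1:4, function(i) {
    set.seed(500 + i)
    compare_groups(stats::rnorm(10), stats::rnorm(10), variable = paste0("v", i))
  })
  adj <- comparison_table(res, p_adjust = "holm")
  expect_equal(adj$p_adjusted, stats::p.adjust(adj$p_value, "holm"))
  expect_equal(adj$significant, adj$p_adjusted < 0.05)
})
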