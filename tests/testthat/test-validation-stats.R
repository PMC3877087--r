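two_group_matrix <- function(case_vals, ctrl_vals, assay = "a") {
  n1 <- length(case_vals); n2 <- length(ctrl_vals)
  cq <- matrix(c(case_vals, ctrl_vals), 1,
               dimnames = list(assay, c(paste0("x", 1:n1),
                                        paste0("y", 1:n2))))
  list(m = cq_matrix(cq),
       sheet = sample_sheet(colnames(cq),
                            rep(c("cancer", "control"), c(n1, n2))))
}

test_that("fold-change bounds are log2 of the cutoff", {
  expect_equal(fold_change_bound(2), 1)
  expect_equal(round(fold_change_bound(3), 2), 1.58)
  expect_error(fold_change_bound(1), "> 1")
})

test_that("group comparison separates shifted groups and not equal ones", {
  set.seed(61)
  g <- two_group_matrix(rnorm(20, 20, 0.1), rnorm(20, 30, 0.1))
  r <- compare_groups(g$m, g$sheet, "a")
  expect_lt(r$p_value, 1e-6)
  expect_equal(r$test, "welch_t")
  expect_equal(r$direction, -1)
  v <- rnorm(15, 22, 0.5)
  eq <- two_group_matrix(v, v)
  r2 <- compare_groups(eq$m, eq$sheet, "a")
  expect_equal(r2$p_value, 1)
  e2 <- equivalence_test(eq$m, eq$sheet, "a")
  expect_equal(e2$estimate, 0)
  expect_true(e2$equivalent_2fold && e2$equivalent)
})

test_that("the normality gate routes to Mann-Whitney for skewed data", {
  set.seed(62)
  x <- exp(rnorm(30, 0, 1.5))          # grossly lognormal
  y <- exp(rnorm(30, 0, 1.5)) + 1
  g <- two_group_matrix(x, y)
  r <- compare_groups(g$m, g$sheet, "a")
  expect_equal(r$test, "mann_whitney")
  set.seed(1062)
  g2 <- two_group_matrix(rnorm(30, 20, 1), rnorm(30, 20, 1))
  expect_equal(compare_groups(g2$m, g2$sheet, "a")$test, "welch_t")
})

test_that("null rejection rate is calibrated near alpha", {
  set.seed(63)
  rej <- 0
  n_seeds <- 300
  for (s in 1:n_seeds) {
    g <- two_group_matrix(rnorm(20, 20, 0.8), rnorm(20, 20, 0.8))
    rej <- rej + (compare_groups(g$m, g$sheet, "a")$p_value < 0.05)
  }
  expect_gt(rej / n_seeds, 0.02)
  expect_lt(rej / n_seeds, 0.08)
})

test_that("equivalence verdicts follow the CI against the bounds", {
  set.seed(64)
  # 2-cycle shift, tiny noise: CI ~ [-2.2, -1.8] on the expression scale
  g <- two_group_matrix(rnorm(20, 22, 0.2), rnorm(20, 20, 0.2))
  e <- equivalence_test(g$m, g$sheet, "a")
  expect_lt(abs(e$estimate + 2), 0.2)
  expect_false(e$equivalent)
  expect_false(e$equivalent_2fold)
  expect_true(e$ci_lower <= e$estimate && e$estimate <= e$ci_upper)
  # monotone in the bound: equivalent at b implies equivalent at b' > b
  set.seed(65)
  for (i in 1:20) {
    delta <- runif(1, 0, 2)
    g2 <- two_group_matrix(rnorm(15, 20 + delta, 0.5),
                           rnorm(15, 20, 0.5))
    e1 <- equivalence_test(g2$m, g2$sheet, "a", bound = 1)
    e2 <- equivalence_test(g2$m, g2$sheet, "a", bound = fold_change_bound(3))
    if (e1$equivalent) expect_true(e2$equivalent)
  }
})

test_that("tests are invariant to a global Cq shift", {
  set.seed(66)
  g <- two_group_matrix(rnorm(12, 21, 0.6), rnorm(12, 20.5, 0.6))
  r1 <- compare_groups(g$m, g$sheet, "a")
  e1 <- equivalence_test(g$m, g$sheet, "a")
  m2 <- cq_matrix(g$m$cq + 2.5)
  r2 <- compare_groups(m2, g$sheet, "a")
  e2 <- equivalence_test(m2, g$sheet, "a")
  expect_equal(r2$p_value, r1$p_value)
  expect_equal(e2$estimate, e1$estimate)
  expect_equal(e2$ci_lower, e1$ci_lower)
})

test_that("Bartlett comparison detects unequal assay variances", {
  set.seed(67)
  # equal sigma: null calibration near alpha
  rej <- 0
  for (s in 1:100) {
    cq <- rbind(a = rnorm(30, 20, 0.5), b = rnorm(30, 24, 0.5),
                c = rnorm(30, 28, 0.5))
    colnames(cq) <- paste0("s", 1:30)
    rej <- rej + (variance_homogeneity(cq_matrix(cq))$p_value < 0.05)
  }
  expect_lt(rej / 100, 0.12)
  # sigma ratio 3 at n = 60: essentially always rejected
  hits <- 0
  for (s in 1:20) {
    cq <- rbind(a = rnorm(60, 20, 0.3), b = rnorm(60, 24, 0.9))
    colnames(cq) <- paste0("s", 1:60)
    hits <- hits + (variance_homogeneity(cq_matrix(cq))$p_value < 0.05)
  }
  expect_gte(hits / 20, 0.95)
  # duplicated assay: statistic 0, p = 1
  cq <- rbind(a = rnorm(10, 20, 0.5))
  colnames(cq) <- paste0("s", 1:10)
  dup <- cq_matrix(rbind(a = cq[1, ], b = cq[1, ] + 1))
  vh <- variance_homogeneity(dup)
  expect_equal(vh$statistic, 0)
  expect_equal(vh$p_value, 1)
  # Bonferroni chi-square intervals bracket the sample SD
  expect_true(all(vh$sd_ci$ci_lower <= vh$sd_ci$sd &
                    vh$sd_ci$sd <= vh$sd_ci$ci_upper))
})
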