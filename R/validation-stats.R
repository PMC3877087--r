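#' Log2 equivalence bound for a fold-change cutoff
#'
#' A fold change of F on the linear scale corresponds to a +/- log2(F)
#' window on the log2 scale: 2-fold = +/-1, 3-fold = +/-1.58 (2 dp).
#'
#' @param fold fold-change cutoff (> 1).
#' @return log2(fold).
#' @export
fold_change_bound <- function(fold) {
  if (fold <= 1) stop("`fold` must be > 1")
  log2(fold)
}

# Normality p-value with estimated parameters: Lilliefors-corrected KS for
# n >= 5, Shapiro-Wilk for 3 <= n < 5, else 0 (forces the nonparametric arm).
normality_p <- function(x) {
  if (stats::sd(x) == 0) return(0)
  if (length(x) >= 5) return(nortest::lillie.test(x)$p.value)
  if (length(x) >= 3) return(stats::shapiro.test(x)$p.value)
  0
}

# Two-sample comparison with a normality gate: Welch t when both groups pass
# the gate at `alpha`, Mann-Whitney U otherwise.
compare_two_samples <- function(x, y, alpha = 0.05) {
  if (stats::sd(c(x, y)) == 0)  # degenerate: all values identical
    return(list(test = "degenerate", statistic = 0, p_value = 1,
                p_normal = c(0, 0)))
  p_norm <- c(normality_p(x), normality_p(y))
  if (all(p_norm > alpha)) {
    tt <- stats::t.test(x, y)
    list(test = "welch_t", statistic = unname(tt$statistic),
         p_value = tt$p.value, p_normal = p_norm)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    list(test = "mann_whitney", statistic = unname(wt$statistic),
         p_value = wt$p.value, p_normal = p_norm)
  }
}

#' Compare an assay's values between two groups
#'
#' Applies a per-group normality gate (Kolmogorov-Smirnov with estimated
#' parameters, i.e. Lilliefors, at `alpha`); when both groups pass, a Welch
#' two-sample t-test is used, otherwise a Mann-Whitney U test. Optionally
#' the values are log10-transformed first.
#'
#' @param m a `cq_matrix`.
#' @param sheet sample sheet with exactly two groups among `m`'s samples.
#' @param assay assay id to test.
#' @param log10_transform test log10 of the values instead (for positive
#'   quantities such as relative quantities; not meaningful for raw Cq).
#' @param alpha significance level for both the normality gate and the
#'   significance call.
#' @return one-row data.frame: assay, group labels and means, chosen test,
#'   per-group normality p-values, statistic, p_value, significant,
#'   direction (sign of group1 mean - group2 mean).
#' @export
compare_groups <- function(m, sheet, assay, log10_transform = FALSE,
                           alpha = 0.05) {
  v <- assay_values(m, assay)
  grp <- groups_for(m, sheet)
  glev <- unique(grp)
  if (length(glev) != 2)
    stop("need exactly 2 groups, got: ", paste(glev, collapse = ", "))
  x <- v[grp == glev[1]]
  y <- v[grp == glev[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 detected samples per group")
  if (log10_transform) {
    if (any(c(x, y) <= 0)) stop("log10 transform needs positive values")
    x <- log10(x); y <- log10(y)
  }
  cmp <- compare_two_samples(x, y, alpha = alpha)
  data.frame(assay = assay, group1 = glev[1], group2 = glev[2],
             n1 = length(x), n2 = length(y),
             mean1 = mean(x), mean2 = mean(y),
             p_normal1 = cmp$p_normal[1], p_normal2 = cmp$p_normal[2],
             test = cmp$test, statistic = cmp$statistic,
             p_value = cmp$p_value, significant = cmp$p_value < alpha,
             direction = sign(mean(x) - mean(y)),
             stringsAsFactors = FALSE, row.names = NULL)
}

assay_values <- function(m, assay) {
  if (!assay %in% assay_ids(m)) stop("unknown assay: ", assay)
  m$cq[assay, ]
}

#' Equivalence test of group expression against fold-change bounds
#'
#' Tests whether two groups express an assay equivalently: the difference
#' of group means on the log2 expression scale (expression = -Cq, so a
#' positive estimate means higher abundance in group 1) is surrounded by a
#' symmetric two-sided Welch confidence interval, and the assay is declared
#' equivalent at a bound b when the whole interval lies within [-b, +b].
#' Verdicts are reported both at +/-1 (2-fold) and at +/-`bound`
#' (default log2(3) ~ 1.58, i.e. 3-fold). A 90% interval corresponds to a
#' TOST at the 5% level; the 95% default reports the conventional
#' symmetric interval.
#'
#' @inheritParams compare_groups
#' @param bound equivalence bound in log2 units (default `log2(3)`).
#' @param ci_level two-sided confidence level of the interval.
#' @return one-row data.frame: assay, estimate (log2 expression difference,
#'   group1 - group2), ci_lower, ci_upper, bound_2fold, bound tested,
#'   equivalent_2fold, equivalent (at `bound`), ci_level.
#' @export
equivalence_test <- function(m, sheet, assay, bound = fold_change_bound(3),
                             ci_level = 0.95) {
  v <- -assay_values(m, assay)  # log2 expression scale
  grp <- groups_for(m, sheet)
  glev <- unique(grp)
  if (length(glev) != 2)
    stop("need exactly 2 groups, got: ", paste(glev, collapse = ", "))
  x <- v[grp == glev[1]]; y <- v[grp == glev[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 detected samples per group")
  if (stats::sd(c(x, y)) == 0) {   # degenerate: no variation at all
    ci <- rep(mean(x) - mean(y), 2)
  } else {
    tt <- stats::t.test(x, y, conf.level = ci_level)
    ci <- unname(tt$conf.int)
  }
  eq_at <- function(b) ci[1] >= -b && ci[2] <= b
  data.frame(assay = assay, group1 = glev[1], group2 = glev[2],
             estimate = mean(x) - mean(y), ci_lower = ci[1],
             ci_upper = ci[2], ci_level = ci_level,
             bound_2fold = 1, equivalent_2fold = eq_at(1),
             bound = bound, equivalent = eq_at(bound),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Variance homogeneity across assays
#'
#' Bartlett's test of equal variances across the given assays' Cq
#' distributions (pooling all samples), plus per-assay SDs with
#' Bonferroni-adjusted chi-square confidence intervals (each interval at
#' level 1 - alpha/m, so the family holds jointly at 1 - alpha).
#'
#' @param m a `cq_matrix`.
#' @param assays assay ids to compare (>= 2).
#' @param alpha family-wise error rate for the SD intervals.
#' @return list with `statistic`, `df`, `p_value` (Bartlett), and `sd_ci`
#'   (data.frame: assay, n, sd, ci_lower, ci_upper, conf_level).
#' @export
variance_homogeneity <- function(m, assays = assay_ids(m), alpha = 0.05) {
  if (length(assays) < 2) stop("need >= 2 assays")
  vals <- lapply(assays, function(a) {
    v <- assay_values(m, a)
    v[!is.na(v)]
  })
  if (any(lengths(vals) < 3)) stop("need >= 3 detected samples per assay")
  bt <- stats::bartlett.test(vals)
  mtests <- length(assays)
  a_adj <- alpha / mtests
  sd_ci <- do.call(rbind, Map(function(a, v) {
    n <- length(v)
    s2 <- stats::var(v)
    lo <- sqrt((n - 1) * s2 / stats::qchisq(1 - a_adj / 2, n - 1))
    hi <- sqrt((n - 1) * s2 / stats::qchisq(a_adj / 2, n - 1))
    data.frame(assay = a, n = n, sd = sqrt(s2), ci_lower = lo,
               ci_upper = hi, conf_level = 1 - a_adj,
               stringsAsFactors = FALSE)
  }, assays, vals))
  rownames(sd_ci) <- NULL
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p_value = bt$p.value, sd_ci = sd_ci)
}
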