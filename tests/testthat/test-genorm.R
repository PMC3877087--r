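qmat <- function(cq_mat) to_relative_quantity(cq_matrix(cq_mat))

test_that("relative quantities follow the efficiency power law", {
  cq <- rbind(a = c(20, 21, 22))
  colnames(cq) <- paste0("s", 1:3)
  m <- cq_matrix(cq)
  q <- to_relative_quantity(m)            # E = 100, anchor = min
  expect_equal(unname(q["a", ]), c(1, 0.5, 0.25))
  q90 <- to_relative_quantity(m, efficiency = 90)
  expect_equal(unname(q90["a", 3]), 1.9^-2)
  expect_equal(unname(q90["a", 3]), 0.27701, tolerance = 1e-5)
  cq[1, 2] <- NA
  expect_error(to_relative_quantity(cq_matrix(cq)), "undetected")
})

test_that("pairwise variation is the SD of log ratios", {
  q <- rbind(j = c(2, 8), k = c(1, 1))
  colnames(q) <- c("s1", "s2")
  expect_equal(pairwise_variation(q, "j", "k"), sd(c(1, 3)))
  expect_equal(pairwise_variation(q, "j", "k"), sqrt(2), tolerance = 1e-9)
  # proportional assays: V = 0
  q2 <- rbind(j = c(1, 2, 5), k = 3 * c(1, 2, 5))
  colnames(q2) <- paste0("s", 1:3)
  expect_equal(pairwise_variation(q2, "j", "k"), 0)
  # per-sample scaling cancels
  q3 <- rbind(j = runif(4, 1, 2), k = runif(4, 1, 2))
  colnames(q3) <- paste0("s", 1:4)
  scl <- sweep(q3, 2, c(1, 10, 0.5, 2), "*")
  expect_equal(pairwise_variation(scl, "j", "k"),
               pairwise_variation(q3, "j", "k"))
})

test_that("stability M matches its definition and the oracle", {
  q0 <- rbind(a = c(1, 2, 4), b = 2 * c(1, 2, 4), c = 0.5 * c(1, 2, 4))
  colnames(q0) <- paste0("s", 1:3)
  expect_equal(unname(stability_m(q0)), rep(0, 3))
  set.seed(41)
  for (i in 1:25) {
    q <- matrix(2^runif(4 * 6, -3, 3), 4, 6,
                dimnames = list(letters[1:4], paste0("s", 1:6)))
    expect_equal(stability_m(q), oracle_stability_m(q))
  }
  # two assays share M = V_jk
  q2 <- q0[1:2, ]
  m2 <- stability_m(q2)
  expect_equal(unname(m2), rep(pairwise_variation(q2, "a", "b"), 2))
})

test_that("stepwise ranking eliminates the noisiest assay and is stable
           under reordering", {
  set.seed(42)
  spec <- cohort_spec(data.frame(
    assay_id = c("A", "B", "C"), baseline = c(16, 20, 24),
    sigma = c(0.05, 0.05, 1.0), delta = 0),
    n_case = 8, n_control = 8, n_replicates = 1)
  d <- generate_cohort(spec, seed = 420)
  gr <- stepwise_ranking(to_relative_quantity(d$cq))
  expect_equal(gr$final_pair, c("A", "B"))
  expect_equal(gr$rounds$eliminated, "C")
  # permutation invariance
  q <- to_relative_quantity(d$cq)
  gr2 <- stepwise_ranking(q[c(3, 1, 2), ])
  expect_equal(gr2$ranking, gr$ranking)
  expect_equal(gr2$final_m, gr$final_m)
  # final two assays report equal M at the last round
  last <- gr$m_by_round[[length(gr$m_by_round)]]
  expect_equal(unname(last[1]), unname(last[2]))
})

test_that("a high-noise assay is eliminated first in almost all cohorts", {
  hits <- 0
  n_seeds <- 100
  for (s in 1:n_seeds) {
    spec <- cohort_spec(data.frame(
      assay_id = c(paste0("ok", 1:6), "noisy"),
      baseline = seq(16, 28, 2),
      sigma = c(rep(0.2, 6), 1.5), delta = 0),
      n_case = 5, n_control = 5, n_replicates = 1)
    d <- generate_cohort(spec, seed = 4200 + s)
    gr <- stepwise_ranking(to_relative_quantity(d$cq))
    hits <- hits + (gr$rounds$eliminated[1] == "noisy")
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("V series matches the oracle and flags uninformative additions", {
  set.seed(43)
  for (i in 1:20) {
    q <- matrix(2^runif(5 * 8, -2, 2), 5, 8,
                dimnames = list(letters[1:5], paste0("s", 1:8)))
    gr <- stepwise_ranking(q)
    v <- optimal_ec_count(q, gr)
    expect_equal(v$v$v, oracle_v_series(q, gr$ranking))
    # recommendation rule: first below cutoff, else argmin
    below <- which(v$v$v < v$v_cutoff)
    expected_n <- if (length(below)) v$v$n[below[1]]
                  else v$v$n[which.min(v$v$v)]
    expect_equal(v$recommended_n, expected_n)
  }
  # an assay proportional to NF_n adds no information: V = 0
  q3 <- matrix(2^runif(3 * 6, -2, 2), 3, 6,
               dimnames = list(c("A", "B", "C"), paste0("s", 1:6)))
  d_col <- apply(q3, 2, function(col) prod(col)^(1 / 3))
  q4 <- rbind(q3, D = 5 * d_col)
  fake <- structure(list(ranking = c("A", "B", "C", "D")),
                    class = "genorm_result")
  v4 <- optimal_ec_count(q4, fake)
  expect_equal(v4$v$v[v4$v$n == 3], 0)
})

test_that("geNorm outputs are invariant to per-sample scaling and anchor", {
  set.seed(44)
  m <- random_cq(5, 8, 18, 28)
  q1 <- to_relative_quantity(m, anchor = "min")
  q2 <- to_relative_quantity(m, anchor = "mean")
  expect_equal(stability_m(q1), stability_m(q2))
  gr1 <- stepwise_ranking(q1)
  gr2 <- stepwise_ranking(q2)
  expect_equal(gr1$ranking, gr2$ranking)
  expect_equal(optimal_ec_count(q1, gr1)$v, optimal_ec_count(q2, gr2)$v)
  # per-sample additive Cq shift (= per-sample scaling of quantities)
  m3 <- cq_matrix(sweep(m$cq, 2, runif(8, -2, 2), "+"))
  q3 <- to_relative_quantity(m3)
  expect_equal(stability_m(q3), stability_m(q1))
  gr3 <- stepwise_ranking(q3)
  expect_equal(gr3$ranking, gr1$ranking)
  expect_equal(optimal_ec_count(q3, gr3)$v, optimal_ec_count(q1, gr1)$v)
})
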