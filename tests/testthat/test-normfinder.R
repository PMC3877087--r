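nf_cohort <- function(sigmas, deltas, seed, n_case = 20, n_control = 20,
                      tau = 0.5, sigma_rep = 0) {
  spec <- cohort_spec(data.frame(
    assay_id = paste0("g", seq_along(sigmas)),
    baseline = seq(16, by = 2, length.out = length(sigmas)),
    sigma = sigmas, delta = deltas), n_case = n_case,
    n_control = n_control, tau = tau, sigma_rep = sigma_rep,
    n_replicates = 1)
  generate_cohort(spec, seed = seed)
}

test_that("stability is zero for a noise-free cohort and minimal for a
           constant-z gene", {
  d <- nf_cohort(c(0, 0, 0), c(0, 0, 0), seed = 51, tau = 0)
  nf <- normfinder_stability(d$cq, d$samples)
  expect_equal(nf$stability$rho, rep(0, 3))
  # one near-noiseless gene among noisy ones ranks most stable
  d2 <- nf_cohort(c(0.02, 0.6, 0.6, 0.6), c(0, 0, 0, 0), seed = 52)
  nf2 <- normfinder_stability(d2$cq, d2$samples)
  expect_equal(nf2$best_single, "g1")
})

test_that("stability is invariant to sample shifts and assay location", {
  d <- nf_cohort(c(0.2, 0.4, 0.6, 0.3), c(0, 0.5, 0, 0), seed = 53)
  nf <- normfinder_stability(d$cq, d$samples)
  shift <- runif(ncol(d$cq$cq), -2, 2)
  m2 <- cq_matrix(sweep(d$cq$cq, 2, shift, "+"))
  nf2 <- normfinder_stability(m2, d$samples)
  expect_equal(nf2$stability, nf$stability)
  # adding a constant to one assay's Cq everywhere changes nothing
  cq3 <- d$cq$cq
  cq3["g2", ] <- cq3["g2", ] + 3
  nf3 <- normfinder_stability(cq_matrix(cq3), d$samples)
  expect_equal(nf3$stability, nf$stability)
})

test_that("group-bias centering and preconditions hold", {
  d <- nf_cohort(c(0.3, 0.3, 0.3, 0.3), c(0, 1, 0, 0), seed = 54)
  nf <- normfinder_stability(d$cq, d$samples)
  expect_equal(unname(rowSums(nf$d)), rep(0, 4))  # equal-weight centering
  expect_true(all(nf$sigma2 >= 0))
  expect_error(normfinder_stability(cq_subset(d$cq, assays = c("g1", "g2")),
                                    d$samples), ">= 3")
  # single group: rho reduces to sqrt(gene variance)
  nf1 <- normfinder_stability(d$cq, sheet = NULL)
  expect_equal(nf1$stability$rho[order(nf1$stability$assay)],
               unname(sqrt(nf1$sigma2[order(rownames(nf1$sigma2)), 1])))
})

test_that("a group-biased assay ranks least stable", {
  hits <- 0
  n_seeds <- 100
  for (s in 1:n_seeds) {
    d <- nf_cohort(rep(0.25, 5), c(0, 0, 0, 0, 1), seed = 540 + s)
    nf <- normfinder_stability(d$cq, d$samples)
    hits <- hits + (nf$stability$assay[nf$stability$rank == 5] == "g5")
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("opposite group biases cancel in a pair", {
  d <- nf_cohort(c(0.2, 0.2, 0.2, 0.2), c(0.8, -0.8, 0, 0), seed = 55)
  nf <- normfinder_stability(d$cq, d$samples)
  bp <- best_pair(nf)
  tab <- bp$all_pairs
  s12 <- tab$stability[tab$assay1 == "g1" & tab$assay2 == "g2"]
  rho <- setNames(nf$stability$rho, nf$stability$assay)
  expect_lt(s12, rho["g1"])
  expect_lt(s12, rho["g2"])
})

test_that("pair search matches enumeration and the duplicate-gene
           closed form", {
  d <- nf_cohort(c(0.2, 0.4, 0.5, 0.3), c(0, 0.4, 0, 0), seed = 56)
  nf <- normfinder_stability(d$cq, d$samples)
  expect_equal(best_pair(nf)$all_pairs[, c("assay1", "assay2")],
               oracle_pair_table(nf)[order(oracle_pair_table(nf)$stability),
                                     c("assay1", "assay2")],
               ignore_attr = TRUE)
  expect_equal(sort(best_pair(nf)$all_pairs$stability),
               sort(oracle_pair_table(nf)$stability))
  # duplicated gene: pair (g1, dup) has g1's bias with halved variance
  cq_dup <- rbind(d$cq$cq, dup = d$cq$cq["g1", ])
  nfd <- normfinder_stability(cq_matrix(cq_dup), d$samples)
  tab <- best_pair(nfd)$all_pairs
  got <- tab$stability[tab$assay1 == "dup" & tab$assay2 == "g1" |
                         tab$assay1 == "g1" & tab$assay2 == "dup"]
  se2_half <- nfd$se["g1", ]^2 / 2
  shr <- nfd$tau2 / (nfd$tau2 + se2_half)
  expect_equal(got,
               mean(abs(nfd$d["g1", ] * shr) + sqrt(se2_half)))
})

test_that("variance estimates recover the generating sigma^2", {
  est <- truth <- NULL
  for (s in 1:30) {
    sig <- c(0.3, 0.45, 0.6, 0.75, 0.9)
    d <- nf_cohort(sig, rep(0, 5), seed = 560 + s)
    nf <- normfinder_stability(d$cq, d$samples)
    est <- rbind(est, as.numeric(nf$sigma2))
    truth <- rbind(truth, rep(sig^2, 2))
  }
  med <- apply(est, 2, median)
  rel <- abs(med - truth[1, ]) / truth[1, ]
  expect_lt(median(rel), 0.25)
})

test_that("geNorm and NormFinder usually agree without group effects", {
  agree <- 0
  n_seeds <- 50
  for (s in 1:n_seeds) {
    d <- nf_cohort(c(0.15, 0.3, 0.5, 0.7), rep(0, 4), seed = 5600 + s)
    nf <- normfinder_stability(d$cq, d$samples)
    gr <- stepwise_ranking(to_relative_quantity(d$cq))
    agree <- agree + (nf$best_single %in% gr$final_pair)
  }
  expect_gte(agree / n_seeds, 0.8)
})
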