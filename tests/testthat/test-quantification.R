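test_that("efficiency estimation reproduces the closed forms", {
  fit <- estimate_efficiency(generate_dilution_series(100, anchor_cq = 22))
  expect_equal(fit$slope, -3.3219, tolerance = 1e-4)
  expect_equal(fit$efficiency, 100, tolerance = 1e-6)
  expect_true(fit$accepted)
  expect_equal(fit$r_squared, 1)
  f36 <- estimate_efficiency(data.frame(log10_input = -(0:4),
                                        cq = 20 + 3.6 * (0:4)))
  expect_equal(f36$slope, -3.6)
  expect_equal(f36$efficiency, 89.6, tolerance = 1e-2)
  expect_false(f36$accepted)
  f31 <- estimate_efficiency(data.frame(log10_input = -(0:4),
                                        cq = 20 + 3.1 * (0:4)))
  expect_equal(f31$efficiency, 110.1, tolerance = 0.05)
  expect_false(f31$accepted)
  expect_error(estimate_efficiency(data.frame(log10_input = rep(0, 3),
                                              cq = c(20, 21, 22))),
               "zero variance")
})

test_that("delta-delta-Cq follows the comparative formula", {
  expect_equal(delta_delta_ct(20, 18, 20, 18), 0)
  # target drops one cycle, ECs unchanged: ddCq = -1, RQ = 2
  dd <- delta_delta_ct(19, 18, 20, 18)
  expect_equal(dd, -1)
  expect_equal(2^-dd, 2)
  # multi-EC term is the arithmetic mean of the ECs' Cq
  expect_equal(delta_delta_ct(20, c(15, 21), 22, c(16, 22)),
               (20 - 18) - (22 - 19))
  expect_equal(delta_delta_ct(20, c(15, 15), 22, c(16, 16)),
               delta_delta_ct(20, 15, 22, 16))
  expect_error(delta_delta_ct(20, NA, 22, 16), "present")
})

test_that("relative quantities agree with ddCq and the closed-form
           oracle", {
  set.seed(71)
  m <- random_cq(4, 6, 16, 26)
  rownames(m$cq) <- rownames(m$detected) <- c("t1", "t2", "e1", "e2")
  rq <- relative_quantities(m, "t1", "e1", calibrator = "S1")
  for (j in sample_ids(m)) {
    dd <- delta_delta_ct(m$cq["t1", j], m$cq["e1", j],
                         m$cq["t1", "S1"], m$cq["e1", "S1"])
    expect_equal(rq$rq[rq$sample == j], 2^-dd)
  }
  expect_equal(rq$rq[rq$sample == "S1"], 1)  # self-calibration
  # duplicated EC in the strategy is idempotent
  rq2 <- relative_quantities(m, "t1", c("e1", "e1"), calibrator = "S1")
  expect_equal(rq2$rq, rq$rq)
  # efficiency-corrected closed form on random inputs
  eff <- c(t1 = 92, t2 = 104, e1 = 98, e2 = 107)
  rq3 <- relative_quantities(m, c("t1", "t2"), c("e1", "e2"),
                             efficiency = eff, calibrator = "S2")
  for (t in c("t1", "t2")) {
    expected <- oracle_rq(m$cq, t, c("e1", "e2"), eff, m$cq[, "S2"])
    expect_equal(rq3$rq[rq3$target == t], unname(expected))
  }
})

test_that("RQ is invariant to per-sample loading shifts at equal
           efficiency", {
  set.seed(72)
  m <- random_cq(3, 8, 16, 26)
  rownames(m$cq) <- rownames(m$detected) <- c("t", "e1", "e2")
  shift <- runif(8, -2, 2)
  m2 <- cq_matrix(sweep(m$cq, 2, shift, "+"))
  rq1 <- relative_quantities(m, "t", c("e1", "e2"), calibrator = "S3")
  rq2 <- relative_quantities(m2, "t", c("e1", "e2"), calibrator = "S3")
  expect_equal(rq2$rq, rq1$rq)
})

test_that("control-mean calibrator and error paths behave", {
  d <- generate_cohort(headline_cohort_spec(), seed = 73)
  rq <- relative_quantities(d$cq, "miR-93", "miR-16", sheet = d$samples)
  expect_equal(attr(rq, "calibrator"), "mean(control)")
  expect_true(all(rq$rq > 0))
  expect_error(relative_quantities(d$cq, "miR-93", "nope",
                                   sheet = d$samples), "not in matrix")
  expect_error(relative_quantities(d$cq, "miR-93", "miR-16",
                                   calibrator = "ghost"), "ghost")
})

test_that("EC-strategy sensitivity reproduces the biased-EC artifact", {
  flips <- strong <- 0
  n_seeds <- 60
  for (s in 1:n_seeds) {
    d <- generate_cohort(headline_cohort_spec(), seed = 7300 + s)
    res <- ec_sensitivity_experiment(
      d$cq, d$samples, c("miR-93", "miR-652"),
      list(U6 = "U6", pair = c("miR-16", "miR-425")))
    flips <- flips + (res$p_values["miR-93", "U6"] < 0.05 &&
                        res$p_values["miR-93", "pair"] >= 0.05)
    strong <- strong + all(res$p_values["miR-652", ] < 0.05)
  }
  expect_gte(flips / n_seeds, 0.75)
  expect_gte(strong / n_seeds, 0.95)
  # identical strategies give identical columns
  d <- generate_cohort(headline_cohort_spec(), seed = 74)
  res2 <- ec_sensitivity_experiment(d$cq, d$samples, "miR-93",
                                    list(a = "miR-16", b = "miR-16"))
  expect_equal(res2$p_values[, "a"], res2$p_values[, "b"])
})
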