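reps_df <- function(cqs, sample = "s1", assay = "a1", plate = "P1") {
  data.frame(sample = sample, assay = assay,
             replicate = seq_along(cqs), plate = plate, cq = cqs,
             stringsAsFactors = FALSE)
}

test_that("replicate collapsing keeps tight sets and excludes noisy ones", {
  reps <- rbind(reps_df(c(20, 20, 20), assay = "a1"),
                reps_df(c(20, 20, 21), assay = "a2"),
                reps_df(c(15.40, 15.52), assay = "a3"))
  out <- collapse_replicates(reps, sd_max = 0.28)
  qc <- out$qc
  expect_equal(qc$status[qc$assay == "a1"], "pass")
  expect_equal(qc$mean_cq[qc$assay == "a1"], 20)
  expect_equal(qc$sd_cq[qc$assay == "a1"], 0)
  # sd(c(20,20,21)) = 0.5774 > 0.28: flagged and excluded
  expect_equal(qc$status[qc$assay == "a2"], "flagged")
  expect_equal(qc$sd_cq[qc$assay == "a2"], 0.57735, tolerance = 1e-4)
  expect_true(is.na(out$cq$cq["a2", "s1"]))
  # sd(c(15.40,15.52)) = 0.0849 <= 0.28: mean retained
  expect_equal(qc$status[qc$assay == "a3"], "pass")
  expect_equal(out$cq$cq["a3", "s1"], 15.46)
  expect_error(collapse_replicates(reps[0, ]), "non-empty")
})

test_that("no collapsed cell ever exceeds the replicate-SD gate", {
  set.seed(21)
  for (rep_i in 1:20) {
    reps <- do.call(rbind, lapply(1:6, function(i)
      reps_df(rnorm(3, 20, 0.4), sample = paste0("s", i %% 2),
              assay = paste0("a", i))))
    out <- collapse_replicates(reps, sd_max = 0.28)
    for (r in which(out$qc$status == "flagged"))
      expect_true(is.na(out$cq$cq[out$qc$assay[r], out$qc$sample[r]]))
    for (r in which(out$qc$status == "pass"))
      expect_lte(out$qc$sd_cq[r], 0.28)
  }
})

test_that("IAC calibration removes between-plate offsets only", {
  # two plates whose IAC means are 18.2 and 18.8 -> offsets -0.3 and +0.3
  cq <- rbind(IAC = c(18.1, 18.3, 18.7, 18.9),
              t1  = c(20.0, 21.0, 22.0, 23.0))
  colnames(cq) <- paste0("s", 1:4)
  m <- cq_matrix(cq)
  plates <- c(s1 = "P1", s2 = "P1", s3 = "P2", s4 = "P2")
  out <- apply_iac_calibration(m, plates)
  cal <- attr(out, "calibration")
  expect_equal(cal$offset, c(-0.3, 0.3))
  expect_equal(sum(cal$offset * cal$n_samples), 0)
  expect_equal(unname(out$cq["t1", ]), c(20.3, 21.3, 21.7, 22.7))
  expect_false("IAC" %in% assay_ids(out))
  # within-plate contrasts unchanged
  expect_equal(out$cq["t1", "s2"] - out$cq["t1", "s1"], 1)
  # single plate: identity
  one <- apply_iac_calibration(m, c(s1 = "P1", s2 = "P1", s3 = "P1",
                                    s4 = "P1"))
  expect_equal(one$cq["t1", ], m$cq["t1", ])
  expect_error(apply_iac_calibration(m, c(s1 = "P1", s2 = "P1")),
               "plate")
})

test_that("within-plate shift invariance holds on random matrices", {
  set.seed(22)
  m <- random_cq(4, 8)
  rownames(m$cq)[1] <- rownames(m$detected)[1] <- "IAC"
  plates <- setNames(rep(c("P1", "P2"), each = 4), sample_ids(m))
  out <- apply_iac_calibration(m, plates)
  for (p in c("P1", "P2")) {
    cols <- names(plates)[plates == p]
    before <- m$cq[-1, cols]
    after <- out$cq[, cols]
    expect_equal(sweep(after, 1, after[, 1]), sweep(before, 1, before[, 1]))
  }
})

test_that("assay summaries compute range = max - min and group rows", {
  cq <- rbind("miR-16" = c(13.565, 15.2, 16.0, 18.765),
              "flat"   = rep(21, 4))
  colnames(cq) <- paste0("s", 1:4)
  m <- cq_matrix(cq)
  s <- summarize_assays(m)
  r <- s[s$assay == "miR-16", ]
  expect_equal(r$min_cq, 13.565)
  expect_equal(r$max_cq, 18.765)
  expect_equal(round(r$range_cq, 3), 5.2)
  f <- s[s$assay == "flat", ]
  expect_equal(f$sd_cq, 0)
  expect_equal(f$range_cq, 0)
  sheet <- sample_sheet(paste0("s", 1:4), c("cancer", "cancer",
                                            "control", "control"))
  sg <- summarize_assays(m, sheet)
  expect_setequal(unique(sg$group), c("all", "cancer", "control"))
})

test_that("summary range is non-negative and SD shift-invariant", {
  set.seed(23)
  m <- random_cq(6, 10)
  s1 <- summarize_assays(m)
  expect_true(all(s1$range_cq >= 0))
  expect_equal(s1$range_cq, s1$max_cq - s1$min_cq)
  m2 <- cq_matrix(m$cq + 3, max_cycles = 50)
  s2 <- summarize_assays(m2)
  expect_equal(s2$sd_cq, s1$sd_cq)
  expect_equal(s2$range_cq, s1$range_cq)
})
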