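# Independent brute-force oracles, deliberately written as plain two-pass
# loops so they share no code path with the package implementations.

# random cq_matrix with no structure
random_cq <- function(n_assays, n_samples, lo = 15, hi = 30) {
  cq <- matrix(runif(n_assays * n_samples, lo, hi), n_assays, n_samples,
               dimnames = list(paste0("A", seq_len(n_assays)),
                               paste0("S", seq_len(n_samples))))
  cq_matrix(cq)
}

# GME deviation scores by naive recomputation
oracle_gme_scores <- function(cq, cutoff = 35) {
  gm <- numeric(ncol(cq))
  for (j in seq_len(ncol(cq))) {
    v <- cq[, j]
    gm[j] <- mean(v[!is.na(v) & v < cutoff])
  }
  scores <- rep(NA_real_, nrow(cq))
  for (i in seq_len(nrow(cq))) {
    if (any(is.na(cq[i, ]) | cq[i, ] >= cutoff)) next
    d <- cq[i, ] - gm
    scores[i] <- sqrt(sum((d - mean(d))^2) / (length(d) - 1))
  }
  names(scores) <- rownames(cq)
  scores
}

# geNorm M by naive recomputation
oracle_stability_m <- function(q) {
  n <- nrow(q)
  m <- numeric(n)
  for (j in seq_len(n)) {
    vs <- c()
    for (k in seq_len(n)) {
      if (k == j) next
      r <- log2(q[j, ] / q[k, ])
      vs <- c(vs, sqrt(sum((r - mean(r))^2) / (length(r) - 1)))
    }
    m[j] <- mean(vs)
  }
  names(m) <- rownames(q)
  m
}

# V_{n/n+1} series by naive recomputation, for a given stability order
oracle_v_series <- function(q, ord) {
  out <- numeric(0)
  for (n in 2:(length(ord) - 1)) {
    nf_n <- apply(q[ord[1:n], , drop = FALSE], 2,
                  function(col) prod(col)^(1 / n))
    nf_n1 <- apply(q[ord[1:(n + 1)], , drop = FALSE], 2,
                   function(col) prod(col)^(1 / (n + 1)))
    r <- log2(nf_n / nf_n1)
    out <- c(out, sqrt(sum((r - mean(r))^2) / (length(r) - 1)))
  }
  out
}

# NormFinder pair stability recomputed from a fitted result's components,
# independently of best_pair()'s vectorized search
oracle_pair_table <- function(nf) {
  assays <- rownames(nf$sigma2)
  out <- NULL
  for (i in seq_along(assays)) {
    for (l in seq_along(assays)) {
      if (l <= i) next
      if (is.null(nf$d)) {
        s <- mean(sqrt((nf$sigma2[i, ] + nf$sigma2[l, ]) / 4))
      } else {
        vals <- numeric(0)
        for (g in colnames(nf$d)) {
          d_p <- (nf$d[i, g] + nf$d[l, g]) / 2
          se2_p <- (nf$se[i, g]^2 + nf$se[l, g]^2) / 4
          d_sh <- d_p * nf$tau2 / (nf$tau2 + se2_p)
          vals <- c(vals, abs(d_sh) + sqrt(se2_p))
        }
        s <- mean(vals)
      }
      out <- rbind(out, data.frame(assay1 = assays[i], assay2 = assays[l],
                                   stability = s))
    }
  }
  out
}

# efficiency-corrected RQ by direct evaluation of the closed form
oracle_rq <- function(cq, target, ecs, eff, cal_cq) {
  K <- length(ecs)
  sapply(colnames(cq), function(j) {
    num <- (1 + eff[target] / 100)^(cal_cq[target] - cq[target, j])
    den <- 1
    for (k in ecs)
      den <- den * ((1 + eff[k] / 100)^(cal_cq[k] - cq[k, j]))^(1 / K)
    num / den
  })
}
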