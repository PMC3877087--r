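#' Model-based (NormFinder-style) stability estimation
#'
#' Fits an additive decomposition of log2 expression into gene, sample and
#' group effects and scores each candidate by the sum of its estimated
#' inter-group bias and intra-group variability (lower = more stable):
#'
#' 1. Cq values are expressed as log2 quantities `y = -Cq` (one cycle = one
#'    log2 unit at 100% efficiency; any per-assay constant cancels).
#' 2. Sample effects are removed exactly by subtracting each sample's mean
#'    over the k candidates, giving `z`.
#' 3. Per group g the gene variances `sigma2_ig` are estimated from all
#'    pairwise gene differences: `Var(y_i - y_l) = sigma2_i + sigma2_l`
#'    exactly, since the shared sample effect (and the sample-mean noise
#'    that deflates variances computed from `z`) cancels in every
#'    difference. The k variances are recovered from the k(k-1)/2
#'    observed pairwise variances by iteratively reweighted least squares
#'    (weights inversely proportional to the squared expected pairwise
#'    variance, the delta-method precision of a sample variance), then
#'    truncated at 0. This is the finite-gene correction in
#'    pairwise-difference form; it needs k >= 3 genes.
#' 4. The group-mean contrast `d_ig` (group means of z, centered across
#'    groups with equal weights, so `sum_g d_ig = 0`) is shrunk toward 0
#'    by its estimated signal-to-total-variance ratio
#'    `tau2 / (tau2 + se2_ig)`, where `se2_ig` is the model-based
#'    sampling variance of `d_ig` and `tau2` a pretest-shrinkage
#'    method-of-moments estimate of the variance of true group biases
#'    across genes: unless the standardized contrasts reject a
#'    no-bias chi-square null at the 5% level, `tau2 = 0` and apparent
#'    biases are treated as sampling noise (with few genes, one noisy
#'    gene's error leaks into every contrast through the panel mean).
#' 5. The stability value is
#'    `rho_i = mean_g( |shrunken d_ig| + se(d_ig) )`.
#'
#' With a single group (no sample sheet), `rho_i` reduces to the square
#' root of the corrected gene variance.
#'
#' @param m a `cq_matrix` with complete data on the candidates.
#' @param sheet optional sample sheet; `NULL` treats all samples as one
#'   group.
#' @param candidates assay ids to score (default: all assays of `m`);
#'   at least 3.
#' @return an object of class `normfinder_result`: list with `stability`
#'   (data.frame: assay, rho, rank), `best_single`, matrices `d`,
#'   `d_shrunk`, `se`, `sigma2` (gene x group), `tau2`, `group_sizes`, `k`,
#'   and `correction` (a string documenting the variance correction used).
#' @export
normfinder_stability <- function(m, sheet = NULL, candidates = NULL) {
  if (is.null(candidates)) candidates <- assay_ids(m)
  if (length(candidates) < 3)
    stop("NormFinder needs >= 3 candidate assays")
  missing_a <- setdiff(candidates, assay_ids(m))
  if (length(missing_a))
    stop("unknown candidate assay(s): ", paste(missing_a, collapse = ", "))
  sub <- cq_subset(m, assays = candidates)
  if (any(!sub$detected)) {
    idx <- which(!sub$detected, arr.ind = TRUE)[1, ]
    stop(sprintf("candidate '%s' undetected in sample '%s'",
                 candidates[idx[1]], sample_ids(sub)[idx[2]]))
  }
  y <- -sub$cq
  k <- nrow(y)
  z <- sweep(y, 2, colMeans(y))
  grp <- if (is.null(sheet)) rep("all", ncol(y)) else groups_for(sub, sheet)
  glev <- unique(grp)
  G <- length(glev)
  n_g <- stats::setNames(as.integer(table(grp)[glev]), glev)
  if (any(n_g < 2)) stop("need >= 2 samples per group")
  sigma2 <- sapply(glev, function(g)
    pairwise_gene_variances(y[, grp == g, drop = FALSE]))
  sigma2 <- matrix(sigma2, nrow = k, dimnames = list(candidates, glev))
  correction <- paste(
    "gene variances by pairwise-difference IRLS:",
    "Var(y_i - y_l) = sigma2_i + sigma2_l (sample effects cancel exactly),",
    "solved by weighted least squares and truncated at 0")

  if (G == 1) {
    rho <- sqrt(sigma2[, 1])
    stab <- data.frame(assay = candidates, rho = rho,
                       stringsAsFactors = FALSE, row.names = NULL)
    stab <- stab[order(stab$rho, stab$assay), ]
    stab$rank <- seq_len(k)
    rownames(stab) <- NULL
    return(structure(list(stability = stab, best_single = stab$assay[1],
                          d = NULL, d_shrunk = NULL, se = NULL,
                          sigma2 = sigma2, tau2 = NA_real_,
                          group_sizes = n_g, k = k, correction = correction),
                     class = "normfinder_result"))
  }
  zbar <- sapply(glev, function(g)
    rowMeans(z[, grp == g, drop = FALSE]))
  zbar <- matrix(zbar, nrow = k, dimnames = list(candidates, glev))
  d <- zbar - rowMeans(zbar)            # equal group weights
  # model-correct sampling variance of the group mean of z: the
  # sample-mean subtraction deflates the gene's own variance by (1 - 2/k)
  # and adds the shared panel-mean noise sum(sigma2)/k^2
  vz <- sapply(glev, function(g)
    ((1 - 2 / k) * sigma2[, g] + sum(sigma2[, g]) / k^2) / n_g[g])
  vz <- matrix(vz, nrow = k, dimnames = dimnames(sigma2))
  se2 <- matrix(0, k, G, dimnames = dimnames(d))
  for (gi in seq_len(G)) {
    others <- setdiff(seq_len(G), gi)
    se2[, gi] <- (1 - 1 / G)^2 * vz[, gi] +
      rowSums(vz[, others, drop = FALSE]) / G^2
  }
  # Pretest-shrinkage estimate of the between-group bias variance tau2:
  # with few genes, sampling noise in the contrasts is easily mistaken for
  # real group bias (one noisy gene leaks -d/k into every other gene via
  # the panel mean), so tau2 is set to 0 — full shrinkage, no evidence of
  # inter-group variation — unless the standardized contrasts exceed their
  # null chi-square scale.
  bias_p <- bias_pretest_p(d, sigma2, n_g, k, G, se2)
  tau2 <- if (bias_p < 0.05) max(0, mean(d^2 - se2)) else 0
  shrink <- ifelse(tau2 + se2 > 0, tau2 / (tau2 + se2), 0)
  d_shrunk <- d * shrink
  rho <- rowMeans(abs(d_shrunk) + sqrt(se2))
  stab <- data.frame(assay = candidates, rho = rho,
                     stringsAsFactors = FALSE, row.names = NULL)
  stab <- stab[order(stab$rho, stab$assay), ]
  stab$rank <- seq_len(k)
  rownames(stab) <- NULL
  structure(list(stability = stab, best_single = stab$assay[1],
                 d = d, d_shrunk = d_shrunk, se = sqrt(se2),
                 sigma2 = sigma2, tau2 = tau2, bias_test_p = bias_p,
                 group_sizes = n_g, k = k, correction = correction),
            class = "normfinder_result")
}

# Pretest for inter-group variation. For two groups the contrast vector
# d (one group's column; the other is its mirror) has model covariance
# V = (h/4) (diag(sigma2*) - sigma2 1'/k - 1 sigma2'/k + (sum sigma2/k^2) J)
# with h = 1/n_1 + 1/n_2 and sigma2* the (1 - 2/k)-deflated variances --
# the sample-mean subtraction correlates all genes, and sum(d) = 0 makes V
# rank k-1. The Mahalanobis form d' V^- d is chi-square(k-1) under the
# no-bias null. For more than two groups a sum-of-ratios approximation is
# used.
bias_pretest_p <- function(d, sigma2, n_g, k, G, se2) {
  if (G == 2) {
    # per-gene variance of the pooled group-mean noise entering d:
    # vsum_i = sigma2_i,1/n_1 + sigma2_i,2/n_2.
    # Var(d_i)   = (vsum_i (1 - 2/k) + S/k^2) / 4,
    # Cov(d_i,l) = (-vsum_i/k - vsum_l/k + S/k^2) / 4,  S = sum(vsum)
    vsum <- rowSums(sweep(sigma2, 2, n_g, "/"))
    S <- sum(vsum)
    V <- (-outer(vsum, rep(1 / k, k)) - outer(rep(1 / k, k), vsum) +
            matrix(S / k^2, k, k)) / 4
    diag(V) <- (vsum * (1 - 2 / k) + S / k^2) / 4
    eg <- eigen(V, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-8
    if (!any(pos)) return(1)
    vinv <- eg$vectors[, pos, drop = FALSE] %*%
      (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
    stat <- drop(t(d[, 1]) %*% vinv %*% d[, 1])
    stats::pchisq(stat, sum(pos), lower.tail = FALSE)
  } else {
    ratio <- ifelse(se2 > 0, d^2 / se2, 0)
    stats::pchisq(sum(ratio) / G, (k - 1) * (G - 1), lower.tail = FALSE)
  }
}

# Per-gene variance estimation from pairwise gene differences within one
# group. For genes i, l: Var(y_i - y_l) = sigma2_i + sigma2_l, free of the
# shared sample effect. Solved by iteratively reweighted least squares,
# weights 1 / (sigma2_i + sigma2_l)^2 (delta-method precision of a sample
# variance); estimates truncated at 0.
pairwise_gene_variances <- function(y) {
  k <- nrow(y)
  pairs <- utils::combn(k, 2)
  s2 <- apply(pairs, 2, function(p) stats::var(y[p[1], ] - y[p[2], ]))
  A <- matrix(0, ncol(pairs), k)
  A[cbind(seq_len(ncol(pairs)), pairs[1, ])] <- 1
  A[cbind(seq_len(ncol(pairs)), pairs[2, ])] <- 1
  w <- rep(1, length(s2))
  est <- rep(mean(s2) / 2, k)
  for (it in 1:5) {
    aw <- A * w
    est <- tryCatch(solve(crossprod(aw, A), crossprod(aw, s2))[, 1],
                    error = function(e) est)
    fitted <- as.numeric(A %*% pmax(est, 0))
    floor_v <- max(mean(s2) * 0.05, 1e-12)
    w <- 1 / pmax(fitted, floor_v)^2
  }
  pmax(est, 0)
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("NormFinder-style stability (lower = more stable):\n")
  print(x$stability, row.names = FALSE)
  cat("best single:", x$best_single, "\n")
  invisible(x)
}

#' Best two-EC combination under the NormFinder model
#'
#' For every unordered pair the combined log-scale signal is the mean of
#' the two members, so the pair's group bias is the mean of the members'
#' biases (opposite-sign biases cancel — the rationale for two-EC
#' normalization) and its sampling variance a quarter of their sum. The
#' pair score applies the same shrunken-|bias| + SE composition used for
#' single assays; with a single group it is the square root of the pair's
#' combined variance.
#'
#' @param result a `normfinder_result` from [normfinder_stability()].
#' @return list with `pair` (character(2)), `stability` (scalar) and
#'   `all_pairs` (data.frame of every pair's combined stability, sorted).
#' @export
best_pair <- function(result) {
  stopifnot(inherits(result, "normfinder_result"))
  assays <- rownames(result$sigma2)
  if (length(assays) < 2) stop("need >= 2 candidates")
  pairs <- utils::combn(assays, 2)
  score <- apply(pairs, 2, function(p) {
    if (is.null(result$d)) {
      sig2_p <- colSums(result$sigma2[p, , drop = FALSE]) / 4
      return(mean(sqrt(sig2_p)))
    }
    d_p <- colMeans(result$d[p, , drop = FALSE])
    se2_p <- colSums(result$se[p, , drop = FALSE]^2) / 4
    shr <- ifelse(result$tau2 + se2_p > 0,
                  result$tau2 / (result$tau2 + se2_p), 0)
    d_sh <- d_p * shr
    mean(abs(d_sh) + sqrt(se2_p))
  })
  tab <- data.frame(assay1 = pairs[1, ], assay2 = pairs[2, ],
                    stability = score, stringsAsFactors = FALSE)
  tab <- tab[order(tab$stability, tab$assay1, tab$assay2), ]
  rownames(tab) <- NULL
  list(pair = c(tab$assay1[1], tab$assay2[1]),
       stability = tab$stability[1], all_pairs = tab)
}
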