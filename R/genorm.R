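#' Convert Cq values to relative quantities
#'
#' `Q_ij = (1 + E_i/100)^(anchorCq_i - Cq_ij)` with per-assay efficiency E
#' in percent (default 100, i.e. perfect doubling, factor 2 per cycle). The
#' default anchor is the per-assay minimum Cq, so the highest-expressed
#' sample has Q = 1; the anchor cancels in all ratio-based stability
#' statistics.
#'
#' @param m a `cq_matrix`; all assays must be detected in all samples.
#' @param efficiency scalar or named per-assay vector of percent
#'   efficiencies.
#' @param anchor `"min"` or `"mean"` per-assay anchor Cq.
#' @return numeric matrix of positive quantities (assays x samples).
#' @export
to_relative_quantity <- function(m, efficiency = 100,
                                 anchor = c("min", "mean")) {
  anchor <- match.arg(anchor)
  if (any(!m$detected)) {
    idx <- which(!m$detected, arr.ind = TRUE)[1, ]
    stop(sprintf("undetected Cq for assay '%s', sample '%s'",
                 assay_ids(m)[idx[1]], sample_ids(m)[idx[2]]))
  }
  eff <- efficiency_vector(efficiency, assay_ids(m))
  anchor_cq <- apply(m$cq, 1, if (anchor == "min") min else mean)
  base <- 1 + eff / 100
  # length-nrow vectors recycle down columns, i.e. per assay row
  base^(anchor_cq - m$cq)
}

# per-assay efficiency vector in percent, validated
efficiency_vector <- function(efficiency, assays) {
  if (length(efficiency) == 1L && is.null(names(efficiency)))
    efficiency <- stats::setNames(rep(efficiency, length(assays)), assays)
  if (is.null(names(efficiency)) || !all(assays %in% names(efficiency)))
    stop("`efficiency` must be a scalar or a named vector covering all assays")
  eff <- efficiency[assays]
  if (any(!is.finite(eff) | eff <= 0))
    stop("efficiencies must be positive percentages")
  eff
}

#' Pairwise variation between two assays
#'
#' `V_jk` = sample SD (n-1) across samples of `log2(Q_j / Q_k)`. Two
#' proportional (perfectly co-varying) assays have V = 0; V is unchanged by
#' per-sample rescaling since sample factors cancel in the ratio.
#'
#' @param q positive quantity matrix (assays x samples), e.g. from
#'   [to_relative_quantity()].
#' @param j,k assay names or row indices, `j != k`.
#' @return scalar V_jk.
#' @export
pairwise_variation <- function(q, j, k) {
  if (ncol(q) < 2) stop("need >= 2 samples")
  lj <- log2(q[j, ])
  lk <- log2(q[k, ])
  if (identical(j, k)) stop("j and k must differ")
  stats::sd(lj - lk)
}

#' geNorm expression-stability measure M
#'
#' `M_j` is the mean of `V_jk` over all other assays k: the average pairwise
#' variation of assay j with every other candidate. Lower M = more stable.
#' With exactly two assays both carry `M = V_jk`.
#'
#' @inheritParams pairwise_variation
#' @return named numeric vector of M values.
#' @export
stability_m <- function(q) {
  n <- nrow(q)
  if (n < 2) stop("need >= 2 assays")
  lq <- log2(q)
  v <- matrix(0, n, n, dimnames = list(rownames(q), rownames(q)))
  for (j in seq_len(n - 1))
    for (k in (j + 1):n)
      v[j, k] <- v[k, j] <- stats::sd(lq[j, ] - lq[k, ])
  if (n == 2) return(stats::setNames(rep(v[1, 2], 2), rownames(q)))
  rowSums(v) / (n - 1)
}

#' geNorm stepwise stability ranking
#'
#' Iteratively recomputes M and drops the assay with the highest M (least
#' stable) until two remain; those two share the final M and jointly rank
#' most stable. Ties on M are broken by assay name (alphabetically earlier
#' assay is kept) and reported.
#'
#' @inheritParams pairwise_variation
#' @return an object of class `genorm_result`: list with `ranking` (assay
#'   ids, most stable first; the final pair in alphabetical order), `rounds`
#'   (data.frame: round, assay eliminated, its M, tie flag), `m_by_round`
#'   (list of M vectors), `final_pair`, `final_m`, and `v_initial` (the full
#'   pairwise-variation matrix at round 1).
#' @export
stepwise_ranking <- function(q) {
  if (nrow(q) < 3) stop("need >= 3 assays for a stepwise ranking")
  lq <- log2(q)
  n <- nrow(q)
  v0 <- matrix(0, n, n, dimnames = list(rownames(q), rownames(q)))
  for (j in seq_len(n - 1))
    for (k in (j + 1):n)
      v0[j, k] <- v0[k, j] <- stats::sd(lq[j, ] - lq[k, ])
  remaining <- rownames(q)
  rounds <- data.frame(round = integer(), eliminated = character(),
                       m = numeric(), tie = logical(),
                       stringsAsFactors = FALSE)
  m_by_round <- list()
  r <- 0L
  order_out <- character()
  while (length(remaining) > 2) {
    r <- r + 1L
    m <- rowSums(v0[remaining, remaining]) / (length(remaining) - 1)
    m_by_round[[r]] <- m
    worst_m <- max(m)
    tied <- names(m)[m == worst_m]
    drop_assay <- sort(tied, decreasing = TRUE)[1]  # drop the later name
    rounds <- rbind(rounds, data.frame(
      round = r, eliminated = drop_assay, m = worst_m,
      tie = length(tied) > 1, stringsAsFactors = FALSE))
    order_out <- c(drop_assay, order_out)
    remaining <- setdiff(remaining, drop_assay)
  }
  final_m <- v0[remaining[1], remaining[2]]
  m_by_round[[r + 1L]] <- stats::setNames(rep(final_m, 2), sort(remaining))
  structure(list(ranking = c(sort(remaining), order_out),
                 rounds = rounds, m_by_round = m_by_round,
                 final_pair = sort(remaining), final_m = final_m,
                 v_initial = v0),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stepwise ranking (most stable first):\n ",
      paste(x$ranking, collapse = " > "), "\n")
  cat(sprintf("final pair: %s (M = %.4f)\n",
              paste(x$final_pair, collapse = " + "), x$final_m))
  invisible(x)
}

#' Optimal number of ECs by normalization-factor pairwise variation
#'
#' `NF_n(sample)` is the geometric mean of the n most stable assays'
#' relative quantities; `V_{n/n+1}` is the sample SD of
#' `log2(NF_n / NF_{n+1})`, the change incurred by adding the (n+1)-th
#' assay. The recommendation is the smallest n with `V_{n/n+1}` below
#' `v_cutoff` (canonically 0.15); when no V clears the cutoff — as happens
#' with modest candidate panels — the n minimizing V is recommended
#' instead.
#'
#' @inheritParams pairwise_variation
#' @param ranking a `genorm_result` from [stepwise_ranking()].
#' @param v_cutoff V threshold below which adding more ECs is deemed
#'   unnecessary.
#' @return list with `v` (data.frame: n, v = V_{n/n+1}), `nf` (matrix of
#'   NF_n per sample, rows n = 2..N), `recommended_n`, `recommendation`
#'   ("below_cutoff" or "argmin"), `ec_set` (the recommended assays).
#' @export
optimal_ec_count <- function(q, ranking, v_cutoff = 0.15) {
  stopifnot(inherits(ranking, "genorm_result"))
  ord <- ranking$ranking
  if (length(ord) < 3) stop("need >= 3 ranked assays")
  lq <- log2(q[ord, , drop = FALSE])
  # log2 NF_n = mean of the top-n assays' log2 quantities
  lnf <- apply(lq, 2, cumsum) / seq_along(ord)
  ns <- 2:(length(ord) - 1)
  v <- vapply(ns, function(n) stats::sd(lnf[n, ] - lnf[n + 1, ]), 0)
  vtab <- data.frame(n = ns, v = v)
  below <- which(v < v_cutoff)
  if (length(below)) {
    rec_n <- ns[below[1]]
    why <- "below_cutoff"
  } else {
    rec_n <- ns[which.min(v)]
    why <- "argmin"
  }
  nf <- 2^lnf[-1, , drop = FALSE]
  rownames(nf) <- paste0("NF", 2:length(ord))
  list(v = vtab, nf = nf, recommended_n = rec_n, recommendation = why,
       ec_set = ord[seq_len(rec_n)], v_cutoff = v_cutoff)
}
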