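#' Per-sample global mean expression (GME)
#'
#' The mean Cq over all *expressed* assays of a sample (detected and below
#' the expressed cutoff), excluding control wells (snoRNAs, negative
#' controls). Used as a per-sample normalization factor for profiling
#' panels: subtracting it removes sample loading effects.
#'
#' @param m a `cq_matrix`.
#' @param expressed_cutoff Cq below which an assay counts as expressed.
#' @param exclude assay ids excluded from the mean (control wells).
#' @return named numeric vector of per-sample mean Cq.
#' @export
global_mean_per_sample <- function(m, expressed_cutoff = 35,
                                   exclude = character()) {
  keep <- setdiff(assay_ids(m), exclude)
  cq <- m$cq[keep, , drop = FALSE]
  cq[!(m$detected[keep, , drop = FALSE] & cq < expressed_cutoff)] <- NA_real_
  n_expr <- colSums(!is.na(cq))
  if (any(n_expr < 2))
    stop("sample(s) with fewer than 2 expressed assays: ",
         paste(sample_ids(m)[n_expr < 2], collapse = ", "))
  colMeans(cq, na.rm = TRUE)
}

#' Rank assays by deviation from the global mean
#'
#' For each eligible assay i (expressed in every sample), the deviation
#' `d_ij = Cq_ij - GME_j` is computed per sample; the stability score is the
#' sample SD (n-1) of the deviations — 0 for an assay tracking the global
#' mean up to a constant offset. Assays are ranked ascending by score, ties
#' broken lexicographically by assay name. Control assays are excluded from
#' the global mean itself but still scored against it (and are never
#' eligible for nomination).
#'
#' @inheritParams global_mean_per_sample
#' @param controls assay ids treated as control wells.
#' @return a data.frame (class `gme_ranking`) with columns assay, score,
#'   rank (NA for ineligible assays), eligible, is_control,
#'   detected_in_all; attribute `"gme"` holds the per-sample means.
#' @export
rank_by_gme <- function(m, expressed_cutoff = 35, controls = character()) {
  if (ncol(m$cq) < 2) stop("need >= 2 samples to rank by GME")
  gme <- global_mean_per_sample(m, expressed_cutoff, exclude = controls)
  expressed <- m$detected & m$cq < expressed_cutoff
  det_all <- rowSums(expressed) == ncol(m$cq)
  score <- rep(NA_real_, nrow(m$cq))
  names(score) <- assay_ids(m)
  for (a in which(det_all))
    score[a] <- stats::sd(m$cq[a, ] - gme)
  is_control <- assay_ids(m) %in% controls
  eligible <- det_all & !is_control
  res <- data.frame(assay = assay_ids(m), score = score,
                    eligible = eligible, is_control = is_control,
                    detected_in_all = det_all, stringsAsFactors = FALSE,
                    row.names = NULL)
  res <- res[order(!res$eligible, res$score, res$assay), ]
  res$rank <- NA_integer_
  res$rank[res$eligible] <- seq_len(sum(res$eligible))
  rownames(res) <- NULL
  attr(res, "gme") <- gme
  attr(res, "expressed_cutoff") <- expressed_cutoff
  class(res) <- c("gme_ranking", "data.frame")
  res
}

#' Nominate candidate ECs from a GME ranking
#'
#' The top-k assays of the ranking are selected, then any on a
#' user-supplied exclusion list (e.g. miRNAs with documented disease
#' associations; that screening is a manual, literature-based step) are
#' struck from the selection — so heavy exclusion can leave a single
#' nominee.
#'
#' @param ranking a `gme_ranking` from [rank_by_gme()].
#' @param k size of the short-list taken from the top of the ranking.
#' @param exclusion_list assay ids struck from the short-list.
#' @return character vector of nominated assay ids, ordered by rank; if
#'   fewer than `k` assays are eligible, all of them form the short-list
#'   and a warning is raised.
#' @export
nominate_candidates <- function(ranking, k = 10, exclusion_list = character()) {
  if (k < 1) stop("`k` must be >= 1")
  pool <- ranking$assay[ranking$eligible]
  if (length(pool) < k) {
    warning(sprintf("only %d eligible assays (k = %d); using all",
                    length(pool), k))
    k <- length(pool)
  }
  shortlist <- pool[seq_len(k)]
  setdiff(shortlist, exclusion_list)
}
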