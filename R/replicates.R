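#' Collapse replicate wells with a replicate-SD quality gate
#'
#' Per (sample, assay): the mean Cq of detected replicates is kept when the
#' replicate standard deviation (sample SD, n-1 denominator) does not exceed
#' `sd_max`; sets above the threshold are flagged and excluded from the
#' output matrix (no best-2-of-3 rescue). The default threshold is 0.28
#' cycles, the conventional intra-/inter-assay replicate tolerance.
#'
#' @param reps data.frame of replicate wells with columns `sample`, `assay`,
#'   `cq` and optionally `replicate`, `plate` (see [read_cq_long()]);
#'   undetected wells carry `NA` cq.
#' @param sd_max maximum allowed replicate SD in cycles (> 0).
#' @param max_cycles passed to [cq_matrix()].
#' @return a list with `cq` (a `cq_matrix` of collapsed means) and `qc`
#'   (a data.frame per replicate set: n wells, n detected, mean, sd, status).
#' @export
collapse_replicates <- function(reps, sd_max = 0.28, max_cycles = 40) {
  if (!is.data.frame(reps) || nrow(reps) == 0L)
    stop("`reps` must be a non-empty data.frame of replicate wells")
  if (!all(c("sample", "assay", "cq") %in% names(reps)))
    stop("`reps` needs columns sample, assay, cq")
  if (!is.numeric(sd_max) || sd_max <= 0)
    stop("`sd_max` must be a positive number of cycles")
  key <- paste(reps$assay, reps$sample, sep = "\r")
  idx <- split(seq_len(nrow(reps)), key)
  idx <- idx[unique(key)]  # keep input order
  qc <- do.call(rbind, lapply(idx, function(i) {
    v <- reps$cq[i]
    det <- v[!is.na(v)]
    m <- if (length(det)) mean(det) else NA_real_
    s <- if (length(det) >= 2) stats::sd(det) else 0
    status <- if (!length(det)) "undetected"
              else if (s > sd_max) "flagged"
              else "pass"
    data.frame(assay = reps$assay[i[1]], sample = reps$sample[i[1]],
               n_wells = length(v), n_detected = length(det),
               mean_cq = m, sd_cq = if (length(det)) s else NA_real_,
               status = status, stringsAsFactors = FALSE)
  }))
  rownames(qc) <- NULL
  assays <- unique(qc$assay)
  samples <- unique(qc$sample)
  cq <- matrix(NA_real_, length(assays), length(samples),
               dimnames = list(assays, samples))
  keep <- qc$status == "pass"
  cq[cbind(match(qc$assay[keep], assays), match(qc$sample[keep], samples))] <-
    qc$mean_cq[keep]
  list(cq = cq_matrix(cq, max_cycles = max_cycles), qc = qc)
}

#' Inter-assay (between-plate) calibration of a Cq matrix
#'
#' An inter-assay control (IAC) is a common assay measured on every sample;
#' shifts of its mean between plates estimate run-to-run offsets. Per plate
#' p the offset is mean(IAC Cq on plate p) - mean(IAC Cq over all samples),
#' and every Cq on plate p is shifted by -offset(p); the IAC assay is then
#' dropped from the matrix. Offsets weighted by plate sample-count sum to 0,
#' and within-plate Cq contrasts are untouched.
#'
#' @param m a `cq_matrix` containing the IAC assay.
#' @param plates named character vector or data.frame (`sample_id`/`sample`,
#'   `plate`) mapping every sample of `m` to a plate.
#' @param iac_assay name of the IAC assay row.
#' @return a `cq_matrix` without the IAC row; the calibration table
#'   (plate, n samples, plate IAC mean, global IAC mean, offset) is attached
#'   as attribute `"calibration"`.
#' @export
apply_iac_calibration <- function(m, plates, iac_assay = "IAC") {
  if (is.data.frame(plates)) {
    sc <- if ("sample_id" %in% names(plates)) "sample_id" else "sample"
    plates <- stats::setNames(as.character(plates$plate), plates[[sc]])
  }
  plate <- plates[sample_ids(m)]
  if (anyNA(plate) || is.null(names(plates)))
    stop("every sample must map to a plate")
  if (!iac_assay %in% assay_ids(m))
    stop(sprintf("IAC assay '%s' not present in matrix", iac_assay))
  iac <- m$cq[iac_assay, ]
  for (p in unique(plate))
    if (all(is.na(iac[plate == p])))
      stop(sprintf("plate '%s' has no detected IAC measurement", p))
  global_mean <- mean(iac, na.rm = TRUE)
  plate_mean <- tapply(iac, plate, mean, na.rm = TRUE)
  offset <- plate_mean - global_mean
  keep <- setdiff(assay_ids(m), iac_assay)
  cq <- m$cq[keep, , drop = FALSE]
  cq <- sweep(cq, 2, offset[plate], "-")
  out <- cq_matrix(cq, max_cycles = m$max_cycles)
  attr(out, "calibration") <- data.frame(
    plate = names(plate_mean), n_samples = as.integer(table(plate)[names(plate_mean)]),
    iac_assay = iac_assay, plate_iac_mean = as.numeric(plate_mean),
    global_iac_mean = global_mean, offset = as.numeric(offset),
    stringsAsFactors = FALSE)
  out
}

#' Per-assay Cq summaries, overall and by group
#'
#' For each assay (and, when a sample sheet is supplied, each group):
#' mean, SD, min, max and range = max - min of detected Cq values.
#' Values are carried at full precision; round for reporting.
#'
#' @param m a `cq_matrix`.
#' @param sheet optional sample sheet ([sample_sheet()]).
#' @return a data.frame with columns assay, group ("all" for the pooled
#'   rows), n, mean_cq, sd_cq, min_cq, max_cq, range_cq.
#' @export
summarize_assays <- function(m, sheet = NULL) {
  grp <- if (is.null(sheet)) rep("all", ncol(m$cq)) else groups_for(m, sheet)
  one <- function(a, cols, label) {
    v <- m$cq[a, cols]
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(assay = a, group = label, n = 0L, mean_cq = NA_real_,
                        sd_cq = NA_real_, min_cq = NA_real_, max_cq = NA_real_,
                        range_cq = NA_real_, stringsAsFactors = FALSE))
    data.frame(assay = a, group = label, n = length(v), mean_cq = mean(v),
               sd_cq = if (length(v) > 1) stats::sd(v) else 0,
               min_cq = min(v), max_cq = max(v), range_cq = max(v) - min(v),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (a in assay_ids(m)) {
    rows[[length(rows) + 1L]] <- one(a, seq_len(ncol(m$cq)), "all")
    if (!is.null(sheet))
      for (g in unique(grp))
        rows[[length(rows) + 1L]] <- one(a, which(grp == g), g)
  }
  do.call(rbind, rows)
}
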