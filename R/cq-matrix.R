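#' Cq matrix: assays x samples quantification-cycle values
#'
#' The central measurement container. Rows are assays (miRNAs, snoRNAs,
#' controls), columns are samples. Undetected wells carry `NA` in `cq` and
#' `FALSE` in `detected`; a numeric Cq of 40 is a legitimate value, not a
#' non-detect.
#'
#' @param cq numeric matrix (assays x samples) with dimnames; `NA` marks
#'   undetected wells.
#' @param detected optional logical matrix of the same shape; defaults to
#'   `!is.na(cq)`.
#' @param max_cycles maximum cycle number any detected Cq may take.
#' @return an object of class `cq_matrix` with elements `cq`, `detected`
#'   and `max_cycles`.
#' @export
cq_matrix <- function(cq, detected = NULL, max_cycles = 40) {
  if (!is.matrix(cq) || !is.numeric(cq))
    stop("`cq` must be a numeric matrix (assays x samples)")
  if (is.null(rownames(cq)) || is.null(colnames(cq)))
    stop("`cq` must have assay row names and sample column names")
  if (anyDuplicated(rownames(cq)))
    stop("duplicate assay ids: ",
         paste(unique(rownames(cq)[duplicated(rownames(cq))]), collapse = ", "))
  if (anyDuplicated(colnames(cq)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(cq)[duplicated(colnames(cq))]), collapse = ", "))
  if (is.null(detected)) detected <- !is.na(cq)
  if (!is.logical(detected) || !identical(dim(detected), dim(cq)))
    stop("`detected` must be a logical matrix with the same shape as `cq`")
  cq[!detected] <- NA_real_
  bad <- detected & (!is.finite(cq) | cq < 0 | cq > max_cycles)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("detected Cq out of [0, %g] at assay '%s', sample '%s'",
                 max_cycles, rownames(cq)[idx[1]], colnames(cq)[idx[2]]))
  }
  dimnames(detected) <- dimnames(cq)
  structure(list(cq = cq, detected = detected, max_cycles = max_cycles),
            class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("cq_matrix: %d assays x %d samples (%d undetected wells)\n",
              nrow(x$cq), ncol(x$cq), sum(!x$detected)))
  invisible(x)
}

#' @rdname cq_matrix
#' @param m a `cq_matrix`.
#' @export
assay_ids <- function(m) rownames(m$cq)

#' @rdname cq_matrix
#' @export
sample_ids <- function(m) colnames(m$cq)

#' @export
dim.cq_matrix <- function(x) dim(x$cq)

#' Subset a Cq matrix by assay and/or sample ids
#'
#' @param m a `cq_matrix`.
#' @param assays,samples character vectors of ids to keep (default: all).
#' @return a `cq_matrix`.
#' @export
cq_subset <- function(m, assays = assay_ids(m), samples = sample_ids(m)) {
  missing_a <- setdiff(assays, assay_ids(m))
  if (length(missing_a))
    stop("unknown assay(s): ", paste(missing_a, collapse = ", "))
  missing_s <- setdiff(samples, sample_ids(m))
  if (length(missing_s))
    stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  cq_matrix(m$cq[assays, samples, drop = FALSE],
            m$detected[assays, samples, drop = FALSE],
            max_cycles = m$max_cycles)
}

# Tokens (lower-cased) read as "no amplification call" in input files.
UNDETERMINED_TOKENS <- c("undetermined", "undet", "na", "n/a", "")

parse_cq_values <- function(x, what = "Cq") {
  x_chr <- trimws(as.character(x))
  undet <- tolower(x_chr) %in% UNDETERMINED_TOKENS | is.na(x)
  val <- suppressWarnings(as.numeric(x_chr))
  bad <- !undet & is.na(val)
  if (any(bad))
    stop(sprintf("non-numeric %s value '%s' at data row %d",
                 what, x_chr[which(bad)[1]], which(bad)[1]))
  val[undet] <- NA_real_
  val
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character",
                    comment.char = "", quote = "\"")
}

LONG_COLUMNS <- c("sample", "assay", "cq")

#' Read a Cq table from delimited text
#'
#' Two layouts are supported. Wide: assays as rows, samples as columns, with
#' the first column holding assay names (typical instrument export). Long:
#' columns `sample`, `assay`, `cq` and optionally `replicate`, `plate`
#' (case-insensitive). Cells reading "Undetermined" (or empty) become
#' non-detects. Layout is auto-detected from the header unless given.
#'
#' @param path path to a CSV/TSV file.
#' @param layout `"auto"`, `"wide"` or `"long"`. A long file read here must
#'   have one record per (sample, assay); use [read_cq_long()] +
#'   [collapse_replicates()] for replicate-level files.
#' @param max_cycles passed to [cq_matrix()].
#' @return a `cq_matrix`.
#' @export
read_cq_table <- function(path, layout = c("auto", "wide", "long"),
                          max_cycles = 40) {
  layout <- match.arg(layout)
  df <- read_delim_auto(path)
  lower <- tolower(names(df))
  if (layout == "auto")
    layout <- if (all(LONG_COLUMNS %in% lower)) "long" else "wide"
  if (layout == "long") {
    # key column names are case-insensitive in long layout
    names(df) <- lower
    if (!all(LONG_COLUMNS %in% names(df)))
      stop("long layout needs columns: ", paste(LONG_COLUMNS, collapse = ", "))
    key <- paste(df$sample, df$assay, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE][1, ]
      stop(sprintf(paste0("multiple records for sample '%s', assay '%s'; ",
                          "use read_cq_long() + collapse_replicates() for ",
                          "replicate-level files"), d$sample, d$assay))
    }
    cqv <- parse_cq_values(df$cq)
    assays <- unique(df$assay)
    samples <- unique(df$sample)
    cq <- matrix(NA_real_, length(assays), length(samples),
                 dimnames = list(assays, samples))
    cq[cbind(match(df$assay, assays), match(df$sample, samples))] <- cqv
    return(cq_matrix(cq, max_cycles = max_cycles))
  }
  assays <- df[[1]]
  if (anyDuplicated(assays))
    stop("duplicate assay rows in wide table: ",
         paste(unique(assays[duplicated(assays)]), collapse = ", "))
  vals <- vapply(df[-1], parse_cq_values, numeric(nrow(df)))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  cq <- matrix(as.numeric(vals), nrow = nrow(df),
               dimnames = list(assays, names(df)[-1]))
  cq_matrix(cq, max_cycles = max_cycles)
}

#' Read a replicate-level (long) Cq file
#'
#' Returns the records as a data frame with columns `sample`, `assay`,
#' `replicate`, `plate`, `cq` — the input expected by
#' [collapse_replicates()]. Missing `replicate`/`plate` columns are filled
#' with defaults (well index within the (sample, assay) set; plate "P1").
#'
#' @param path path to a CSV/TSV file with columns `sample`, `assay`, `cq`
#'   and optionally `replicate`, `plate` (case-insensitive).
#' @return a data.frame of replicate wells; undetected wells have `NA` cq.
#' @export
read_cq_long <- function(path) {
  df <- read_delim_auto(path)
  names(df) <- tolower(names(df))
  if (!all(LONG_COLUMNS %in% names(df)))
    stop("long layout needs columns: ", paste(LONG_COLUMNS, collapse = ", "))
  out <- data.frame(sample = df$sample, assay = df$assay,
                    stringsAsFactors = FALSE)
  out$replicate <- if ("replicate" %in% names(df)) {
    as.integer(df$replicate)
  } else {
    stats::ave(seq_len(nrow(df)), df$sample, df$assay, FUN = seq_along)
  }
  out$plate <- if ("plate" %in% names(df)) as.character(df$plate) else "P1"
  out$cq <- parse_cq_values(df$cq)
  key <- paste(out$sample, out$assay, out$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- out[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate (sample, assay, replicate) key: %s / %s / %s",
                 d$sample, d$assay, d$replicate))
  }
  out
}

#' Write a Cq matrix to delimited text
#'
#' Inverse of [read_cq_table()]: `read_cq_table(write_cq_table(m, f))`
#' recovers `m` up to row/column order. Undetected wells are written as
#' "Undetermined".
#'
#' @param m a `cq_matrix`.
#' @param path output file path.
#' @param layout `"wide"` or `"long"`.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(m, path, layout = c("wide", "long"), sep = ",") {
  layout <- match.arg(layout)
  fmt <- function(x) ifelse(is.na(x), "Undetermined", format(x, digits = 15))
  if (layout == "wide") {
    df <- data.frame(assay = assay_ids(m), apply(m$cq, 2, fmt),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("assay", sample_ids(m))
  } else {
    df <- expand.grid(assay = assay_ids(m), sample = sample_ids(m),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$cq <- fmt(m$cq[cbind(df$assay, df$sample)])
    df <- df[, c("sample", "assay", "cq")]
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build or read a sample sheet
#'
#' A sample sheet assigns each sample to a `group` (e.g. cancer/control) and
#' a `cohort` (e.g. screen/validation); it drives all between-group
#' statistics.
#'
#' @param sample_id character vector of sample names (unique).
#' @param group character vector of group labels.
#' @param cohort character vector (recycled) of cohort labels.
#' @return a data.frame with columns `sample_id`, `group`, `cohort`.
#' @export
sample_sheet <- function(sample_id, group, cohort = "validation") {
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in sample sheet")
  if (length(group) != length(sample_id))
    stop("`group` must match `sample_id` in length")
  data.frame(sample_id = as.character(sample_id),
             group = as.character(group),
             cohort = rep_len(as.character(cohort), length(sample_id)),
             stringsAsFactors = FALSE)
}

#' @rdname sample_sheet
#' @param path CSV/TSV file with columns `sample_id` (or `sample`), `group`
#'   and optionally `cohort` (case-insensitive).
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_auto(path)
  names(df) <- tolower(names(df))
  if ("sample" %in% names(df) && !"sample_id" %in% names(df))
    names(df)[names(df) == "sample"] <- "sample_id"
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample sheet needs columns sample_id (or sample) and group")
  sample_sheet(df$sample_id, df$group,
               if ("cohort" %in% names(df)) df$cohort else "validation")
}

# Group labels for the samples of m, in column order; errors on samples
# missing from the sheet or carrying no label.
groups_for <- function(m, sheet) {
  idx <- match(sample_ids(m), sheet$sample_id)
  if (anyNA(idx))
    stop("samples missing from sample sheet: ",
         paste(sample_ids(m)[is.na(idx)], collapse = ", "))
  sheet$group[idx]
}
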