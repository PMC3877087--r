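#' Estimate amplification efficiency from a dilution series
#'
#' Ordinary least-squares fit of Cq on log10 input (the semi-log standard
#' curve); efficiency in percent is `E = (10^(-1/slope) - 1) * 100`, so a
#' perfect-doubling assay has slope -3.3219 and E = 100. An assay is
#' accepted when E lies within the band (default 90-110%, i.e. 10% either
#' side of perfect).
#'
#' @param dilution data.frame with columns `log10_input` and `cq` (>= 3
#'   points spanning >= 2 distinct inputs); an optional `assay` column
#'   labels the output.
#' @param band length-2 numeric acceptance band for E (percent).
#' @return one-row data.frame (class `efficiency_model`): assay, slope,
#'   intercept, r_squared, efficiency, accepted.
#' @export
estimate_efficiency <- function(dilution, band = c(90, 110)) {
  stopifnot(all(c("log10_input", "cq") %in% names(dilution)))
  if (nrow(dilution) < 3) stop("need >= 3 dilution points")
  if (stats::var(dilution$log10_input) == 0)
    stop("dilution inputs have zero variance; need >= 2 distinct inputs")
  fit <- stats::lm(cq ~ log10_input, data = dilution)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    warning("non-negative standard-curve slope; assay is not amplifying")
  eff <- efficiency_from_slope(slope)
  # noiseless series fit exactly; summary.lm warns about that, harmlessly
  r2 <- suppressWarnings(summary(fit)$r.squared)
  out <- data.frame(
    assay = if ("assay" %in% names(dilution)) dilution$assay[1] else "assay",
    slope = slope, intercept = unname(stats::coef(fit)[1]),
    r_squared = r2, efficiency = eff,
    accepted = is.finite(eff) && eff >= band[1] && eff <= band[2],
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("efficiency_model", "data.frame")
  out
}

#' @rdname estimate_efficiency
#' @param slope standard-curve slope (cycles per log10 input; negative for
#'   a functional assay).
#' @export
efficiency_from_slope <- function(slope) {
  (10^(-1 / slope) - 1) * 100
}

#' Comparative cycle-threshold difference
#'
#' `ddCq = (Cq_target,test - Cq_EC,test) - (Cq_target,cal - Cq_EC,cal)`.
#' For a multi-EC strategy the EC term is the arithmetic mean of the ECs'
#' Cq values (equivalent to the geometric mean of their linear
#' quantities). The relative quantity at 100% efficiency is `2^(-ddCq)`.
#'
#' @param target_test,target_cal target Cq in the test and calibrator
#'   sample.
#' @param ec_test,ec_cal EC Cq values (scalar or vector over the ECs of the
#'   strategy) in the test and calibrator sample.
#' @return the ddCq value in cycles.
#' @export
delta_delta_ct <- function(target_test, ec_test, target_cal, ec_cal) {
  vals <- c(target_test, ec_test, target_cal, ec_cal)
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("all four Cq terms must be present and finite")
  if (length(ec_test) != length(ec_cal))
    stop("test and calibrator EC vectors must have equal length")
  (target_test - mean(ec_test)) - (target_cal - mean(ec_cal))
}

#' Efficiency-corrected relative quantities under an EC strategy
#'
#' For target t, sample j, calibrator Cq `Cq_cal` and ECs k = 1..K with
#' per-assay percent efficiencies E:
#' `RQ_tj = (1 + E_t/100)^(Cq_t,cal - Cq_t,j) /
#'          prod_k ((1 + E_k/100)^(Cq_k,cal - Cq_k,j))^(1/K)`.
#' The multi-EC denominator is the geometric mean of the ECs' relative
#' quantities. With all efficiencies at 100% and a single EC this is
#' exactly `2^(-ddCq)`. The calibrator is either a named sample or an
#' "average control" pseudo-sample (per-assay mean Cq of the control
#' group).
#'
#' @param m a `cq_matrix`.
#' @param targets target assay ids.
#' @param ecs EC assay ids (the normalization strategy).
#' @param efficiency scalar or named per-assay percent efficiencies
#'   (default 100 for all, i.e. uncorrected perfect doubling).
#' @param calibrator a sample id, or `NULL` to use the control-group mean
#'   (requires `sheet`).
#' @param sheet sample sheet (needed for the control-mean calibrator).
#' @param control_group group label of the controls.
#' @return data.frame: target, sample, rq, log2_rq; attribute
#'   `"calibrator"` records the policy used.
#' @export
relative_quantities <- function(m, targets, ecs, efficiency = 100,
                                calibrator = NULL, sheet = NULL,
                                control_group = "control") {
  ecs <- unique(ecs)
  involved <- unique(c(targets, ecs))
  missing_a <- setdiff(involved, assay_ids(m))
  if (length(missing_a))
    stop("assay(s) not in matrix: ", paste(missing_a, collapse = ", "))
  sub <- cq_subset(m, assays = involved)
  if (any(!sub$detected[ecs, , drop = FALSE])) {
    idx <- which(!sub$detected[ecs, , drop = FALSE], arr.ind = TRUE)[1, ]
    stop(sprintf("EC assay '%s' undetected in sample '%s'",
                 ecs[idx[1]], sample_ids(sub)[idx[2]]))
  }
  eff <- efficiency_vector(efficiency, involved)
  if (is.null(calibrator)) {
    if (is.null(sheet))
      stop("control-mean calibrator needs a sample sheet")
    grp <- groups_for(sub, sheet)
    if (!control_group %in% grp)
      stop("no samples in control group '", control_group, "'")
    cal_cq <- rowMeans(sub$cq[, grp == control_group, drop = FALSE],
                       na.rm = TRUE)
    cal_label <- paste0("mean(", control_group, ")")
  } else {
    if (!calibrator %in% sample_ids(sub))
      stop("calibrator sample '", calibrator, "' not in matrix")
    cal_cq <- sub$cq[, calibrator]
    cal_label <- calibrator
  }
  log2rq_assay <- function(a) {
    log2(1 + eff[a] / 100) * (cal_cq[a] - sub$cq[a, ])
  }
  ec_l2 <- rowMeans(do.call(cbind, lapply(ecs, function(k)
    log2rq_assay(k))))  # per-sample mean over ECs of log2 quantities
  out <- do.call(rbind, lapply(targets, function(t) {
    l2 <- log2rq_assay(t) - ec_l2
    data.frame(target = t, sample = sample_ids(sub), rq = 2^l2,
               log2_rq = as.numeric(l2), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  attr(out, "calibrator") <- cal_label
  attr(out, "efficiency") <- eff
  out
}

#' EC-strategy sensitivity of target differential expression
#'
#' The design question behind EC validation: does the verdict on a target
#' miRNA depend on which EC it is normalized to? For each strategy the
#' targets' relative quantities are computed, log10-transformed and
#' compared between groups with [compare_groups()]'s gate; the result is a
#' p-value matrix (target x strategy) plus a discordance summary listing
#' targets whose significance flips between strategies.
#'
#' @param m a `cq_matrix`.
#' @param sheet sample sheet with two groups.
#' @param targets target assay ids.
#' @param strategies named list of EC id vectors, e.g.
#'   `list(U6 = "U6", pair = c("miR-16", "miR-425"))`.
#' @param efficiency per-assay percent efficiencies (scalar or named).
#' @param alpha significance level.
#' @param control_group group label used for the calibrator pseudo-sample.
#' @return list with `p_values` (matrix target x strategy), `details`
#'   (data.frame of every comparison), `discordant` (targets whose
#'   significance differs between strategies).
#' @export
ec_sensitivity_experiment <- function(m, sheet, targets, strategies,
                                      efficiency = 100, alpha = 0.05,
                                      control_group = "control") {
  if (!length(strategies)) stop("`strategies` must be non-empty")
  if (is.null(names(strategies)))
    names(strategies) <- vapply(strategies, paste, "", collapse = "+")
  if (!length(targets))
    return(list(p_values = matrix(numeric(), 0, length(strategies),
                                  dimnames = list(NULL, names(strategies))),
                details = NULL, discordant = character()))
  grp <- groups_for(m, sheet)
  glev <- unique(grp)
  details <- list()
  pmat <- matrix(NA_real_, length(targets), length(strategies),
                 dimnames = list(targets, names(strategies)))
  for (s in names(strategies)) {
    rq <- relative_quantities(m, targets, strategies[[s]],
                              efficiency = efficiency, sheet = sheet,
                              control_group = control_group)
    for (t in targets) {
      v <- log10(rq$rq[rq$target == t])
      cmp <- compare_two_samples(v[grp == glev[1]], v[grp == glev[2]],
                                 alpha = alpha)
      pmat[t, s] <- cmp$p_value
      details[[length(details) + 1L]] <- data.frame(
        target = t, strategy = s, ecs = paste(strategies[[s]],
                                              collapse = "+"),
        test = cmp$test, p_value = cmp$p_value,
        significant = cmp$p_value < alpha,
        direction = sign(mean(v[grp == glev[1]]) -
                           mean(v[grp == glev[2]])),
        stringsAsFactors = FALSE)
    }
  }
  details <- do.call(rbind, details)
  sig <- pmat < alpha
  discordant <- rownames(sig)[apply(sig, 1, function(r)
    length(unique(r)) > 1)]
  list(p_values = pmat, details = details, discordant = discordant)
}
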