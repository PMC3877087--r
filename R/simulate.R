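#' Specify a synthetic Cq cohort
#'
#' The generative model for sample j and assay i is
#' `Cq_ij = B_i + S_j + delta_i * 1[group(j) == case] + eps_ij`, with the
#' sample loading effect `S_j ~ N(0, tau^2)` shared by all assays of a
#' sample (the nuisance that endogenous controls and global-mean
#' normalization exist to remove), per-assay noise `eps_ij ~ N(0, sigma_i^2)`,
#' and replicate wells adding `N(0, sigma_rep^2)` jitter. `delta_i` is the
#' case-group shift in cycles on the Cq scale (positive delta = higher Cq =
#' lower abundance in cases).
#'
#' @param assays data.frame with columns `assay_id`, `baseline` (cycles),
#'   `sigma` (cycles, >= 0), `delta` (cycles, signed; 0 for non-differential
#'   assays), and optionally `role` (free-text tag, e.g. candidate/target).
#' @param n_case,n_control group sizes (>= 1).
#' @param tau sample loading-effect SD in cycles (>= 0).
#' @param sigma_rep replicate-well jitter SD in cycles (>= 0).
#' @param n_replicates wells per (sample, assay).
#' @param plate_size samples per plate (consecutive assignment).
#' @param plate_effect_sd SD of an additive per-plate run effect (cycles);
#'   0 disables it.
#' @param include_iac add an inter-assay control assay whose Cq depends only
#'   on the plate (a shared calibrator sample), for exercising
#'   [apply_iac_calibration()].
#' @param iac_baseline baseline Cq of the IAC assay.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(assays, n_case, n_control, tau = 0.5,
                        sigma_rep = 0.1, n_replicates = 3, plate_size = 20,
                        plate_effect_sd = 0, include_iac = FALSE,
                        iac_baseline = 18) {
  stopifnot(is.data.frame(assays),
            all(c("assay_id", "baseline", "sigma", "delta") %in% names(assays)))
  if (anyDuplicated(assays$assay_id)) stop("duplicate assay ids in spec")
  if (any(assays$sigma < 0)) stop("sigma must be >= 0")
  if (n_case < 1 || n_control < 1) stop("group sizes must be >= 1")
  if (tau < 0) stop("tau must be >= 0")
  if (sigma_rep < 0) stop("sigma_rep must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!"role" %in% names(assays)) assays$role <- "candidate"
  structure(list(assays = assays, n_case = n_case, n_control = n_control,
                 tau = tau, sigma_rep = sigma_rep,
                 n_replicates = n_replicates, plate_size = plate_size,
                 plate_effect_sd = plate_effect_sd,
                 include_iac = include_iac, iac_baseline = iac_baseline),
            class = "cohort_spec")
}

#' Default validation-cohort specification
#'
#' Emulates an RQ-PCR validation arm of 40 cancer + 20 control blood samples
#' with triplicate wells: three candidate ECs whose Cq location/scale match
#' published summaries for abundant blood miRNAs (miR-16-like mean ~15.46,
#' miR-425-like ~20.74, U6-like ~21.04 with a +0.57-cycle case shift, i.e.
#' more abundant in controls), plus three target miRNAs — a null target
#' (miR-93-like, delta = 0), a moderately shifted target (miR-181a-like)
#' and a strongly shifted target (miR-652-like). Per-assay sigma values are
#' chosen so that total per-assay SD (sqrt(sigma^2 + tau^2)) matches the
#' published totals.
#'
#' @param n_case,n_control group sizes.
#' @param tau loading-effect SD (cycles).
#' @param delta_u6 case shift of the U6-like assay (cycles).
#' @param ... passed on to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
validation_cohort_spec <- function(n_case = 40, n_control = 20, tau = 0.5,
                                   delta_u6 = 0.57, ...) {
  f <- n_case / (n_case + n_control)
  assays <- data.frame(
    assay_id = c("miR-16", "miR-425", "U6", "miR-93", "miR-181a", "miR-652"),
    baseline = c(15.460, 20.740, 21.042 - f * delta_u6, 23.0, 19.0, 24.0),
    sigma    = c(sqrt(1.342^2 - tau^2), sqrt(1.415^2 - tau^2),
                 sqrt(max(0.8^2 - tau^2, 0.01)), 0.8, 0.8, 0.8),
    delta    = c(0, 0, delta_u6, 0, 0.5, 1.5),
    role     = c("candidate", "candidate", "candidate",
                 "target", "target", "target"),
    stringsAsFactors = FALSE)
  cohort_spec(assays, n_case = n_case, n_control = n_control, tau = tau, ...)
}

#' Cohort with a designated stable pair, for parameter-recovery studies
#'
#' Five candidate assays: a designated stable pair (sigma = 0.05,
#' delta = 0) and three high-noise ones (sigma 0.3-0.8, no group effect).
#' Stability algorithms should recover the stable pair. Group-biased
#' assays are studied separately (see [headline_cohort_spec()]): a bias in
#' one panel member leaks into every gene's group contrast through the
#' sample-mean normalization, which is a property of the measurement
#' model, not an estimation artifact.
#'
#' @inheritParams validation_cohort_spec
#' @return a `cohort_spec` with attribute `"stable_pair"`.
#' @export
recovery_cohort_spec <- function(n_case = 40, n_control = 20, tau = 0.5, ...) {
  assays <- data.frame(
    assay_id = c("EC-A", "EC-B", "EC-C", "EC-D", "EC-E"),
    baseline = c(16, 19, 21, 22, 24),
    sigma    = c(0.05, 0.05, 0.30, 0.55, 0.80),
    delta    = 0,
    role     = "candidate",
    stringsAsFactors = FALSE)
  spec <- cohort_spec(assays, n_case = n_case, n_control = n_control,
                      tau = tau, ...)
  attr(spec, "stable_pair") <- c("EC-A", "EC-B")
  spec
}

#' Headline-pattern cohort: a biased EC against null and shifted targets
#'
#' Constructed to demonstrate, reliably at n = 40/20, the qualitative
#' consequence of normalizing to a group-biased EC: the U6-like candidate
#' carries a 0.57-cycle case shift while miR-16/miR-425-like candidates do
#' not; the miR-93-like target is truly null and the miR-652-like target
#' strongly shifted. Assay noise is set to 0.25 cycles so that the
#' 0.57-cycle bias is detectable with high power at these group sizes (see
#' the methods vignette for the power analysis).
#'
#' @inheritParams validation_cohort_spec
#' @return a `cohort_spec`.
#' @export
headline_cohort_spec <- function(n_case = 40, n_control = 20, tau = 0.5,
                                 delta_u6 = 0.57, ...) {
  assays <- data.frame(
    assay_id = c("miR-16", "miR-425", "U6", "miR-93", "miR-181a", "miR-652"),
    baseline = c(15.5, 20.7, 21.0, 23.0, 19.0, 24.0),
    sigma    = 0.25,
    delta    = c(0, 0, delta_u6, 0, 0.5, 1.5),
    role     = c("candidate", "candidate", "candidate",
                 "target", "target", "target"),
    stringsAsFactors = FALSE)
  cohort_spec(assays, n_case = n_case, n_control = n_control, tau = tau, ...)
}

#' Generate a synthetic Cq cohort
#'
#' Deterministic for a fixed (spec, seed); the ground-truth record carries
#' every parameter drawn, sufficient to recompute each sample's expected Cq
#' exactly as `baseline + S_j + delta * 1[case]` (+ plate effect, if any).
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (mandatory; no hidden global randomness).
#' @return a list with `cq` (a `cq_matrix` of per-well means across
#'   replicates), `replicates` (long data.frame: sample, assay, replicate,
#'   plate, cq), `samples` (sample sheet) and `truth` (spec, seed, sample
#'   effects, plate effects, expected Cq matrix).
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  n <- spec$n_case + spec$n_control
  samples <- c(sprintf("case%02d", seq_len(spec$n_case)),
               sprintf("ctrl%02d", seq_len(spec$n_control)))
  group <- rep(c("cancer", "control"), c(spec$n_case, spec$n_control))
  sheet <- sample_sheet(samples, group, cohort = "validation")
  plate <- sprintf("P%d", (seq_len(n) - 1) %/% spec$plate_size + 1)
  plate_ids <- unique(plate)
  S <- stats::rnorm(n, 0, spec$tau)
  P <- stats::setNames(stats::rnorm(length(plate_ids), 0,
                                    spec$plate_effect_sd), plate_ids)
  a <- spec$assays
  expected <- outer(a$baseline, S, "+") +
    outer(a$delta, as.numeric(group == "cancer")) +
    matrix(P[plate], nrow(a), n, byrow = TRUE)
  dimnames(expected) <- list(a$assay_id, samples)
  eps <- matrix(stats::rnorm(nrow(a) * n, 0, a$sigma), nrow(a), n)
  mu_well <- expected + eps
  reps <- expand.grid(replicate = seq_len(spec$n_replicates),
                      assay = a$assay_id, sample = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  reps <- reps[, c("sample", "assay", "replicate")]
  reps$plate <- plate[match(reps$sample, samples)]
  reps$cq <- mu_well[cbind(match(reps$assay, a$assay_id),
                           match(reps$sample, samples))] +
    stats::rnorm(nrow(reps), 0, spec$sigma_rep)
  if (spec$include_iac) {
    iac <- data.frame(sample = samples, assay = "IAC",
                      replicate = 1L, plate = plate,
                      cq = spec$iac_baseline + P[plate] +
                        stats::rnorm(n, 0, spec$sigma_rep),
                      stringsAsFactors = FALSE)
    reps <- rbind(reps, iac)
  }
  cq <- well_means(reps)
  list(cq = cq, replicates = reps, samples = sheet,
       truth = list(spec = spec, seed = seed,
                    sample_effect = stats::setNames(S, samples),
                    plate_effect = P, expected_cq = expected))
}

#' Generate a profiling-screen cohort (array layout)
#'
#' Emulates a 384-well miRNA profiling card run on 10 cancer + 10 control
#' samples: 377 miRNA assays, U6 in quadruplicate wells, RNU44, RNU48 and a
#' never-detected negative-control well (ath-miR-159a-like), i.e. 384 assay
#' wells per sample. The panel embeds literature EC candidates (miR-16,
#' miR-425, miR-484, miR-142-3p) among generically named miRNAs; a
#' designated stable set (small sigma, delta = 0, including the miR-425-like
#' assay) is recorded in the ground truth. A configurable fraction of
#' generic-miRNA wells is undetected.
#'
#' @param n_case,n_control group sizes.
#' @param n_stable number of designated near-global-mean generic assays.
#' @param undetected_fraction per-well dropout probability for generic
#'   miRNA assays (candidates and controls are always detected).
#' @param diff_fraction fraction of generic assays given a group effect.
#' @param tau loading-effect SD (cycles).
#' @param seed integer seed.
#' @return a list with `cq` (a `cq_matrix`; U6 quadruplicate collapsed to
#'   its well mean), `wells` (long well table), `samples` (sample sheet)
#'   and `truth` (per-assay parameters, designated stable set).
#' @export
generate_array_screen <- function(n_case = 10, n_control = 10, n_stable = 9,
                                  undetected_fraction = 0.05,
                                  diff_fraction = 0.1, tau = 0.5, seed) {
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  candidates <- c("miR-16", "miR-425", "miR-484", "miR-142-3p")
  n_generic <- 377 - length(candidates)
  generic <- sprintf("miR-sim-%03d", seq_len(n_generic))
  stable_set <- c("miR-425", generic[seq_len(n_stable)])
  assays <- data.frame(
    assay_id = c(generic, candidates),
    baseline = stats::runif(n_generic + length(candidates), 18, 30),
    sigma = stats::runif(n_generic + length(candidates), 0.3, 0.9),
    delta = 0, role = "mirna", stringsAsFactors = FALSE)
  assays$baseline[assays$assay_id == "miR-16"] <- 16
  assays$baseline[assays$assay_id == "miR-425"] <- 21
  assays$sigma[assays$assay_id %in% candidates] <- c(0.18, 0.05, 0.25, 0.30)
  assays$sigma[assays$assay_id %in% stable_set] <- 0.08
  assays$sigma[assays$assay_id == "miR-425"] <- 0.05
  n_diff <- round(diff_fraction * n_generic)
  diff_idx <- sample(which(!assays$assay_id %in% stable_set &
                             assays$role == "mirna"), n_diff)
  assays$delta[diff_idx] <- sample(c(-1, 1), n_diff, replace = TRUE) *
    stats::runif(n_diff, 0.5, 1.5)
  controls <- data.frame(
    assay_id = c("U6", "RNU44", "RNU48"),
    baseline = c(21, 24, 26), sigma = c(0.4, 0.5, 0.7), delta = 0,
    role = "control", stringsAsFactors = FALSE)
  assays <- rbind(assays, controls)
  n <- n_case + n_control
  samples <- c(sprintf("scr-case%02d", seq_len(n_case)),
               sprintf("scr-ctrl%02d", seq_len(n_control)))
  group <- rep(c("cancer", "control"), c(n_case, n_control))
  sheet <- sample_sheet(samples, group, cohort = "screen")
  S <- stats::rnorm(n, 0, tau)
  expected <- outer(assays$baseline, S, "+") +
    outer(assays$delta, as.numeric(group == "cancer"))
  dimnames(expected) <- list(assays$assay_id, samples)
  eps <- matrix(stats::rnorm(nrow(assays) * n, 0, assays$sigma),
                nrow(assays), n)
  mu <- expected + eps
  n_wells_of <- ifelse(assays$assay_id == "U6", 4L, 1L)
  wells <- expand.grid(assay = assays$assay_id, sample = samples,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  wells <- wells[rep(seq_len(nrow(wells)),
                     n_wells_of[match(wells$assay, assays$assay_id)]), ]
  wells$replicate <- stats::ave(seq_len(nrow(wells)), wells$sample,
                                wells$assay, FUN = seq_along)
  wells$plate <- "card"
  wells$cq <- mu[cbind(match(wells$assay, assays$assay_id),
                       match(wells$sample, samples))] +
    stats::rnorm(nrow(wells), 0, 0.1)
  generic_well <- wells$assay %in% generic &
    !wells$assay %in% stable_set
  drop <- generic_well & stats::runif(nrow(wells)) < undetected_fraction
  wells$cq[drop] <- NA_real_
  neg <- data.frame(assay = "ath-miR-159a", sample = samples,
                    replicate = 1L, plate = "card", cq = NA_real_,
                    stringsAsFactors = FALSE)
  wells <- rbind(wells[, c("assay", "sample", "replicate", "plate", "cq")],
                 neg)
  wells <- wells[, c("sample", "assay", "replicate", "plate", "cq")]
  rownames(wells) <- NULL
  cq <- well_means(wells)
  list(cq = cq, wells = wells, samples = sheet,
       truth = list(assays = assays, seed = seed, stable_set = stable_set,
                    sample_effect = stats::setNames(S, samples),
                    negative_control = "ath-miR-159a",
                    control_assays = c("U6", "RNU44", "RNU48",
                                       "ath-miR-159a")))
}

# Fast well-mean collapse for generator output (no SD gate): mean of
# detected wells per (assay, sample); all-undetected cells stay NA.
well_means <- function(reps) {
  fa <- factor(reps$assay, levels = unique(reps$assay))
  fs <- factor(reps$sample, levels = unique(reps$sample))
  cq <- tapply(reps$cq, list(fa, fs),
               function(v) mean(v[!is.na(v)]))
  cq[is.nan(cq)] <- NA_real_
  cq <- matrix(as.numeric(cq), nrow = nlevels(fa),
               dimnames = list(levels(fa), levels(fs)))
  cq_matrix(cq)
}

#' Generate a standard-curve dilution series
#'
#' Cq at dilution step d follows the exact standard-curve line for the
#' given amplification efficiency: the slope of Cq on log10 input is
#' `-1 / log10(1 + E/100)` (at E = 100%, -3.3219 cycles per 10-fold step),
#' plus optional Gaussian noise.
#'
#' @param true_efficiency percent efficiency (0 < E <= 120).
#' @param anchor_cq Cq at the undiluted point (log10 input = 0).
#' @param n_points number of dilutions (>= 3).
#' @param fold dilution factor between successive points (> 1).
#' @param noise_sd Gaussian Cq noise SD (cycles).
#' @param seed integer seed; required when `noise_sd > 0`.
#' @param assay assay label for the output table.
#' @return a data.frame with columns `assay`, `log10_input`, `cq`.
#' @export
generate_dilution_series <- function(true_efficiency = 100, anchor_cq = 20,
                                     n_points = 5, fold = 10, noise_sd = 0,
                                     seed = NULL, assay = "assay") {
  if (n_points < 3) stop("n_points must be >= 3")
  if (fold <= 1) stop("fold must be > 1")
  if (true_efficiency <= 0 || true_efficiency > 120)
    stop("true_efficiency must be in (0, 120]")
  log10_input <- -(seq_len(n_points) - 1) * log10(fold)
  slope <- -1 / log10(1 + true_efficiency / 100)
  cq <- anchor_cq + slope * log10_input
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` is required when noise_sd > 0")
    set.seed(seed)
    cq <- cq + stats::rnorm(n_points, 0, noise_sd)
  }
  data.frame(assay = assay, log10_input = log10_input, cq = cq,
             stringsAsFactors = FALSE)
}
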