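#' Pipeline configuration
#'
#' Collects every tunable threshold of the screen -> validate -> quantify
#' workflow in one declarative object. Defaults are the conventional
#' values: expressed cutoff Cq 35, replicate SD tolerance 0.28 cycles,
#' geNorm V cutoff 0.15, 3-fold equivalence bound, 90-110% efficiency
#' band, alpha 0.05.
#'
#' @param expressed_cutoff Cq below which an assay counts as expressed.
#' @param replicate_sd_max replicate-SD quality gate (cycles).
#' @param v_cutoff geNorm pairwise-variation cutoff.
#' @param fold_bound equivalence fold-change cutoff (bound = log2 of it).
#' @param efficiency_band length-2 percent acceptance band for E.
#' @param alpha significance level.
#' @param top_k nominees taken from the GME ranking.
#' @param exclusion_list assays excluded from nomination (literature step).
#' @param candidates candidate ECs carried into validation.
#' @param targets target miRNAs for the quantification stage.
#' @param strategies named list of EC strategies for the sensitivity
#'   experiment; `NULL` builds the canonical four (each candidate alone +
#'   the best-ranked pair).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(expressed_cutoff = 35, replicate_sd_max = 0.28,
                            v_cutoff = 0.15, fold_bound = 3,
                            efficiency_band = c(90, 110), alpha = 0.05,
                            top_k = 10, exclusion_list = character(),
                            candidates = c("miR-16", "miR-425", "U6"),
                            targets = c("miR-93", "miR-181a", "miR-652"),
                            strategies = NULL) {
  cfg <- list(expressed_cutoff = expressed_cutoff,
              replicate_sd_max = replicate_sd_max, v_cutoff = v_cutoff,
              fold_bound = fold_bound, efficiency_band = efficiency_band,
              alpha = alpha, top_k = top_k,
              exclusion_list = exclusion_list, candidates = candidates,
              targets = targets, strategies = strategies)
  num <- c("expressed_cutoff", "replicate_sd_max", "v_cutoff",
           "fold_bound", "alpha", "top_k")
  for (f in num)
    if (any(cfg[[f]] <= 0)) stop("`", f, "` must be positive")
  if (any(efficiency_band <= 0) || efficiency_band[1] >= efficiency_band[2])
    stop("`efficiency_band` must be an increasing positive pair")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration (JSON round trip)
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns a `pipeline_config` equal to
#'   the one written.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$strategies)) x["strategies"] <- list(NULL)
  x$exclusion_list <- as.character(x$exclusion_list)
  do.call(pipeline_config, x)
}

log_line <- function(log, ...) c(log, sprintf(...))

#' Screening stage: GME ranking and candidate nomination
#'
#' Ranks a profiling panel by deviation from the global mean, nominates
#' the top candidates after literature exclusions, and merges the
#' configured candidate list.
#'
#' @param cq a `cq_matrix` of the profiling screen (replicates collapsed).
#' @param config a [pipeline_config()].
#' @param controls control assay ids (excluded from the global mean and
#'   from nomination).
#' @return list with `ranking` (gme_ranking), `nominees`, `candidates`
#'   (nominees merged with configured candidates present in the panel),
#'   `log` (character lines).
#' @export
run_screen_stage <- function(cq, config, controls = character()) {
  log <- character()
  ranking <- rank_by_gme(cq, expressed_cutoff = config$expressed_cutoff,
                         controls = controls)
  log <- log_line(log, "screen: %d/%d assays eligible (expressed Cq < %g in all samples)",
                  sum(ranking$eligible), nrow(ranking),
                  config$expressed_cutoff)
  nominees <- withCallingHandlers(
    nominate_candidates(ranking, k = config$top_k,
                        exclusion_list = config$exclusion_list),
    warning = function(w) {
      log <<- log_line(log, "screen: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  for (a in intersect(config$exclusion_list, ranking$assay[ranking$eligible]))
    log <- log_line(log, "screen: excluded %s (exclusion list)", a)
  log <- log_line(log, "screen: nominated %s",
                  paste(nominees, collapse = ", "))
  list(ranking = ranking, nominees = nominees,
       candidates = union(nominees,
                          intersect(config$candidates, assay_ids(cq))),
       log = log)
}

#' Validation stage: summaries, group statistics and stability rankings
#'
#' Produces the per-assay Cq summary, group-difference and equivalence
#' tests, the Bartlett variance comparison, and geNorm plus
#' NormFinder-style stability rankings with a combined recommendation.
#' Candidates undetected in any sample are disqualified with a log entry.
#'
#' @param cq a `cq_matrix` of the validation cohort (replicates collapsed,
#'   plates calibrated).
#' @param sheet sample sheet (two groups).
#' @param config a [pipeline_config()].
#' @return list with `summary`, `group_tests`, `equivalence`, `variance`,
#'   `genorm` (ranking + v series; with 2 candidates, the shared M),
#'   `normfinder` (or the refusal message), `recommendation` (best single
#'   and best pair per algorithm), `candidates` (qualified set), `log`.
#' @export
run_validation_stage <- function(cq, sheet, config) {
  log <- character()
  cand <- intersect(config$candidates, assay_ids(cq))
  for (a in setdiff(config$candidates, cand))
    log <- log_line(log, "validate: candidate %s absent from matrix", a)
  ok <- vapply(cand, function(a) all(cq$detected[a, ]), TRUE)
  for (a in cand[!ok])
    log <- log_line(log, "validate: candidate %s disqualified (undetected in >=1 sample)", a)
  cand <- cand[ok]
  if (length(cand) < 2) stop("fewer than 2 qualified candidates")
  summary_tab <- summarize_assays(cq_subset(cq, assays = cand), sheet)
  group_tests <- do.call(rbind, lapply(cand, function(a)
    compare_groups(cq, sheet, a, alpha = config$alpha)))
  for (i in seq_len(nrow(group_tests)))
    if (group_tests$significant[i])
      log <- log_line(log,
        "validate: %s differs between groups (%s, p = %.4g) - flagged",
        group_tests$assay[i], group_tests$test[i], group_tests$p_value[i])
  equivalence <- do.call(rbind, lapply(cand, function(a)
    equivalence_test(cq, sheet, a,
                     bound = fold_change_bound(config$fold_bound))))
  variance <- variance_homogeneity(cq, cand, alpha = config$alpha)
  q <- to_relative_quantity(cq_subset(cq, assays = cand))
  if (length(cand) >= 3) {
    gr <- stepwise_ranking(q)
    vsel <- optimal_ec_count(q, gr, v_cutoff = config$v_cutoff)
    log <- log_line(log, "validate: geNorm final pair %s (M = %.3f); V rule: %s (n = %d)",
                    paste(gr$final_pair, collapse = "+"), gr$final_m,
                    vsel$recommendation, vsel$recommended_n)
    genorm <- list(ranking = gr, v = vsel)
    genorm_pair <- gr$final_pair
  } else {
    m2 <- stability_m(q)
    log <- log_line(log, "validate: only 2 candidates; geNorm M = %.3f for both",
                    m2[1])
    genorm <- list(m = m2)
    genorm_pair <- sort(cand)
  }
  nf <- tryCatch(normfinder_stability(cq, sheet, candidates = cand),
                 error = function(e) conditionMessage(e))
  if (is.character(nf)) {
    log <- log_line(log, "validate: NormFinder skipped: %s", nf)
    nf_pair <- NULL
  } else {
    bp <- best_pair(nf)
    nf_pair <- bp$pair
    log <- log_line(log, "validate: NormFinder best single %s; best pair %s (%.3f)",
                    nf$best_single, paste(bp$pair, collapse = "+"),
                    bp$stability)
  }
  recommendation <- list(
    genorm_pair = genorm_pair,
    normfinder_single = if (!is.character(nf)) nf$best_single,
    normfinder_pair = nf_pair,
    flagged = group_tests$assay[group_tests$significant])
  list(summary = summary_tab, group_tests = group_tests,
       equivalence = equivalence, variance = variance, genorm = genorm,
       normfinder = nf, recommendation = recommendation,
       candidates = cand, log = log)
}

#' Quantification stage: EC-strategy sensitivity of target expression
#'
#' @param cq a `cq_matrix`.
#' @param sheet sample sheet (two groups).
#' @param config a [pipeline_config()]; when `config$strategies` is
#'   `NULL`, the canonical strategies are built from the qualified
#'   candidates (each alone plus `pair`).
#' @param pair optional character(2) EC pair for the combined strategy.
#' @return list with `rq` (relative quantities per strategy), `result`
#'   (from [ec_sensitivity_experiment()]), `log`.
#' @export
run_quantification_stage <- function(cq, sheet, config, pair = NULL) {
  log <- character()
  targets <- intersect(config$targets, assay_ids(cq))
  if (!length(targets)) {
    log <- log_line(log, "quantify: no targets present; empty report")
    return(list(rq = NULL,
                result = ec_sensitivity_experiment(cq, sheet, character(),
                                                   strategies = list(none = character(0))),
                log = log))
  }
  strategies <- config$strategies
  if (is.null(strategies)) {
    cand <- intersect(config$candidates, assay_ids(cq))
    strategies <- stats::setNames(as.list(cand), cand)
    if (is.null(pair) && length(cand) >= 2) pair <- sort(cand)[1:2]
    if (!is.null(pair))
      strategies[[paste(pair, collapse = "+")]] <- pair
  }
  res <- ec_sensitivity_experiment(cq, sheet, targets, strategies,
                                   alpha = config$alpha)
  rq <- lapply(strategies, function(s)
    relative_quantities(cq, targets, s, sheet = sheet))
  for (t in res$discordant)
    log <- log_line(log, "quantify: %s verdict flips between EC strategies", t)
  if (!length(res$discordant))
    log <- log_line(log, "quantify: verdicts concordant across strategies")
  list(rq = rq, result = res, log = log)
}

#' One-command synthetic demonstration of the full workflow
#'
#' Generates the profiling screen and the validation cohort, runs the
#' screening, validation and quantification stages, and writes every table
#' plus a log under `out_dir`. Pure function of the seed: re-running with
#' the same seed reproduces the directory byte for byte.
#'
#' @param seed integer seed.
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `screen`, `validation`, `quantification`,
#'   `config`, `log`.
#' @export
run_demo <- function(seed, out_dir = NULL, config = pipeline_config()) {
  scr_data <- generate_array_screen(seed = seed)
  # exclusion list: the designated-stable generic assays, leaving the
  # miR-425-like assay as the lone nominee (the literature-screen step)
  if (!length(config$exclusion_list))
    config$exclusion_list <- setdiff(scr_data$truth$stable_set, "miR-425")
  screen <- run_screen_stage(scr_data$cq, config,
                             controls = scr_data$truth$control_assays)
  val_data <- generate_cohort(validation_cohort_spec(), seed = seed + 1)
  validation <- run_validation_stage(val_data$cq, val_data$samples, config)
  quantification <- run_quantification_stage(
    val_data$cq, val_data$samples, config,
    pair = validation$recommendation$genorm_pair)
  log <- c(sprintf("config: %s = %s",
                   names(unclass(config)),
                   vapply(unclass(config), function(x)
                     paste(format(unlist(x)), collapse = ","), "")),
           sprintf("seed: %d", seed),
           screen$log, validation$log, quantification$log)
  out <- list(screen = screen, validation = validation,
              quantification = quantification, config = config, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(x, f)
      utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
    wcsv(as.data.frame(screen$ranking), "screen_gme_ranking.csv")
    wcsv(data.frame(nominee = screen$nominees), "screen_nominees.csv")
    wcsv(validation$summary, "validation_cq_summary.csv")
    wcsv(validation$group_tests, "validation_group_tests.csv")
    wcsv(validation$equivalence, "validation_equivalence.csv")
    wcsv(validation$variance$sd_ci, "validation_sd_intervals.csv")
    if (!is.null(validation$genorm$ranking)) {
      wcsv(validation$genorm$ranking$rounds, "validation_genorm_rounds.csv")
      wcsv(validation$genorm$v$v, "validation_genorm_v.csv")
    }
    if (!is.character(validation$normfinder))
      wcsv(validation$normfinder$stability, "validation_normfinder.csv")
    wcsv(as.data.frame(quantification$result$p_values),
         "quantification_p_values.csv")
    wcsv(quantification$result$details, "quantification_details.csv")
    write_pipeline_config(config, file.path(out_dir, "config.json"))
    writeLines(log, file.path(out_dir, "demo.log"))
  }
  invisible(out)
}
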