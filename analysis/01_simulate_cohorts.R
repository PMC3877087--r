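#!/usr/bin/env Rscript
# Generate the two synthetic cohorts the analysis runs on: a 384-well
# profiling screen (10 cancer / 10 control blood samples) and an RQ-PCR
# validation cohort (40 cancer / 20 control, triplicate wells) whose Cq
# location/scale mirror the published summaries. Writes the delimited
# files every later stage reads.

library(ecselect)

seed <- 20260101
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scr <- generate_array_screen(seed = seed)
write_cq_table(scr$cq, file.path(out, "screen_cq.csv"))
write.csv(scr$samples, file.path(out, "screen_samples.csv"),
          row.names = FALSE)
write.csv(scr$truth$assays, file.path(out, "screen_truth_assays.csv"),
          row.names = FALSE)
writeLines(scr$truth$stable_set, file.path(out, "screen_stable_set.txt"))

val <- generate_cohort(validation_cohort_spec(), seed = seed + 1)
write.csv(val$replicates, file.path(out, "validation_wells.csv"),
          row.names = FALSE)
write_cq_table(val$cq, file.path(out, "validation_cq.csv"))
write.csv(val$samples, file.path(out, "validation_samples.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(seed = seed + 1, assays = val$truth$spec$assays,
       tau = val$truth$spec$tau, sigma_rep = val$truth$spec$sigma_rep),
  file.path(out, "validation_truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("screen: %d assay rows x %d samples (%d wells/sample)\n",
            nrow(scr$cq$cq), ncol(scr$cq$cq),
            nrow(scr$wells) / ncol(scr$cq$cq)))
cat(sprintf("validation: %d assays x %d samples, %d wells\n",
            nrow(val$cq$cq), ncol(val$cq$cq), nrow(val$replicates)))
cat("ground truth written alongside the data under", out, "\n")
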