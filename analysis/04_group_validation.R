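#!/usr/bin/env Rscript
# Validation statistics: per-assay Cq summaries (the Table-4-style view),
# case/control comparison of each candidate EC, equivalence testing
# against the 2-fold and 3-fold bounds, and Bartlett's comparison of
# candidate variances with Bonferroni SD intervals.

library(ecselect)

data_dir <- "results/data"
out <- "results/validation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cq <- read_cq_table(file.path(data_dir, "validation_cq.csv"))
sheet <- read_sample_sheet(file.path(data_dir, "validation_samples.csv"))
cfg <- pipeline_config()

stage <- run_validation_stage(cq, sheet, cfg)

write.csv(stage$summary, file.path(out, "cq_summary.csv"), row.names = FALSE)
write.csv(stage$group_tests, file.path(out, "group_tests.csv"),
          row.names = FALSE)
write.csv(stage$equivalence, file.path(out, "equivalence.csv"),
          row.names = FALSE)
write.csv(stage$variance$sd_ci, file.path(out, "sd_intervals.csv"),
          row.names = FALSE)
writeLines(stage$log, file.path(out, "validation.log"))

fmt <- stage$summary
fmt[, sapply(fmt, is.numeric)] <- round(fmt[, sapply(fmt, is.numeric)], 3)
cat("candidate EC Cq summary (3 dp):\n")
print(fmt, row.names = FALSE)
cat("\ngroup comparisons:\n")
print(stage$group_tests[, c("assay", "test", "p_value", "significant")],
      row.names = FALSE)
cat("\nequivalence at the 3-fold bound (log2 scale):\n")
print(stage$equivalence[, c("assay", "estimate", "ci_lower", "ci_upper",
                            "equivalent_2fold", "equivalent")],
      row.names = FALSE)
cat(sprintf("\nBartlett test across candidates: K2 = %.2f, p = %.3g\n",
            stage$variance$statistic, stage$variance$p_value))
cat("recommended pair (geNorm):",
    paste(stage$recommendation$genorm_pair, collapse = " + "), "\n")
if (length(stage$recommendation$flagged))
  cat("flagged by group comparison:",
      paste(stage$recommendation$flagged, collapse = ", "), "\n")
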