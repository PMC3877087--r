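#!/usr/bin/env Rscript
# Screening stage: rank the profiling panel by deviation from the global
# mean expression (GME), short-list the ten most stable miRNAs, and strike
# the ones with documented disease associations (here: the generator's
# designated-stable decoys), leaving the miR-425-like assay as nominee.

library(ecselect)

data_dir <- "results/data"
out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cq <- read_cq_table(file.path(data_dir, "screen_cq.csv"))
stable_set <- readLines(file.path(data_dir, "screen_stable_set.txt"))
controls <- c("U6", "RNU44", "RNU48", "ath-miR-159a")

cfg <- pipeline_config(exclusion_list = setdiff(stable_set, "miR-425"))
stage <- run_screen_stage(cq, cfg, controls = controls)

write.csv(as.data.frame(stage$ranking), file.path(out, "gme_ranking.csv"),
          row.names = FALSE)
write.csv(data.frame(nominee = stage$nominees),
          file.path(out, "nominees.csv"), row.names = FALSE)
writeLines(stage$log, file.path(out, "screen.log"))

top10 <- head(stage$ranking[stage$ranking$eligible, ], 10)
cat("top 10 assays by GME deviation score:\n")
print(top10[, c("rank", "assay", "score")], row.names = FALSE)
cat("\nnominee(s) after literature exclusions:",
    paste(stage$nominees, collapse = ", "), "\n")
cat("candidates carried to validation:",
    paste(stage$candidates, collapse = ", "), "\n")
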