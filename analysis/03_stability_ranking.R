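#!/usr/bin/env Rscript
# Stability stage: geNorm stepwise M ranking with the V_{n/n+1} series,
# and the model-based (NormFinder-style) variance decomposition, for the
# three validation candidates (miR-16, miR-425, U6).

library(ecselect)

data_dir <- "results/data"
out <- "results/stability"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cq <- read_cq_table(file.path(data_dir, "validation_cq.csv"))
sheet <- read_sample_sheet(file.path(data_dir, "validation_samples.csv"))
cand <- c("miR-16", "miR-425", "U6")

q <- to_relative_quantity(cq_subset(cq, assays = cand))
gr <- stepwise_ranking(q)
v <- optimal_ec_count(q, gr)
nf <- normfinder_stability(cq, sheet, candidates = cand)
bp <- best_pair(nf)

write.csv(gr$rounds, file.path(out, "genorm_rounds.csv"), row.names = FALSE)
write.csv(v$v, file.path(out, "genorm_v_series.csv"), row.names = FALSE)
write.csv(nf$stability, file.path(out, "normfinder_stability.csv"),
          row.names = FALSE)
write.csv(bp$all_pairs, file.path(out, "normfinder_pairs.csv"),
          row.names = FALSE)

print(gr)
cat(sprintf("geNorm V rule: %s -> n = %d ECs (%s); V cutoff %.2f\n",
            v$recommendation, v$recommended_n,
            paste(v$ec_set, collapse = " + "), v$v_cutoff))
print(nf)
cat(sprintf("NormFinder best pair: %s (stability %.3f)\n",
            paste(bp$pair, collapse = " + "), bp$stability))
cat(sprintf("inter-group bias pretest p = %.3g (tau2 = %.4g)\n",
            nf$bias_test_p, nf$tau2))
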