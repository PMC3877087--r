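# ecselect

Selection and validation of endogenous controls (ECs) for miRNA RQ-PCR in
blood specimens.

Relative quantification by RQ-PCR reports a target miRNA's quantification
cycle (Cq) against that of a reference RNA measured in the same sample, so
every conclusion is conditional on that reference being stably expressed —
across samples and, in a case/control study, across groups. An EC that is
itself shifted between groups transfers its shift, with opposite sign,
onto every target normalized to it. `ecselect` is for researchers choosing
and defending an EC strategy for circulating-miRNA studies: it implements
the complete screen → rank → validate → quantify workflow and a
synthetic-cohort generator with known ground truth, so every statistic in
the pipeline is exercisable and testable without instrument data.

## What it computes

* **Cq data handling** — wide/long delimited IO, replicate collapsing with
  the 0.28-cycle replicate-SD gate, inter-assay (between-plate)
  calibration, per-assay/per-group summaries.
* **Global mean expression (GME) screening** — per-assay score
  `SD_j(Cq_ij − GME_j)`, the SD of an assay's deviation from each sample's
  mean expressed Cq; ranking and top-k nomination with literature
  exclusions.
* **geNorm** — pairwise variation `V_jk = SD(log2 Q_j/Q_k)`, stability
  `M_j = mean_{k≠j} V_jk`, stepwise exclusion ranking, and the
  normalization-factor series `V_{n/n+1} = SD(log2 NF_n/NF_{n+1})` with the
  0.15 cutoff (argmin fallback) for choosing the number of ECs.
* **Model-based stability (NormFinder-style)** — additive decomposition of
  log2 expression into gene, sample and group effects; per-group gene
  variances by pairwise-difference least squares; group bias `d_ig` with
  pretest shrinkage; stability `ρ_i = mean_g(|d̃_ig| + se_ig)`; best
  single EC and best pair.
* **Group validation** — normality-gated Welch t / Mann-Whitney comparison
  of candidate Cq between groups; equivalence testing of the log2
  expression difference against ±1 (2-fold) and ±log2 3 ≈ ±1.58 (3-fold)
  bounds; Bartlett variance comparison with Bonferroni SD intervals.
* **Quantification** — standard-curve efficiency
  `E = (10^(−1/slope) − 1) × 100` with the 90–110% acceptance band;
  efficiency-corrected ΔΔCq relative quantities under single- or multi-EC
  strategies; the EC-sensitivity experiment (a target × strategy p-value
  matrix showing which verdicts depend on the EC).

## Worked example

A synthetic validation cohort (40 cancer / 20 control blood samples) with
three candidate ECs — miR-16-like and miR-425-like unbiased, U6-like
carrying a +0.57-cycle case shift (more abundant in controls) — and two
targets, one truly null (miR-93-like) and one strongly shifted
(miR-652-like):

```r
library(ecselect)
d <- generate_cohort(headline_cohort_spec(), seed = 11)

q  <- to_relative_quantity(cq_subset(d$cq, assays = c("miR-16", "miR-425", "U6")))
stepwise_ranking(q)
#> geNorm stepwise ranking (most stable first):
#>   miR-16 > miR-425 > U6
#> final pair: miR-16 + miR-425 (M = 0.3646)

nf <- normfinder_stability(d$cq, d$samples, c("miR-16", "miR-425", "U6"))
nf
#> NormFinder-style stability (lower = more stable):
#>    assay        rho rank
#>  miR-425 0.06962481    1
#>   miR-16 0.10236269    2
#>       U6 0.14224487    3
#> best single: miR-425

compare_groups(d$cq, d$samples, "U6")[, c("test", "p_value", "significant")]
#>      test    p_value significant
#>   welch_t 0.02950076        TRUE
```

geNorm keeps the unbiased pair (pairwise variation V = 0.127, under the
0.15 cutoff, so two ECs suffice), and the group comparison flags the
U6-like assay (Welch p = 0.030) even though its equivalence interval
[−0.56, −0.03] stays inside the ±1 two-fold bound — "statistically
different yet < 2-fold" is exactly the situation the dual difference /
equivalence view is for. Note the model-based *pair* search still picks
miR-16 + U6 (combined stability 0.041) because opposite apparent biases
cancel in a pair — stability rankings alone do not disqualify a biased EC;
the sensitivity experiment does:

```r
ec_sensitivity_experiment(d$cq, d$samples, c("miR-93", "miR-652"),
                          list(U6 = "U6",
                               "miR-16+miR-425" = c("miR-16", "miR-425")))$p_values
#>            U6 miR-16+miR-425
#> miR-93  6e-04         0.4671
#> miR-652 0e+00         0.0000
```

The null target becomes "significant" (p = 0.0006) only when normalized to
the biased EC; the truly shifted target is significant under every
strategy. `run_demo(seed, out_dir)` runs the whole pipeline (profiling
screen, nomination, validation, quantification) and writes all tables and
a log.

## Analysis workflow

The `analysis/` directory contains the narrative drivers, each writing its
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R   # the two synthetic cohorts + ground truth
Rscript analysis/02_gme_screen.R         # GME ranking, top-10, nomination
Rscript analysis/03_stability_ranking.R  # geNorm M/V + model-based stability
Rscript analysis/04_group_validation.R   # summaries, group tests, equivalence, Bartlett
Rscript analysis/05_quantification.R     # efficiencies, RQ, EC-sensitivity matrix
```

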