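---
title: "Selecting and validating endogenous controls for miRNA RQ-PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating endogenous controls for miRNA RQ-PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecselect)
```

## The problem

Relative quantification of miRNAs by RQ-PCR reports a target's
quantification cycle (Cq) against that of an endogenous control (EC)
measured in the same sample. Everything the method concludes is therefore
conditional on the EC being stably expressed across samples and — in a
case/control design — across groups. An EC that is itself shifted between
groups silently transfers its shift, with opposite sign, onto every target
normalized to it. `ecselect` implements the full candidate-selection and
validation workflow for blood-derived miRNA ECs: a global-mean-expression
screen of a profiling panel, geNorm and model-based (NormFinder-style)
stability ranking, case/control difference and equivalence testing, and
efficiency-corrected comparative quantification under alternative EC
strategies, together with a synthetic-cohort generator that makes the whole
pipeline testable without instrument data.

## Data model and quality control

A `cq_matrix` holds assays x samples Cq values with a parallel detection
mask; undetected wells carry no number. Detected Cq must lie in
`[0, max_cycles]` (default 40); a Cq of exactly 40 is a value, not a
non-detect, since instruments differ in how they censor. Replicate wells
are collapsed by arithmetic mean on the Cq scale — Cq is already a log
quantity — and a replicate set whose sample SD exceeds 0.28 cycles (the
conventional intra-/inter-assay tolerance, configurable) is excluded
outright rather than rescued by dropping a well, because any best-2-of-3
rule biases the retained mean. Between-run shifts are removed with an
inter-assay control (IAC): per plate, the IAC assay's mean Cq minus its
global mean is subtracted from every well on the plate, an additive
correction that cannot alter any within-plate contrast.

## The synthetic cohorts

The generator draws

\[
\mathrm{Cq}_{ij} = B_i + S_j + \delta_i\,[\,j \in \mathrm{case}\,]
  + \varepsilon_{ij}, \qquad
S_j \sim N(0, \tau^2),\quad \varepsilon_{ij} \sim N(0, \sigma_i^2),
\]

with replicate wells adding \(N(0, \sigma_{rep}^2)\) jitter. The shared
loading effect \(S_j\) (default \(\tau = 0.5\) cycles) is exactly the
nuisance that ECs and global-mean normalization exist to remove; noise is
Gaussian on the Cq scale, consistent with the log-abundance meaning of Cq
and with the normality-gated t-tests downstream. Three ready-made designs
are provided:

* `validation_cohort_spec()` — 40 cancer / 20 control samples, triplicate
  wells, three candidate ECs whose Cq location and scale reproduce
  published validation-cohort summaries (miR-16-like mean 15.46, total SD
  1.34; miR-425-like 20.74 / 1.42; U6-like 21.04 / ~0.8 with a
  +0.57-cycle case shift, i.e. more abundant in controls), plus three
  targets: null (miR-93-like), moderately shifted (miR-181a-like,
  +0.5 cycles) and strongly shifted (miR-652-like, +1.5 cycles). Per-assay
  \(\sigma_i\) is chosen so \(\sqrt{\sigma_i^2+\tau^2}\) matches the
  published totals.
* `recovery_cohort_spec()` — a designated stable pair
  (\(\sigma = 0.05\), \(\delta = 0\)) against three high-noise assays
  (\(\sigma = 0.30/0.55/0.80\), \(\delta = 0\)), for parameter-recovery
  studies. The unstable assays carry no group effect here: a biased panel
  member leaks \(-\delta_i/k\) into every gene's group contrast through
  the panel-mean reference (see below), which is a property of the
  measurement model, not an estimation defect, and is studied separately.
* `headline_cohort_spec()` — the biased-EC demonstration: a U6-like
  candidate with \(\delta = +0.57\) cycles among unbiased candidates, a
  truly null target and a strongly shifted one, with \(\sigma = 0.25\)
  cycles for all assays. The noise level is a design choice from a power
  analysis: a Welch test on a 0.57-cycle shift at n = 40/20 has power
  ~0.95 at a within-group SD of \(\sqrt{0.25^2+0.5^2} \approx 0.56\), but
  only ~0.74 at the published Cq scales (within-group SD ~0.8), so the
  faithful-noise cohort cannot demonstrate the pattern reliably — itself
  an instructive limitation. The screen generator
  (`generate_array_screen()`) emits the 384-well card layout: 377 miRNAs,
  U6 in quadruplicate, RNU44, RNU48 and a never-detected negative
  control, with configurable per-well dropout for the generic panel (no
  detection-call model is imposed; the dropout fraction is free).

What the generator does **not** emulate: hemolysis or cell-composition
effects, probe cross-hybridization, censoring of high-Cq wells, and any
non-Gaussian tail behaviour of real blood measurements. Passing tests
therefore certify the statistics under the stated model, not the wet-lab
behaviour of any particular assay.

## Global-mean-expression screening

For each sample the global mean expression (GME) is the mean Cq of all
expressed assays — detected and below an "expressed" cutoff, Cq < 35 by
default (the cutoff has no canonical value; it is configurable and
recorded in output). Control wells (snoRNAs, negative control) are
excluded from the mean but still scored against it, and U6's quadruplicate
wells are collapsed first. An assay's score is the sample SD of its
per-sample deviation from the GME; an assay tracking the panel mean up to
a constant offset scores 0. Eligibility requires expression in every
sample — an EC must be universally measurable. Nomination takes the top-k
short-list and then strikes assays on a user-supplied exclusion list
(literature screening is a manual step), which can leave a single nominee.

## geNorm

Quantities are reconstructed from Cq as
\(Q_{ij} = (1+E_i/100)^{\mathrm{anchor}_i - \mathrm{Cq}_{ij}}\) (default
\(E = 100\%\), anchor at the per-assay minimum; the anchor cancels in all
ratio statistics, which the tests verify). Pairwise variation
\(V_{jk}\) is the sample SD of \(\log_2(Q_j/Q_k)\); the stability measure
\(M_j\) is the mean of \(V_{jk}\) over the other candidates; ranking
proceeds by stepwise exclusion of the highest-M assay, ties broken by
assay name and reported. The optimal EC count examines
\(V_{n/n+1} = \mathrm{SD}(\log_2 NF_n/NF_{n+1})\), with \(NF_n\) the
per-sample geometric mean of the n most stable assays' quantities: the
recommendation is the smallest n with \(V_{n/n+1} < 0.15\) (the canonical
heuristic), falling back to the minimizing n when no V clears the cutoff
— required behaviour for small candidate panels, where the best V
typically exceeds 0.15. Log base 2 and n−1 SDs are used throughout. All
geNorm outputs are invariant to per-sample scaling, the algorithm's
defining property; missing candidate values are never imputed —
incomplete candidates are disqualified upstream.

## Model-based stability (NormFinder-style)

The model is the additive decomposition of log2 expression
(\(y = -\mathrm{Cq}\), so one cycle is one log2 unit at 100% efficiency)
into gene, sample and group effects. Sample effects are removed exactly by
subtracting each sample's mean over the k candidates. Three estimation
choices deserve record, because the original method's finite-gene
correction has published variants and the algorithm here is validated by
parameter recovery and invariants rather than by matching any historical
spreadsheet:

1. **Gene variances from pairwise differences.** For genes i and l,
   \(\mathrm{Var}(y_i - y_l) = \sigma_i^2 + \sigma_l^2\) exactly — sample
   effects and the panel-mean noise cancel in every difference. The k
   per-group variances are recovered from the \(k(k-1)/2\) pairwise
   sample variances by iteratively reweighted least squares (weights
   \(1/(\sigma_i^2+\sigma_l^2)^2\), the delta-method precision of a
   sample variance), truncated at 0. This is the finite-gene correction
   in pairwise form; unlike the classical
   \(k/(k-2)\)-style inversion of the deflated within-panel variances, it
   does not propagate the shared panel-mean noise into every gene's
   estimate, which matters when a \(\sigma = 0.05\) gene sits in a panel
   with \(\sigma = 0.8\) neighbours. Recovery is unbiased in the tests'
   bias checks (median relative error ~5% at n = 40/20, k = 5).
2. **Group contrasts and their covariance.** The per-gene, per-group
   contrast \(d_{ig}\) (group means of the sample-centred data, centred
   across groups with equal weights, so \(\sum_g d_{ig} = 0\); groups are
   deliberately not weighted by size in a case/control design) has a
   known model covariance across genes: the panel-mean reference makes
   all contrasts correlated and the constraint makes the covariance rank
   k−1.
3. **Pretest shrinkage of apparent biases.** With few genes, one noisy
   gene's sampling error masquerades as group bias and leaks \(-d/k\)
   into every other contrast. The between-gene bias variance \(\tau^2\)
   is therefore estimated by a pretest: the Mahalanobis form of the
   contrast vector against its model covariance is chi-square(k−1) under
   the no-bias null, and only when it rejects at the 5% level is
   \(\tau^2\) set to the method-of-moments value
   \(\max(0, \mathrm{mean}(d^2 - \mathrm{se}^2))\); otherwise apparent
   biases are shrunk fully to zero. Each contrast is then shrunk by
   \(\tau^2/(\tau^2 + \mathrm{se}^2_{ig})\) and the stability value is
   \(\rho_i = \mathrm{mean}_g(|\tilde d_{ig}| + \mathrm{se}_{ig})\); with
   a single group \(\rho_i\) reduces to the estimated gene SD.

The best pair treats the combination as the mean of its members on the
log scale: biases average (so opposite-sign biases cancel — the rationale
for two-EC normalization) and the sampling variance is a quarter of the
sum; the same |bias| + SE composition scores the pair. The exact
correction used is recorded in the result's `correction` field. The
method needs at least three candidates and refuses fewer.

## Group validation

Raw candidate Cq values are compared between groups behind a normality
gate: Lilliefors-corrected Kolmogorov–Smirnov per group (estimated
parameters make the plain KS test invalid; Shapiro–Wilk stands in below
n = 5), then Welch's t-test when both groups pass at α = 0.05, otherwise
Mann–Whitney U. Welch is the parametric default because group sizes are
unequal (40 vs 20) and the candidates demonstrably differ in variance
(the Bartlett comparison below). Equivalence testing surrounds the
difference of group means on the log2 expression scale (−Cq, stated
explicitly in reports since the sign flips relative to Cq) with a
symmetric two-sided 95% Welch interval; the assay is equivalent at a
bound b when the whole interval lies in \([-b, +b]\), evaluated at ±1
(2-fold) and ±log2 3 ≈ ±1.58 (3-fold, the default cutoff). A 90%-interval
TOST mode is available via `ci_level`. Variance homogeneity across
candidates uses Bartlett's test with per-assay chi-square SD intervals at
Bonferroni-adjusted level α/m.

## Quantification

Amplification efficiency comes from the slope of the semi-log standard
curve, \(E = (10^{-1/\mathrm{slope}} - 1) \times 100\), with acceptance
band 90–110% (±10% around perfect doubling; slope −3.3219 at 100%).
Relative quantities follow the comparative ΔΔCq method with per-assay
efficiency correction; a multi-EC strategy aggregates ECs by the
geometric mean of their linear quantities (arithmetic mean in Cq space) —
the standard multi-reference factor, since "combined use" has no unique
formula. The calibrator defaults to an "average control" pseudo-sample
(per-assay mean Cq of the control group), flagged in output, because no
named calibrator is canonical; any sample can be named instead. When no
dilution series is supplied, efficiencies default to 100% with a flag.
The EC-sensitivity experiment recomputes each target's group comparison
(on log10 relative quantities, behind the same normality gate) under each
EC strategy and reports the p-value matrix and the targets whose verdict
flips — the operational definition of "your conclusion depends on your
EC".

## Numerical and reporting choices

Summaries mirror instrument-report conventions (3-decimal rounding) only
at the formatting step; all computation is full precision. Ranking ties
break lexicographically and are flagged. Degenerate inputs are defined:
identical replicate sets pass with SD 0; an all-constant comparison
returns p = 1; a zero-variance dilution input axis errors; a sample-less
group errors. Generation, the pipeline stages and the demo are pure
functions of (spec, seed) — reruns are byte-identical.

## Problem sizes

The test-suite simulations use the study's group sizes (40/20 screen-arm
style cohorts for calibration and recovery) at seed counts chosen to make
the binomial noise on the checked rates small relative to their margins:
200 cohorts for stable-pair recovery, 1,000 for null calibration, 500 for
the biased-EC pattern, and 1,000 random instances for oracle agreement.
The acceptance script uses the same designs at 100–400 seeds.

## Known limitations

The faithful-noise validation cohort shows that at published Cq scales a
0.57-cycle group bias in a low-variance control is *harder to detect than
to suffer from*: variance-based stability rankings (geNorm M, and the
model-based score when biases shrink to zero) can legitimately rank the
biased U6-like assay above noisier unbiased candidates — which parallels
the original study's own tables, where the model-based best pair included
U6. The group-difference test and the EC-sensitivity experiment, not the
stability rankings, are what disqualify a biased EC; the package's
combined recommendation therefore reports both. The pretest controls the
false declaration of inter-group variation at ~5% but, like any pretest
estimator, is discontinuous at the threshold. NormFinder-style estimates
assume uncorrelated gene noise; duplicated or co-regulated candidates
violate this (geNorm's assumption too) and are flagged only insofar as
their pairwise variation collapses.
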