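Package: ecselect
Title: Selection and Validation of Endogenous Controls for miRNA RQ-PCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for identifying and validating stably expressed endogenous
    control (EC) RNAs for normalization of miRNA RT-qPCR data from blood
    specimens. Implements quantification-cycle (Cq) data handling with
    replicate quality control and inter-assay calibration, stability
    screening by global mean expression, geNorm stability ranking (M values,
    pairwise variation V), NormFinder-style model-based stability estimation,
    case/control equivalence testing against fold-change bounds, standard-curve
    amplification-efficiency estimation, and efficiency-corrected comparative
    (delta-delta-Cq) relative quantification under alternative EC strategies.
    Ships a synthetic-cohort generator with known ground truth so the whole
    workflow is exercisable and testable without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
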