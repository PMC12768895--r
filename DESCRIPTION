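Package: plasmacna
Title: Copy-Number Aberration Analysis of Plasma ctDNA from Low-Pass
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("plasmacna", "developers", email = "dev@plasmacna.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting chromosomal copy-number
    aberrations in circulating tumor DNA from shallow (0.1-0.5x)
    whole-genome sequencing of plasma. Read counts in fixed-width genomic
    bins are standardized against a panel of healthy-control plasma
    profiles to per-bin Z-scores and log2 ratios, segmented with a
    from-scratch circular binary segmentation implementation using
    permutation significance, and summarized into a tumor-DNA fraction
    (TFx) estimate via a grid-search mixture model over integer copy
    states. Downstream scoring includes a homologous-recombination
    deficiency score (count of large genomic alterations), arm-level
    gain/loss calls from Stouffer-aggregated Z-scores, Wilcoxon group
    comparisons, and ROC/Youden diagnostic evaluation. A negative-binomial
    simulator generates labeled synthetic low-pass WGS cohorts
    (neuroblastoma-typical event presets, paired pre/post-chemotherapy
    designs) so the full pipeline is testable without access-controlled
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
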