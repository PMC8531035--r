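Package: drugTargetMR
Title: Drug-Target Mendelian Randomization for Lipid-Lowering Target Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An LD-aware drug-target Mendelian randomization (MR) pipeline for
    prioritizing druggable genes through their genetic associations with blood
    lipids (LDL-C, HDL-C, triglycerides) and a binary disease outcome such as
    coronary heart disease. Implements harmonization of GWAS summary statistics,
    reference-panel quality control and LD estimation, genome-wide and
    gene-centric (cis) instrument selection with greedy LD clumping, generalized
    least squares IVW and MR-Egger estimation with a Rucker-type model-selection
    framework, heterogeneity and leverage pruning, multivariable MR, approximate
    Bayes factor colocalization with a stepwise (COJO-style) conditional
    decomposition, tissue-specificity scoring (tau and per-tissue z-scores),
    replication concordance, keyword-based drug-annotation matching, a
    region-based phenome-wide scan, and a synthetic-data generator that emulates
    the two-sample discovery/replication design so that the whole pipeline is
    testable without consortium downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
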