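Package: fcdmeth
Title: MBD-Capture Methylation Analysis for Focal Cortical Dysplasia Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for methyl-binding-domain (MBD)
    capture sequencing of paired brain and blood samples from epilepsy surgery
    cohorts. Builds consensus methylated regions from per-sample peak calls,
    annotates them (CpG counts, genomic features, nearest genes), fits
    covariate-adjusted negative-binomial generalized linear models with
    spike-in offsets to call differentially methylated regions across focal
    cortical dysplasia (FCD) subtype contrasts, estimates leukocyte
    composition of blood samples by constrained reference-based deconvolution,
    selects ROC-based biomarker panels distinguishing FCD IIb from IIa,
    ranks combinatorial marker/clinical-factor classifiers, and quantifies
    percent methylation from Methyl-qPCR bound/unbound fractions. Ships a
    synthetic cohort generator mirroring the study design so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
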