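Package: chronomm
Title: Timing Multiple Myeloma Evolution from Mutational Signatures
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the chronology of multiple myeloma (MM)
    development from whole-genome somatic mutation data. Implements
    constrained mutational-signature fitting with cosine-similarity
    censoring and multinomial bootstrap confidence intervals, kataegis
    detection with structural-variant proximity annotation, APOBEC3A/3B
    tetranucleotide (YTCA/RTCA) classification, molecular-time estimation
    of chromosomal gains from duplicated and non-duplicated clonal
    mutations, calibration of the clock-like SBS5 mutation rate with
    through-origin random-slope mixed-effects models, and conversion of
    mutation burdens into absolute patient ages at landmark events such as
    chromosomal gains and the emergence of the most recent common
    ancestor. A synthetic-cohort generator with full ground truth closes
    the test loop for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    Rsamtools,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
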