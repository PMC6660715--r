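Package: methTMB
Title: Linking Tumor Mutation Burden to DNA Methylation Aberrance in NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline connecting tumor mutation burden
    (TMB) to DNA-methylation aberrance in paired tumor/normal cohorts profiled
    by whole-exome sequencing and EPIC-style methylation arrays. Provides
    somatic-variant filtering, nonsynonymous mutation counts (NOMs) and per-Mb
    TMB with tertile stratification, 96-trinucleotide-context mutational
    spectra with nonnegative-least-squares signature refitting, per-probe and
    per-sample differential methylation (DMP/MVP) calling, bump-hunting
    detection of differentially methylated regions with a permutation null,
    subsampled k-means consensus clustering, arm-level copy-number calls and
    aneuploidy scores from probe intensities, and the cross-cutting
    association statistics tying the stages together. A synthetic-cohort
    generator with a recorded ground truth supports recovery testing of every
    stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    pracma,
    jsonlite,
    rlang
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
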