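Package: hydrareg
Title: Multi-Omic Analysis of the Injury Response in Hydra Regeneration
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq and ATAC-seq time courses of
    head and foot regeneration in Hydra after mid-gastric bisection.
    Implements negative-binomial quasi-likelihood differential testing of
    count matrices, regeneration context-effect contrasts, TCF-dependence
    classification under iCRT14 treatment, chromVAR-style transcription
    factor motif deviation scores with GC-matched backgrounds,
    irreproducible discovery rate (IDR) peak consensus with ENCODE-style
    quality ratios, TSS enrichment scoring, hypergeometric and Fisher
    enrichment statistics, peak-to-gene assignment, and a four-criteria
    screen for candidate injury-responsive transcription factors. A
    synthetic multi-omic data generator emulates the full experimental
    design (structure x timepoint x treatment) with planted effect sets
    and a machine-readable ground truth, so every stage of the pipeline
    can be exercised and validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    edgeR,
    IRanges,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
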