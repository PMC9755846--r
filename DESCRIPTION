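Package: cdrlight
Title: Common Deletion Region Discovery and qPCR Copy-Number Calling at
    Tumor-Suppressor Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers common deletion regions (CDRs) from cohorts of
    somatic deletion intervals by sweep-line breakpoint coverage, scores
    PCR amplicons for containment in deletion fragments, quantifies gene
    copy number from multiplex qPCR Ct data (replicate aggregation,
    reference-gene informativeness gating, delta-delta-Ct relative
    quantification, paired-normal deletion/amplification calling,
    titration efficiency, spike-in mixture linearity and detection-limit
    estimation), and computes the contingency-table association
    statistics (odds ratios, Fisher's exact and chi-square tests,
    Cochran-Armitage trend test) used to relate CDKN2A 9p21 deletion
    calls to clinicopathological covariates. Includes seeded synthetic
    generators for deletion cohorts, qPCR plates and clinical tables so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    IRanges
Config/testthat/edition: 3
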