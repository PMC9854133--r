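Package: oncopanel
Title: Tumor Profiling from Targeted Cancer-Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling tumor profiling for targeted gene-panel
    sequencing of formalin-fixed tumor samples, developed around a
    523-gene / 1.94 Mb hybrid-capture assay applied to male breast cancer.
    Implements pathogenic (driver) somatic variant triage from annotated
    tumor-only calls, loss-of-heterozygosity evaluation at germline
    pathogenic variants, gene-level copy-number gain/loss classification
    from fold-changes, tumor mutational burden (mutations per megabase)
    with high/low stratification, microsatellite instability from
    homopolymer-locus read-length histograms, knowledge-base driven
    clinical actionability annotation, and cohort-level reporting with an
    oncoprint-style alteration matrix. Includes a synthetic cohort
    simulator with ground truth and a bundled 15-sample reference cohort
    so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
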