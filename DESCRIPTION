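Package: retinaldx
Title: Diagnostic Variant Triage, Classification and Reporting for an
    Inherited Retinal Disease Gene Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-implements the computational core of a targeted
    next-generation-sequencing diagnostic service for inherited retinal
    disease (IRD). Provides gene-panel and transcript models, VCF ingest
    with allele normalisation, platform-specific quality triage,
    population-frequency and recurrence filtering, transcript consequence
    annotation, an ACMG-style rule cascade for pathogenicity
    classification, inheritance-aware molecular diagnosis and carrier
    calling with family segregation, per-base coverage quality control,
    and cohort-level reporting of diagnostic yield, variant novelty and
    gene-discovery-year statistics. A synthetic-cohort simulator with
    known truth labels makes every pipeline stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    IRanges,
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
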