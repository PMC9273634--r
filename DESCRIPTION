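Package: denovotrio
Title: De Novo Mutation Discovery and Prioritization in Case-Parent Trios
Version: 0.1.0
Authors@R:
    person("AfriCRAN", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a whole-genome case-parent trio analysis for de novo
    mutation (DNM) discovery in orofacial clefting cohorts: pedigree and
    sample quality control (missingness, X-chromosome sex check,
    Hardy-Weinberg exact test, Mendelian-error and heterozygosity outlier
    screens, kinship validation), a staged variant filtration funnel
    (genotype quality, de novo configuration, protein-altering consequence,
    population allele frequency), transcript-model consequence annotation,
    CADD/SIFT/PolyPhen pathogenicity binning, folding free-energy (ddG)
    stability classification, hypergeometric (Fisher/EASE) gene-set
    enrichment, and craniofacial tissue expression contrasts. Ships a
    synthetic trio-cohort simulator with planted truth so the full pipeline
    is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
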