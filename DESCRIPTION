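Package: ocpmd
Title: Recessive Disease-Gene Discovery and Myofibre Contractility Analysis
    for Ovine TNNT1 Congenital Myopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the discovery and validation
    analyses behind the identification of a splice-donor deletion in ovine
    TNNT1 as the cause of ovine congenital progressive muscular dystrophy
    (OCPMD): pedigree-aware runs-of-homozygosity mapping from SNP-array
    genotypes, a segregation-based variant-prioritization cascade over
    per-sample VCFs and low-coverage pileup summaries, splice-donor
    intron-retention consequence modelling (mutant transcript, translation to
    the premature stop, C-terminus residue accounting, molecular weight,
    in-silico RT-PCR), and Hill-equation force-pCa contractility analysis
    (pCa50, Hill coefficient, derived calcium concentrations, group
    comparison). A synthetic-data module forges a TNNT1-like gene model and
    simulates the full study cohort - deep and low-coverage sequenced sheep
    with a planted homozygous splice-donor deletion, an autozygous SNP-array
    block, and force-pCa measurements - so every stage runs and is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
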