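Package: gliomaRelapse
Title: Multi-Omic Analysis of Paired Primary and Relapsed Oligodendroglioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a multi-omic tumor-relapse analysis
    workflow for 1p/19q-codeleted diffuse glioma: somatic-variant artifact
    filtering via a cross-patient chi-squared test, trinucleotide mutational
    signatures and POLE hypermutator scoring, window-based copy-number
    log-ratio tracks with arm-level calls (1p/19q codeletion, chromosome 7
    gain) and focal TSS-deletion detection, structural-variant filtering with
    intragenic-rearrangement annotation, DNA-methylation probe-to-gene
    collapsing by Spearman-distance clustering, WHO-2021 molecular subtype
    classification, and Kaplan-Meier/log-rank survival stratification by
    expression cutoffs. All stages are exercised on a synthetic paired-cohort
    generator that plants the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    withr,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    survival,
    knitr,
    rmarkdown
Config/testthat/edition: 3
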