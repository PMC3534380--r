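Package: pgint
Title: Personal Genome Interpretation: Variant QC, Annotation and Likelihood-Ratio Disease Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for interpreting a single deeply sequenced
    personal genome. Applies depth and quality filters to variant calls,
    checks genotype concordance against array data, summarises coverage
    against a Poisson reference, classifies variants by genomic region,
    coding consequence, repeat and regulatory context, profiles variant
    density around transcription start sites, tests gene-set enrichment,
    compares the subject against panel genomes to identify novel variants,
    classifies mitochondrial substitutions, and combines genotype
    likelihood ratios into post-test disease probabilities (RiskOgram)
    with population percentiles and pharmacogenomic lookup. Ships a
    synthetic-data module that generates every input with planted,
    manifest-recorded ground truth so the whole pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    withr,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
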