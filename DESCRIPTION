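Package: mirpattern
Title: Discovery and Cross-Genotype Pattern Classification of
    Stress-Responsive miRNAs from Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for identifying dehydration-responsive microRNAs
    from unreplicated small RNA sequencing libraries of two plant genotypes.
    Covers adapter trimming and quality filtering, collapsing reads to unique
    tags, cascade annotation against rRNA/tRNA/snoRNA/snRNA and mature miRNA
    references, novel miRNA calling by perfect genome mapping and hairpin
    folding with plant annotation criteria, tags-per-million normalisation
    with a pseudocount for zero counts, exact Poisson (Audic-Claverie) and
    chi-square differential-expression tests with Benjamini-Hochberg FDR
    control, four-way classification of cross-genotype expression patterns,
    miRU-style miRNA-target complementarity scoring, and 2^-ddCT qPCR
    arithmetic. Includes a synthetic small RNA study generator with a known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
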