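Package: ysubtract
Title: Inference of Y-Linked Transcripts by Male/Female Subtraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies Y-chromosome-linked transcripts from male and female
    genome and transcriptome sequencing data using a staged subtraction
    pipeline: transcripts assembled from male RNA-seq reads that do not map to
    a female genome assembly are filtered against the female genome, female
    RNA-seq reads, male/female genomic read coverage, relative expression, a
    k-mer-derived repeat library, and an effective-length criterion. Includes
    a sex-swapped false-positive control, paralog discovery with Nei-Gojobori
    Ka/Ks divergence estimation, X-versus-autosome scaffold classification
    from normalized male/female coverage ratios, tissue-expression
    quantification (TPM) with exact binomial enrichment tests for testis
    bias, and a seeded synthetic-data generator that plants Y genes of known
    origin so that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
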