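Package: somaticmz
Title: Somatic SNV Discovery and Clonality Analysis for Paired Tumor/Normal Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor/normal somatic single-nucleotide-variant discovery for
    microdissected splenic marginal zone lymphoma exomes: a coverage, allele
    frequency and call-quality filtering cascade; HGVS substitution parsing with
    mutation-class and transition/transversion summaries; variant-allele-fraction
    based clonality classification; SNP-array copy-number segment filtering and
    variant overlap; a binomial likelihood-ratio test placing a mutation on the
    duplicated or non-duplicated allele of a single-copy gain; and pooled
    recurrence statistics across discovery and targeted-validation cohorts.
    Includes a synthetic paired-cohort generator with ground-truth labels so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
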