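Package: mthet
Title: Heteroplasmy and Somatic mtDNA Variant Analysis in Paired Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-alignment analysis of mitochondrial DNA heteroplasmy in
    paired tissue cohorts: threshold heteroplasmy calling from per-site
    allele counts, rCRS-coordinate consequence annotation under the
    vertebrate mitochondrial code, coverage and haplogroup-concordance
    sample QC, case/control mutational-burden statistics (exact Fisher,
    Mann-Whitney with exact small-sample p-values, Pearson chi-squared,
    Bonferroni), a four-class somatic variant taxonomy for paired tissues
    (de novo, loss, positive and negative heteroplasmic shift), a
    reference-set filter chain with codon-usage tables, and a synthetic
    paired-cohort generator so the whole pipeline is exercisable without
    tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
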