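Package: sexscan
Title: Sex-Locus Discovery from Pooled and RAD Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection of sex-differentiated and Y-specific genomic regions
    in species with undifferentiated sex chromosomes. Implements pooled-
    sequencing scanning for sex-specific SNPs with between-sex FST in
    sliding windows, detection of Y-specific sequence from male/female
    coverage contrasts, RAD-seq marker presence/absence sex-segregation
    analysis with the sex-bias statistic S, linkage-map marker filtering,
    exact and chi-squared 2x2 association tests, and a seeded simulator of
    XY populations (pooled nucleotide counts, RAD family panels, mapping
    genotypes) with machine-readable truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
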