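Package: fmrscreen
Title: Family-Based Screening of FMR1 CGG Repeat Expansions from WGS Repeat Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population- and family-based screening of the FMR1 CGG
    trinucleotide repeat from whole-genome-sequencing repeat genotypes.
    Reads ExpansionHunter-style JSON/VCF calls, PCR genotype tables and PED
    pedigrees; classifies alleles into normal, gray-zone, premutation and
    full-mutation ranges; infers X-linked parental transmission and de novo
    expansions in trio/quad families; and computes carrier prevalence,
    sex-stratified Fisher exact burden tests, female Hardy-Weinberg
    equilibrium checks and call-set concordance. A synthetic-cohort
    generator with a known ground truth and an ExpansionHunter-like
    measurement model makes every pipeline stage testable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    vcfR,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
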