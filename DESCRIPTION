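Package: ssrmine
Title: Mining Potentially Polymorphic Microsatellite Loci from Multiple
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects simple sequence repeats (SSRs, microsatellites) in de
    novo-assembled transcripts, aggregates repeat-count observations across
    samples under exact flanking-sequence keys to flag potentially polymorphic
    loci, extracts and verifies primer-ready candidate amplicon sequences, and
    computes marker polymorphism statistics (number of alleles, major-allele
    frequency, polymorphism information content) from fragment-length genotype
    tables. Includes a synthetic transcriptome and genotype generator with
    known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
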