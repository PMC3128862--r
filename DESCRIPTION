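Package: viromelib
Title: Direct-Cloned Viral Metagenome Shotgun Library Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing shotgun clone libraries prepared from
    purified marine virus assemblages: trimming and greedy overlap
    assembly of Sanger reads, annotation of tabular similarity-search
    hits with keyword-based virus detection, E-value threshold
    sensitivity analysis, reciprocal read-length-normalised library
    comparison, and virus-particle and DNA accounting from
    density-gradient fractions.  A synthetic-data generator emulates the
    sampling design of a direct-cloned virome survey (multi-size-class
    genomes, sheared size-selected clone inserts with paired end reads,
    similarity-hit tables with controlled source composition, CsCl
    gradient profiles) so that every step of the pipeline can be tested
    against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
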