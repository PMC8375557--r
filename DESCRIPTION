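Package: rad2b
Title: Sex-Specific Marker Discovery from 2b-RAD Tag Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering sex-linked markers from type IIB
    restriction-site associated DNA (2b-RAD) sequencing of a gonochoristic
    population. Provides in-silico BsaXI digestion and 27-nt tag extraction,
    read quality filtering, catalog-based tag locus clustering and depth
    threshold genotyping, k-mer genome-size and heterozygosity survey,
    Fisher exact screening for sex-specific tags and sex-associated SNPs,
    ZW/XY heterogamety inference, in-silico PCR concordance reporting, and a
    fully synthetic diploid population simulator with ground-truth tables so
    every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
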