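Package: spermkaryo
Title: Sperm Aneuploidy Scoring from FISH Signals and Exome Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying chromosomal abnormalities in sperm
    specimens from two complementary assays. A control-normalized exome
    read-depth molecular karyotype calls gene-level copy-number gains and
    losses (1.5x duplication and 0.5x deletion thresholds over more than
    70 percent of a gene's exons), ranks calls by log2 ratio, filters
    polymorphic regions, assigns homozygosity from heterozygous SNP
    fractions, and summarizes chromosome-level aneuploidy. A nine-probe
    FISH scorer classifies per-cell probe signal counts into disomy,
    nullisomy, diploidy and euploidy and aggregates them into
    specimen-level rates with replicate reconciliation. TUNEL chromatin
    fragmentation scoring, ICSI outcome-rate tables, and the
    nonparametric group comparisons used alongside these assays are
    included, together with seeded synthetic-data generators so every
    stage is verifiable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
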