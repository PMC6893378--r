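Package: paralogscreen
Title: Dual-Query Paralog Genetic Interaction Screening and
    Strand-Specific Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for dual-query synthetic genetic array (SGA)
    screens of gene paralogs and for strand-specific RNA-seq surveys of the
    resulting mutants. Scores colony-array fitness ratios, estimates hit
    thresholds from the ratio distribution, calls negative and suppressor
    genetic interactions, and partitions interactors into paralog-unique,
    common, and masked sets. Implements a two-library chi-squared /
    Benjamini-Hochberg differential-expression test at gene and fixed-width
    bin resolution with fold-change and minimum-read filters, merges
    differential bins into genic and intergenic region calls, builds scaled
    100-unit metagene coverage profiles with a 5'-bias statistic, and
    provides qPCR delta-delta-Ct fold changes, hypergeometric category
    enrichment, and reporter-propagation retention statistics. A
    synthetic-data module generates colony tables, fragment alignments, and
    propagation outcomes with known planted truth so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
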