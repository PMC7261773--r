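Package: windmr
Title: Sliding-Window Differential Methylation Analysis for Paired Plant Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two whole-genome bisulfite sequencing methylomes (for
    example a diploid and an autotetraploid derived from it) at single-cytosine
    resolution. Reads Bismark-style cytosine reports, applies joint coverage
    filtering, profiles per-context methylation levels, densities and
    cross-sample correlations, calls differentially methylated regions with a
    sliding-window Kruskal-Wallis rank test and Benjamini-Hochberg correction,
    merges same-trend regions, annotates them against gene models, and tests
    the association between gene-region DMR type and differential expression.
    Includes a beta-binomial methylome and expression simulator with planted
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    yaml,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
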