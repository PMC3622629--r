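Package: cseMotifs
Title: Motif-Based Discovery of Context-Specific Sequencing Errors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers sequence motifs that induce systematic, strand-biased
    base-calling errors (context-specific errors, CSEs) in aligned
    short-read data. Genomic positions are pooled by generalized-string
    motifs over {A,C,G,T,N}; pooled match/mismatch contingency tables are
    tested for strand bias with a log-space implementation of Fisher's
    exact test under the probability-ordering two-sided definition;
    significant motifs are filtered by reverse error rate and error-rate
    difference and ranked. Includes a statistical power simulator for
    position-wise strand-bias testing, BED annotation tracks of error-prone
    positions with variant filtering, and a synthetic read generator with
    planted context-specific errors for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    Rsamtools,
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
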