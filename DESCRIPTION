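Package: iesret
Title: Retention Scoring and Feature Analysis of Internal Eliminated
    Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide analysis of the precise excision of Internal
    Eliminated Sequences (IESs) during programmed genome rearrangement in
    ciliates. Classifies junction-spanning paired-end reads as IES+
    (retention) or IES- (excision), computes per-IES apparent retention
    scores from whole-cell DNA modelled as a mixture of new developing
    somatic (MAC) and old-MAC material, calls significantly retained IESs
    against a control knockdown with a one-sided exact test and
    Benjamini-Hochberg correction, and characterizes retained-IES sets
    (length-peak fractions, neighbor-density enrichment indexes, matched
    random-sampling nulls, replicate overlap and correlation). A synthetic
    data module generates MAC/germline genome pairs with TA-bounded IESs,
    condition-specific retention truths and error-free paired-end reads so
    the whole pipeline runs and is tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    withr,
    yaml,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
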