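Package: xenodissect
Title: Virtual Dissection of Xenograft RNA-Seq into Cancer and
    Microenvironment Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Separates bulk patient-derived-xenograft (PDX) RNA-seq samples
    into cancer (human) and microenvironment (mouse) expression datasets via
    organism-unique k-mer read classification against a pair of
    prefix-labelled references, then runs the downstream analyses that the
    two-compartment view enables: per-species TPM normalization,
    composition-adjusted negative-binomial differential expression with the
    read-fraction covariate, recurrent-gene calling across PDX lines,
    single-sample GSEA with cross-line sum-of-enrichment-score ranking,
    ANOVA-based attribution of metastasis-signature genes to the host liver
    compartment, and triad-based classification of microenvironment-induced
    versus metastasis-selected genes.  A synthetic-cohort module generates
    references, reads, counts, metadata and ground-truth tables with the
    statistical structure these analyses assume, so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
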