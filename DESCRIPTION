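Package: lncforge
Title: Construction and Characterization of Long Noncoding RNA Catalogs
Version: 0.1.0
Authors@R:
    person("lncforge", "developers", email = "lncforge@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and characterizing catalogs of long
    noncoding RNAs (lncRNAs) from assembled transcript models. Merges
    reference gene models under splicing-pattern redundancy rules, scores
    assembled transcripts with a composite Transcript Confidence Score
    against randomly shuffled decoy transcripts, picks a ROC-optimal
    retention cutoff, applies noncoding filters and genomic-context
    classification, computes per-transcript expression metrics (quantile
    normalization, Jensen-Shannon tissue specificity, splicing efficiency,
    conservation averaging, inter-individual variability), and runs
    mixed-model trait association, tumor/normal differential expression,
    clinical-outcome and Cox survival analyses. Ships seeded synthetic-data
    generators so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    nlme,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
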