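Package: codonLRT
Title: Codon-Level Likelihood Ratio Tests for Deleterious Variant
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts deleterious amino acid variants from selective
    constraint at individual codons. Fits a Muse-Gaut codon substitution
    model (MG94 x F1x4) per gene to estimate branch lengths in synonymous
    substitution (dS) units, then tests each codon of interest with a
    likelihood ratio test of dN = dS against dN = omega dS, optionally
    masking the query sequence to avoid reference bias. Site p-values,
    constraint estimates and alignment allele counts feed published
    logistic models that return a single probability of being deleterious.
    Includes ROC/AUC benchmarking with stratified bootstrap confidence
    intervals, frequency-class enrichment, approach-disagreement
    clustering, a per-codon combination rule for nucleotide-level
    conservation scores, and a forward codon-alignment simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    Biostrings,
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
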