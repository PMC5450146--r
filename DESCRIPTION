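Package: ampligold
Title: Synthetic 16S Amplicon Gold Standards and Pipeline Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic 16S rRNA amplicon datasets in which the true
    source organism of every read is known, and scores the output of amplicon
    analysis pipelines against that gold standard. Communities are designed
    from per-genus abundance specifications, amplicons are produced by
    in-silico PCR with degenerate primers, and an optional error model
    corrupts reads. Evaluators cover OTU generation (pair-counting
    sensitivity and specificity), taxonomic classification (six outcome
    categories with ranks-off distances), and alpha/beta diversity (Hill
    number profiles, Shannon index, weighted UniFrac, DPCoA, and Spearman
    monotonicity of estimates against truth).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phyloseq,
    vegan,
    withr
Config/testthat/edition: 3
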