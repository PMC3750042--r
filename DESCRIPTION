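Package: concordis
Title: Cross-Disease Transcriptome Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis of differential expression across multiple
    expression datasets and across two related diseases.  Provides
    SAM-style permutation-based differential-expression calling per
    dataset, binomial tests of cross-dataset direction consistency,
    direction-consistent integration of per-dataset gene lists,
    disease-versus-disease dysregulation-direction classification,
    ontology (GO-style) enrichment with ancestor/offspring redundancy
    pruning, per-function direction-concordance testing, a hypergeometric
    transcription-factor linkage model connecting stimulus-response
    functions to disease-related functions, and binomial tests of
    mutation and copy-number alteration burden against fixed background
    rates.  A synthetic-data generator reproduces the statistical
    structure the analysis assumes, so the full pipeline can be exercised
    end to end without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
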