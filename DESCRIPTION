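Package: seqanchors
Title: Anchor Rule Extraction and Auditing for Black-Box Sequence
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts global, human-readable if-then binding rules from any
    black-box amino-acid sequence classifier (for example a T cell receptor
    epitope-binding predictor) and audits them quantitatively.  Samples are
    split by the model's binding/non-binding predictions, each split is
    clustered under a sequence distance (Levenshtein by default) and the
    medoid of every cluster is explained by a high-precision anchor rule
    found with multi-armed-bandit (KL-LUCB) beam search over
    position/amino-acid predicates.  Rule sets are evaluated for
    faithfulness, overlap and completeness at cluster, cluster-split and
    split level, mapped onto framework and complementarity-determining
    regions, and rendered as sequence-motif style figures.  A synthetic
    repertoire generator with a planted-rule oracle model makes the whole
    pipeline testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    FNN,
    grDevices,
    graphics,
    jsonlite,
    Rtsne,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
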