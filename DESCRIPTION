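Package: cypscout
Title: Substrate Prediction Toolkit for Bacterial Cytochrome P450s
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for predicting substrates of bacterial
    cytochrome P450 monooxygenases (BacCYPs). Combines compound-similarity
    clustering (Tanimoto fingerprints with Butina sphere-exclusion),
    phylogenetic grouping by cophenetic-distance clustering, conserved-motif
    scanning of P450 domain sequences, genomic-neighborhood substrate
    inference, docking-score Z-score statistics with binder calling,
    structural model evaluation by optimal superposition, and an
    evidence-tiered integrator. Ships deterministic synthetic-data
    generators so every stage and the end-to-end benchmark run without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    bio3d,
    methods,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
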