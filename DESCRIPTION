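Package: linksig
Title: Differential Cell Signaling Testing for Single-Cell Cell-Cell
    Communication Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers intercellular (ligand-receptor) and intracellular
    (receptor-transcription factor) signaling linkages per subject from
    annotated single-cell RNA-seq expression, collates them across subjects
    into a linkage summary, and tests for condition-dependent signaling with
    an exact-test framework (the differential cell signaling test) under
    Benjamini-Hochberg false discovery control. Also provides bootstrap
    pseudo-replicates for pooled designs, AUCell-style transcription factor
    activity scoring with optional chromatin-accessibility-based regulon
    pruning, ligand-receptor database parsing and merging (including
    heteromeric complexes), and a two-condition simulation benchmark of test
    sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
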