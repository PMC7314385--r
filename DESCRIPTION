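Package: docrex
Title: Document-Level Biomedical Relation Extraction with a Self-Attention Encoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting document-level biomedical relations such as
    chemical-induced disease (CID) from annotated abstracts.  Reads and writes
    the PubTator corpus format, constructs one relation instance per candidate
    entity pair from the contiguous block of sentences covering its mentions,
    applies entity replacement or boundary-marker pretreatment, and classifies
    instances with a multi-head self-attention (transformer) encoder
    implemented from scratch with exact backpropagation, trainable on a CPU at
    small configurations and able to ingest externally converted pretrained
    weights.  Includes per-class and micro precision/recall/F1 evaluation,
    multi-run averaging, length-binned analysis, attention-weight export, and
    a synthetic corpus generator with planted, learnable relation cues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
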