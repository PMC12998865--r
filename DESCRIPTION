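Package: embedfuse
Title: Embedding Fusion and Model-Subset Selection for Biomedical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combines frozen embeddings from multiple image-encoder
    "providers" into a single task-specific representation. Supports
    exhaustive subset search over registered models scored with a
    fixed-configuration gradient-boosted-tree probe, parameter-free
    concatenation fusion and a trainable multi-head self-attention
    fusion variant, an on-disk embedding cache, AUC-ROC and
    balanced-error evaluation, and reference-normalised corruption
    robustness scores. Ships a synthetic multi-model embedding
    generator with planted class signal so the full pipeline is
    testable without external data or pre-trained weights.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
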