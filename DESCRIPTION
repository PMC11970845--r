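Package: picaso
Title: Permutation-Invariant Cascaded Attentional Set Operators for
    Histopathology Instance Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates variable-size sets of per-instance embeddings (for
    example glomerular image crops from one biopsy) into fixed-size case
    representations with PICASO, a cascade of multihead cross-attention
    Transformer blocks in which learnable histopathologic vectors (HiVe) act
    as queries and are updated step by step against the instance embeddings.
    Ships the baseline permutation-invariant set operators (DeepSet variants,
    Set Transformer), per-instance anomaly and per-set classification heads,
    a small trainable convolutional encoder, Monte Carlo set construction
    with group-aware cross-validation folds, synthetic mixture and planted
    lesion-motif image generators, and a training and evaluation harness
    with rank-based AUROC/AUPR, bootstrap confidence intervals and paired
    significance tests. Forward and backward passes are implemented in plain
    matrix algebra and trained with Adam.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
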