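Package: gemgrn
Title: Gene Regulatory Network Inference from Single-Cell Expression via
    Transformer Classification of Gene-Pair Expression Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Supervised inference of gene regulatory networks from
    single-cell RNA-seq expression matrices. Each (regulator, candidate
    target) gene pair is encoded as a gene expression motif: the two
    expression vectors are cut into aligned contiguous windows of cells
    and concatenated position-wise into a short sequence of sub-vectors.
    A single-layer transformer encoder (sinusoidal positional encoding,
    two-head scaled dot-product self-attention, feed-forward network with
    residual connections and layer normalization) followed by average
    pooling and a two-layer sigmoid classification head scores the pair
    as interacting or not, or resolves the direction of regulation. The
    package provides the encoder and network weights trained by
    backpropagation with Adam, stratified 3:1:1 splits for network
    reconstruction, transcription-factor-disjoint 3-fold cross-validation
    for regulator-held-out prediction, ROC/PR evaluation, a sub-vector
    importance probe for interpretation, and a synthetic single-cell data
    generator with planted regulatory structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
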