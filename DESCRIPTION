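Package: mosae
Title: Multi-Omics Supervised Autoencoders for Clinical Endpoint Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements MOSAE, a multi-omics fusion model built from per-omics
    supervised autoencoders. Each omics layer (e.g. DNA methylation, miRNA-Seq,
    RNA-Seq, RPPA) gets an autoencoder whose first hidden layer compresses
    high-dimensional omics or expands low-dimensional ones before encoding to a
    common latent width; latent codes are fused by element-wise averaging and the
    model is trained with a joint reconstruction plus prediction loss. Includes
    leakage-safe feature filtering and standardization, a stratified k-fold
    cross-validation harness reporting ROC AUC, an ablation-variant factory
    (multi-omics, fusion mode, supervision, dimension-specific structure,
    reconstruction backbone), a synthetic multi-omics generator with a
    Monte-Carlo Bayes-AUC ceiling, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
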