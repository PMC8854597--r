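Package: srimpute
Title: Single-Cell Dropout Imputation via Hypergeometric Testing and
    Subspace Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputes dropout-induced zeros in single-cell RNA-seq
    expression matrices. Every zero entry is tested with an
    overlap-corrected hypergeometric test that contrasts the zero rate of
    its gene with the zero rate of its cell; significantly
    over-represented zeros are flagged as dropouts while
    under-represented zeros are kept as trusted biological zeros. Genes
    whose zeros are all trustworthy form a training set that is split
    into gene subspaces by perturbation clustering (stability of
    connectivity matrices under Gaussian noise, with the cluster number
    chosen by the AUC of the empirical CDF of the connectivity
    difference). Each imputable gene is assigned to its nearest subspace
    and its flagged zeros are predicted by ordinary least squares on its
    most correlated training genes. Ships a block-normal simulation suite
    with controlled dropout masking and the standard evaluation metrics
    (ARI, Jaccard, purity, MAE, Pearson and distance correlation,
    intra-dispersion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
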