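Package: scmixae
Title: Generalized Variational and MMD Autoencoders for Single-Cell Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A unified autoencoder toolkit for dimensionality reduction of
    single-cell RNA-seq count matrices. Six architectures (VAE, MMDAE,
    MMDVAE, GMVAE, GMMMD, GMMMDVAE) are instances of one generalized
    evidence-lower-bound objective parameterized by (alpha, lambda, K),
    combining count reconstruction likelihoods (Poisson, negative binomial,
    their zero-inflated and library-size-constrained variants, and MSE),
    a maximum-mean-discrepancy term, and a Kullback-Leibler term against a
    learnable Gaussian-mixture latent prior. Includes a batch-aware
    integration pipeline (per-batch highly-variable-gene selection, latent
    embedding, kNN graph, Leiden clustering at a target cluster count,
    Mann-Whitney marker ranking), a clustering-agreement metric suite
    (ARI, AMI, FMI, homogeneity, completeness, V-measure), and a
    negative-binomial multi-batch simulator with ground-truth cell types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
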