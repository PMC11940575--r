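Package: beakmorph
Title: Generative Morphometrics of Bill-Like 3D Shapes with a Signed
    Distance Function Autodecoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for learning a latent shape space of
    bill-like 3D meshes with a signed-distance-function (SDF) autodecoder
    and extracting morphological, ecological and phylogenetic meaning from
    the learned latent codes.  Includes a parametric generator of
    watertight beak-like meshes with known shape parameters, class
    structure and Brownian-motion trait evolution on simulated
    phylogenies; a landmark-based mesh preprocessing pipeline (cleaning,
    rigid reorientation, sphere trimming and capping, unit-sphere
    normalization); Monte-Carlo SDF sampling; a clamped-L1 MAP
    autodecoder trained jointly over decoder weights and per-shape latent
    codes; isosurface extraction from predicted SDF grids; a second-stage
    conditional variational autoencoder with trainable reconstruction
    variance; interpretable latent-direction discovery by no-intercept
    regression; class-weighted trophic-niche classification with
    Monte-Carlo cross-validation; and phylogenetic-signal statistics
    (Blomberg's K, its multivariate generalization, phylogenetic PCA and
    phylogenetically aligned components analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    ranger,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
Suggests:
    cluster,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
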