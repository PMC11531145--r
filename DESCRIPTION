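Package: rootfungi
Title: Assembly of Root-Associated Fungal Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how host-plant filtering, background soil
    community structure, spatial autocorrelation and fungus-fungus
    associations jointly assemble root-associated fungal communities
    sampled as root tips and bulk soil across a forest plot. Provides
    coverage-based rarefaction and community-matrix utilities, a
    latent-factor multivariate probit joint species distribution model
    with a 16-model factor lattice and per-OTU log-likelihood factor
    attribution, Bluethgen d' host-specificity statistics with
    position-constrained permutation nulls, root-versus-soil habitat
    preference models, Mantel correlograms, and sparse-plus-low-rank
    inverse-covariance network inference on centred log-ratio
    transformed counts. A seeded synthetic-data generator emulating the
    root-tip/soil sampling design supplies ground-truth datasets for
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    vegan,
    igraph,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
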