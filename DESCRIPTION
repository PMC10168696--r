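Package: driftrescue
Title: Transcriptional Drift and Environmental Rescue Analysis for
    Cultured Endothelial Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how far cultured endothelial cells drift from their
    in-vivo (umbilical cord) transcriptional state and how much of that drift
    is rescued by laminar shear stress or heterotypic co-culture with smooth
    muscle cells. Provides a seeded synthetic-data generator with planted
    ground truth, preprocessing (log10 transform, gene-wise scaling,
    empirical-Bayes batch adjustment, PCA), a per-gene drift screen (Welch's
    t, biweight midcorrelation, Bonferroni and Benjamini-Hochberg control),
    sign-concordance rescue classification with transcriptome partition
    fractions, signed-hybrid weighted co-expression modules (biweight
    midcorrelation, topological overlap, dynamic tree cut, module
    eigengenes), RNA-protein concordance, expression-bin-matched gene-set
    scores, and a time-profile similarity/divergence search engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
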