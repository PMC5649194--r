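Package: wallmech
Title: Nanomechanics and Multi-Omic Integration of the Yeast Cell Wall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell atomic force microscopy (AFM)
    nanomechanics of the Saccharomyces cerevisiae cell wall and its
    integration with bulk transcriptomics. Fits force-indentation curves
    with the conical Hertz (Sneddon) contact model to map the Young's
    modulus of living cells, analyses lectin-tip retract curves with the
    freely-jointed-chain and worm-like-chain polymer models to estimate
    mannan contour lengths and adhesion statistics, normalises probe-level
    microarray intensities and tests differential expression with an
    empirical-Bayes moderated t-test, and relates gene expression to
    biochemical and biophysical phenotypes through sparse partial least
    squares with correlation-circle and clustered-image-map summaries.
    Seeded synthetic-data generators emulate every input with planted
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
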