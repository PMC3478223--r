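Package: chromatex
Title: Nuclear Chromatin Texture and Morphometry for Leukemia Cytology
Version: 0.1.0
Authors@R:
    person("chromatex", "developers", email = "chromatex@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of nuclear chromatin texture in
    May-Grunwald-Giemsa stained leukemic cells. Computes geometric
    morphometry (nuclear area, form factor, gray-level statistics),
    gray-level co-occurrence matrix features (entropy, contrast, local
    homogeneity, cluster prominence), and the Minkowski-Bouligand fractal
    dimension of the pseudo-3D chromatin surface via blanket dilation with
    a goodness-of-fit statistic. Includes a seeded synthetic nucleus and
    cohort generator, cohort statistics (Mann-Whitney, Spearman, exact
    binomial confidence intervals, univariate and stratified Cox
    regression), and a reproducible command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
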