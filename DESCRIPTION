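Package: chemphylo
Title: Phylogenetic Comparative Analysis of Pollen Sterol Chemodiversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of pollen phytosterol profiles
    across plant phylogenies: chemodiversity indices on compositional sterol
    tables (Shannon equitability, commonness, relative abundance,
    biosynthetic group sums), factor analysis with varimax rotation,
    Bray-Curtis dissimilarities with ANOSIM, multiple regression on distance
    matrices (MRM) and nonmetric multidimensional scaling, phylogenetic
    signal statistics (Pagel's lambda, Blomberg's K) implemented from first
    principles, phylogenetically independent contrasts and through-origin
    contrast regression, simulation-based phylogenetic ANOVA with Holm
    post-hoc tests, occurrence-record cleaning, environmental-space PCA and
    3D alpha-shape niche breadth, plus a synthetic-data generator that
    reproduces the statistical structure of such studies so every stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    vegan,
    phytools,
    picante
Config/testthat/edition: 3
RoxygenNote: 7.3.3
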