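Package: assemblage
Title: Phylogenetic Null Models for Microbial Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the ecological processes structuring microbial
    communities from phylogenetic and compositional turnover. Implements
    abundance-weighted beta mean nearest taxon distance (betaMNTD) and beta
    mean pairwise distance (betaMPD), their tip-shuffling standardized
    effect sizes (betaNTI, betaNRI), a Bray-Curtis Raup-Crick null model
    (RC-bray) preserving taxon occurrence frequencies and sample richness,
    and the five-way classification of pairwise turnover into homogeneous
    selection, variable selection, dispersal limitation with drift,
    homogenizing dispersal (or weak homogeneous selection in closed
    systems), and undominated processes. Supporting procedures cover
    Faith's phylogenetic diversity and its standardized effect size,
    abundance-weighted niche optima, phylogenetic signal via Pagel's
    lambda (maximum likelihood with likelihood-ratio test) and Mantel
    correlograms over patristic distance classes, Mantel tests, Monte
    Carlo mean-deviation tests, multivariate dispersion comparisons, and
    segmented regression with bootstrap bands. A synthetic-data module
    simulates pure-birth trees, lambda-transformed Brownian niche traits,
    and communities assembled under known regimes so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    withr,
    optparse
Config/testthat/edition: 3
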