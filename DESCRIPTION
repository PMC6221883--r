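Package: divherit
Title: Heritability of Similarity-Sensitive Symbiont Community Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for treating a host-associated microbial community as a
    continuous quantitative host trait and estimating its narrow-sense
    heritability across a pedigree. Implements the Leinster-Cobbold
    similarity-sensitive diversity family over OTU count tables and
    representative sequences, pedigree relatedness matrices (a discrete
    sib-class convention and the recursive tabular additive relationship
    matrix), a Gibbs-sampled Bayesian animal model with optional maternal
    effects and DIC model comparison, median-of-ratios count normalization
    with negative-binomial Wald differential abundance, distance-based
    community statistics (Bray-Curtis, PCoA, PERMANOVA, multivariate
    dispersion), prevalence networks, spatial linear models, and a synthetic
    data generator emulating mixed-mode symbiont transmission in a brooding
    coral mating design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    coda,
    jsonlite,
    optparse
Config/testthat/edition: 3
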