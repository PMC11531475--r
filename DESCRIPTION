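Package: betaregions
Title: Phylogenetic Bioregionalization and Boundary Dynamics Across
    Climate Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Delineates floristic realms and regions from gridded
    presence/absence communities and a phylogeny using pairwise Simpson
    and Sorensen (phylogenetic) beta diversity, UPGMA-family hierarchical
    clustering with cophenetic linkage selection, and explained-
    dissimilarity cluster-number selection.  Extracts biogeographic
    boundaries from label maps (adjacency and buffer-sum procedures),
    quantifies homogenization and differentiation between scenarios
    (Cohen's d with bootstrap intervals, entropy-based v-measure,
    Dutilleul's spatially corrected correlation), and models boundary
    determinants with an autologistic regression summarised through
    Fisher's z effect sizes.  Includes a synthetic-data generator
    (pure-birth phylogenies, autocorrelated landscapes, clade-structured
    species ranges with planted regions, and contract/expand/shift
    future scenarios) so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    vegan,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
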