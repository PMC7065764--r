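Package: fragdep
Type: Package
Title: Forest Dependency of Small-Mammal Communities in Fragmented Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing small-mammal (and other vertebrate) assemblages
    sampled across fragmented forest landscapes. Converts raw capture tables to
    effort-standardized abundances, estimates sample coverage, computes a
    species-level forest-dependency index with its uncertainty and a
    threshold-based classification into forest-dependent, matrix-tolerant and
    open-habitat species, and derives abundance-weighted community-averaged
    forest dependency. Community structure is summarised by richness, total
    abundance, Bray-Curtis dissimilarity and principal coordinates analysis.
    Gaussian GLM machinery supports collinearity screening, all-subsets AICc
    model selection, confidence-set model averaging with relative importance,
    hierarchical partitioning of explained variance, buffer-radius selection
    and declared outlier-exclusion refits. A landscape-projection module
    delineates forest patches from binary grids, computes patch areas and a
    proximity index, projects community forest dependency from patch size, and
    summarises deforestation chronosequences. Seeded generators produce
    synthetic landscapes, species pools, capture data and deforestation series
    with the statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vegan,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
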