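Package: ensdesign
Title: Ensemble-Based Ranking of Enzyme Point Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ensemble-based computational filter for ranking enzyme point
    mutations. Generates conformer ensembles under structure-derived
    distance bounds with catalytic-triad anchoring, models point mutations
    with a minimal rotamer search, evaluates reactant and
    tetrahedral-intermediate complex states with a swappable molecular
    mechanics energy model, and ranks variants by the wild-type-normalized
    median two-state energy difference under conservation and
    substrate-proximity filters. Includes catalytic hydrogen-bond occupancy
    statistics, RMSF and pairwise RMSD analytics, rank-stability analysis
    across energy parameterizations and frame subsets, and synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
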