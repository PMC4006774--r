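Package: fconn
Title: Graph-Theoretic Analysis of Fetal Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for resting-state functional connectivity
    analysis of the fetal brain: framewise-displacement motion scrubbing
    with subject-level exclusion, aCompCor-style nuisance regression,
    pairwise Pearson/Fisher-z connectivity matrices, signed-weight
    modularity maximization (Louvain with consensus partitioning and
    fine-tuning), nodal hub metrics (participation coefficients and
    within/between-module strength z-scores), distance-strength profiles,
    and gestational-age effect inference with robust regression and
    false-discovery-rate control. Includes a synthetic cohort generator
    that plants known developmental effects so every stage is testable
    end to end, and a simplified spatially constrained normalized-cut
    parcellation of voxel timeseries into contiguous regions of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
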