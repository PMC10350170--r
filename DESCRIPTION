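Package: imcNiche
Title: Phenotyping, Spatial Statistics and Outcome Modeling for Imaging
    Mass Cytometry of Tissue Allografts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for segmented imaging mass cytometry (IMC)
    data from clinical tissue specimens. Provides arcsinh transformation
    and channel standardization of marker intensities, declarative
    hierarchical gating into metaclusters and subclusters, per-patient
    composition features, per-ROI k-nearest-neighbour spatial graphs with
    permutation tests for pairwise cell-type attraction and avoidance,
    cellular-neighbourhood (CN) motif discovery by clustering neighbour
    composition profiles, a simplified minimum-spanning-tree trajectory
    orientation and pseudotime, normality-gated group-difference testing
    with Holm correction, and a bootstrap-stabilized logistic LASSO
    recipe with repeated train/validation evaluation. A synthetic tissue
    cohort generator with planted spatial structure supports testing of
    every stage without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    glmnet,
    igraph,
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'CellTable.R'
    'predict.R'
    'stats.R'
    'spatial.R'
    'phenotype.R'
    'io.R'
    'synth.R'
    'trajectory.R'
    'utils.R'
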