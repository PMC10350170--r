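# imcNiche

Phenotyping, spatial statistics and outcome modeling for imaging mass
cytometry (IMC) of tissue allografts.

## The problem

Clinical biopsy specimens — for example liver transplant biopsies graded
for T-cell mediated rejection — yield small amounts of tissue, but
multiplexed IMC turns a 1 mm² region of interest (ROI) into thousands of
segmented cells with ~20 marker intensities each and spatial coordinates.
Turning those cell tables into biology needs a chain of well-defined
steps: variance stabilization and standardization of marker signal,
reproducible assignment of hierarchical cell phenotypes, per-patient
composition features, tests for which cell types attract or avoid one
another in space, discovery of recurring multicellular neighbourhood
motifs, orientation of differentiation trajectories, and predictive
modeling of the clinical outcome from cell composition. imcNiche
implements that chain for analysts working with segmented IMC (or any
single-cell spatial proteomics) data, as a Bioconductor-style R package
built on `SingleCellExperiment`.

## The methods at its core

* **Preprocessing** — intensities are arcsinh-transformed,
  `x ↦ asinh(x/c)` with cofactor `c = 5`, then each channel is
  standardized to mean 0, SD 1.
* **Gating** — a declarative, ordered rule hierarchy (first match wins,
  fallback by exclusion) assigns 10 metaclusters and refines five immune
  lineages into 30 subclusters; with the parenchymal Ki67/HLADR splits
  the default ruleset yields 41 terminal labels (32 immune, 9
  non-immune).
* **Spatial interactions** — on a directed k-nearest-neighbour graph per
  ROI (k = 10), the mean count of type-B neighbours per type-A cell is
  compared against within-ROI label permutations (default 1000, α =
  0.01); pairs are called *attraction* or *avoidance* with the add-one
  p-value estimator `(1 + #{null ≥ obs}) / (1 + n_perm)`.
* **Cellular neighbourhoods (CN)** — each cell's neighbour-composition
  profile is clustered by seeded k-means (k-means++, 10 restarts) into 9
  CNs; CN proportions per patient are compared across groups.
* **Trajectories** — per metacluster, a 2-D embedding is coarsely
  clustered (k-means, k = 2; k = 5 for CD8 T-cells); the cluster richest
  in no-rejection cells roots a minimum-spanning-tree lineage structure,
  and pseudotime is arc-length projection onto the lineage paths.
* **Statistics** — Shapiro-Wilk-gated choice between ANOVA/t-tests and
  Kruskal-Wallis/Wilcoxon, with Holm correction over the pairwise family
  per feature.
* **Prediction** — logistic LASSO (binomial deviance, λ by stratified
  5-fold CV), bootstrap stability selection (5000 resamples, features
  kept at ≥ 50% frequency), evaluated over 1000 stratified 75/25 splits
  with sensitivity/specificity/accuracy at cutoff 0.5, Mann-Whitney AUC,
  a median-prediction ROC, and Spearman association of median
  predictions with outcome.
* **Synthetic cohorts** — a generator plants known composition shifts,
  Neyman-Scott co-aggregation pairs and motif blocks, so every stage is
  testable against ground truth.

See `vignettes/imcNiche-methods.Rmd` for the models, assumptions, and
design decisions.

## Worked example

```r
library(imcNiche)

## a synthetic cohort: 6 patients per clinical group, 500 cells per ROI
cfg <- cohortConfig(nPatientsPerGroup = c(NR = 6L, TCMR = 6L, CR = 6L),
                    roisPerPatient = 1, cellsPerRoi = 500, seed = 11L)
cohort <- generateCohort(cfg)
cohort$table
#> CellTable: 8758 cells x 22 markers
#>   state: raw
#>   ROIs: 18  patients: 18  groups: CR/NR/TCMR

## preprocess and gate
rules <- defaultGatingRules()
std <- standardizeChannels(transformIntensities(cohort$table, cofactor = 5))
asg <- assignPhenotypes(std, rules)
mean(finalLabels(asg) == cohort$truth@cells$true_label)
#> [1] 0.9930349

## per-patient composition
props <- computeProportions(asg, std, level = "metacluster")
head(subset(props, label == "CD8 T-cell"), 4)
#>    patient group      label proportion denominator
#> 3   NR_p01    NR CD8 T-cell 0.09213483   all_cells
#> 13  NR_p02    NR CD8 T-cell 0.10112360   all_cells
#> 23  NR_p03    NR CD8 T-cell 0.09484536   all_cells
#> 33  NR_p04    NR CD8 T-cell 0.10183299   all_cells

## the full pipeline (reduced iteration counts for a quick run)
res <- runPipeline(cohort$table,
                   pipelineConfig(nPerm = 100, nBoot = 50, nIter = 50,
                                  seed = 42L),
                   outDir = "imcNiche-run")
res$cn
#> CNModel: 9 cellular neighbourhoods over 8758 cells
res$model
#> ModelReport: 50 evaluation iterations
#>   sensitivity  0.990 +/- 0.071
#>   specificity  1.000 +/- 0.000
#>   accuracy     0.995 +/- 0.035
#>   auc          1.000 +/- 0.000
#>   median-prediction AUC 1.000, Spearman rho 0.869 (p 0.00216)
```

The gating recovery (99.3% of cells receive their generating label) shows
the rule hierarchy separating the well-separated synthetic templates; the
CD8 T-cell proportions around 0.09–0.10 per NR patient reflect the
configured composition plus the planted CD8-enriched motif block; and the
near-perfect model metrics are expected here because the synthetic TCMR
group carries strong, planted composition shifts. The run directory
contains one tidy CSV per stage (assignments, proportions, interaction
calls, CN assignments and proportions, trajectories, selection
frequencies, model metrics, median predictions) plus a parameter log and
a deterministic manifest — rerunning with the same seed reproduces every
file bit for bit.

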