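---
title: "Models and methods behind imcNiche"
author: "imcNiche authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind imcNiche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imcNiche)
```

# Scope

imcNiche analyses segmented imaging mass cytometry (IMC) data from clinical
tissue specimens — one row per cell with ROI, patient and clinical-group
identifiers, centroid coordinates in micrometres, and per-marker mean
intensities. It covers five analysis layers: semi-supervised phenotyping,
per-patient composition statistics, spatial interaction and
cellular-neighbourhood (CN) analysis, trajectory orientation with
pseudotime, and bootstrap-stabilized predictive modeling of clinical
outcome. A synthetic cohort generator with planted spatial structure makes
every layer testable without clinical data.

Upstream image processing (spillover correction, denoising, deep-learning
segmentation) is out of scope: the package starts at the segmented cell
table.

# Expression preprocessing

Raw IMC intensities are right-skewed and strictly nonnegative. They are
variance-stabilized with the standard cytometry transform

$$x \mapsto \operatorname{asinh}(x / c), \qquad c = 5,$$

and then each channel is standardized to mean 0 and sample standard
deviation 1 across all cells, so that a single positivity threshold is
meaningful across markers with very different signal intensities. Constant
channels (dropped markers, degenerate synthetic inputs) standardize to
all-zeros with a warning instead of aborting the run. The processing state
(`raw`, `transformed`, `standardized`) is carried on the `CellTable`
object and checked by every stage, so stages cannot be applied out of
order or twice.

# Hierarchical gating

Phenotypes are assigned by a declarative `GatingRuleSet`: an ordered list
of rules, each a conjunction of marker thresholds on the standardized
scale. Metacluster rules are evaluated first-match-wins over all cells;
cells matching no rule receive the fallback label (hepatocyte in the
default ruleset — the parenchymal cell classified by exclusion of all
other lineages). Subcluster rules are evaluated first-match-wins within
their parent metacluster only; cells of a subclustered parent matching no
rule keep a parent-level generic label such as `CD3+CD8+ T-cell`.

The default ruleset encodes a 22-marker liver-allograft panel and
produces:

* 10 metaclusters — hepatocyte, cholangiocyte, endothelial plus 7 immune
  lineages;
* 30 immune subclusters on the five subclustered immune metaclusters
  (9 CD4 T-cell, 5 CD8 T-cell, 9 macrophage, 4 monocyte, 3 B cell);
* Ki67/HLADR phenotype splits of the three parenchymal metaclusters;
* 41 terminal labels in total (32 immune + 9 non-immune).

The macrophage hierarchy realises a two-step scheme — first an M1/M2
split on CD163, then the remaining markers within each branch — through
branch-conditioned predicates (`CD163<0.5;...` vs `CD163>=0.5;...`),
which is equivalent to splitting first and avoids special-case code.

Two conventions deserve a note. First, the default positivity threshold
is standardized expression ≥ 0.5; real panels calibrate thresholds per
marker, and every rule can carry its own threshold in the rule file. The
0.5 default keeps the default pipeline runnable and is well inside the
separation that bimodally expressed markers show after standardization.
Second, `nSubclusters()` counts subcluster targets under immune parents
(30); the parenchymal splits are accounted among the 9 non-immune
terminal labels. This mirrors the accounting convention of the study
design the defaults emulate.

Composition features are computed per patient, pooling each patient's
cells across all of that patient's ROIs (the simplest reading of
per-patient proportions; a per-ROI-then-average variant would weight
small ROIs up). Metacluster and final-label proportions use the patient's
total cell count as denominator; subcluster proportions can instead use
the parent metacluster count (e.g. percent of the CD8 T-cell population).
A patient with no cells of the parent gets a missing value, not a zero.

# Spatial statistics

All spatial statistics operate on a per-ROI directed k-nearest-neighbour
graph (k = 10 by default) over cell centroids, with neighbours sorted by
ascending Euclidean distance and ties broken by cell index, making graph
construction fully deterministic.

**Pairwise interactions.** For an ordered label pair (from, to) within
one clinical group, the observed statistic is the across-ROI mean of the
mean number of to-labelled out-neighbours per from-labelled cell. The
null distribution shuffles labels independently within each ROI
(stratified permutation — cell positions and the label multiset per ROI
are preserved) and recomputes the across-ROI statistic; a single
group-level test on the pooled statistic is performed rather than
per-ROI tests that are later combined. p-values use the add-one
estimator $(1 + \#\{null \ge obs\}) / (1 + n_{perm})$ so they are never
exactly zero; attraction is called when the upper-tail p-value is at most
$\alpha$ (default 0.01, 1000 permutations), avoidance symmetrically.
Because the two p-values sum to more than 1, both calls can never fire
at once. No multiplicity correction is applied across pairs by default
($\alpha$ is per test); the statistics engine's Holm adjustment can be
applied downstream when desired. For ROIs of at most a few cells the
test also offers exhaustive enumeration over all distinct labelings,
which the test suite uses as an oracle for the sampled estimator.

**Cellular neighbourhoods.** Each cell's neighbourhood profile is the
fraction of its out-neighbours bearing each label; fractions rather than
counts keep boundary cells with out-degree below k comparable. Profiles
are clustered by k-means into 9 CNs by default. Plain `stats::kmeans`
does the Lloyd iterations; seeding is k-means++ with the best of 10
restarts by within-cluster sum of squares under a fixed seed, which makes
CN discovery reproducible and stabilises recovery of well-separated
motifs. If there are fewer distinct profiles than requested CNs, each
distinct profile forms its own cluster and the remaining centroids are
flagged empty rather than erroring.

**Distance profiles.** For a reference label (endothelial cells in the
default pipeline, reflecting the vascular focus of rejection grading),
each non-reference cell gets the Euclidean distance to the nearest
reference cell in its ROI; ROIs without reference cells contribute
missing values. Per-label medians are compared across groups with the
statistics engine. The profile depends on coordinates only through
pairwise distances, hence is invariant to translation and rotation.

# Trajectory orientation and pseudotime

Per metacluster, cells are embedded in two dimensions. The embedding is
deliberately plumbing: a deterministic principal-component projection
(signs fixed so the largest-absolute loading of each component is
positive) stands in for any manifold embedding, trading visual
manifold fidelity for exact reproducibility without extra dependencies.

Orientation follows a coarse-clustering rule: k-means on the embedding
with k = 2 (k = 5 for the CD8 T-cell compartment, whose differentiation
structure is richer), and the coarse cluster with the highest fraction of
cells from NR (no-rejection) samples becomes the initial cluster — the
assumption being that the non-rejecting graft holds the least
differentiated immune state. Ties break to the lowest cluster id; with no
NR cells orientation is undefined and the function stops.

Lineage inference is a documented simplification of simultaneous
principal-curve fitting: the minimum spanning tree over coarse-cluster
centroids is rooted at the initial cluster, lineages are its root-to-leaf
paths, and each cell's pseudotime is the arc-length position of its
orthogonal projection onto the piecewise-linear path of its nearest
lineage (root at 0). This retains the scientific content — branching
order and data-driven orientation — with a fraction of the machinery; it
does not reproduce smoothed principal curves numerically, and makes no
claim to. With a single coarse cluster the pseudotime degenerates to the
position along the first principal axis, shifted to start at zero.
Per-group kernel densities of pseudotime summarise where each clinical
group sits along the trajectory; groups with fewer than 5 cells are
flagged instead of smoothed.

# Group-difference testing

Test selection is gated on normality: every group must pass Shapiro-Wilk
at p > 0.05 for the parametric family (one-way ANOVA overall, two-sample
t pairwise); otherwise the rank family is used (Kruskal-Wallis overall,
Wilcoxon rank-sum pairwise). Groups too small for Shapiro-Wilk (n < 3)
default to the rank family. Rank tests use exact enumeration for small
tie-free samples and mid-ranks with a normal approximation under ties
(the stats-package convention). Holm's step-down correction is applied to
the pairwise family within each feature — the 3 group pairs of a
3-group comparison — matching per-panel correction; adjusting across
features instead is a caller-side choice, as the family definition is not
dictated by the engine. Significance is declared at 0.05 throughout.
Patients are the observational unit; repeated ROIs per patient are pooled
at the proportion stage, not modelled as random effects.

# Predictive modeling

The outcome model is an L1-penalized (LASSO) logistic regression on
per-patient composition features for a two-group contrast. Although the
loss is sometimes written in squared-error form in descriptions of this
recipe, the implementation minimizes penalized binomial deviance — the
loss that matches the stated logistic model class and the binary outcome.
The penalty is chosen by stratified 5-fold cross-validation over 100
log-spaced values from the data-derived $\lambda_{max}$ down to
$10^{-4}\lambda_{max}$, minimizing mean cross-validated deviance;
features are standardized inside each fit and the intercept is
unpenalized (glmnet defaults).

Feature selection is stabilised by bootstrapping: patients are resampled
with replacement (single-class resamples are redrawn so the iteration
count stays exact), the penalty is re-selected by internal CV, the model
refitted, and non-zero coefficients recorded — 5000 iterations by
default. Features selected in at least 50% of iterations form the final
model. Evaluation uses 1000 random stratified 75/25 train/validation
splits: per split the model is refitted on the training patients
restricted to the selected features and validation probabilities are
recorded; sensitivity, specificity and accuracy are computed at the 0.5
probability cutoff (the simplest documented choice) and AUC by the
Mann-Whitney identity with ties counting one half. Final coefficients are
averaged over all iterations; each patient's median validation
probability feeds the median-prediction ROC and a Spearman correlation
with outcome, accompanied by a two-sided Wilcoxon rank-sum p-value
comparing median predictions between classes.

One numerical guard: cross-validated penalty selection needs at least 3
members per class (otherwise some fold complement loses a class), and
bootstrap resamples of small cohorts routinely violate this. Such fits
fall back to the unpenalized logistic fit, so tiny-cohort runs complete
with documented behaviour instead of failing deep inside an iteration.

# The synthetic cohort generator

The generator emulates the structure the pipeline assumes, not the
microscopy. Its defaults mirror the study design the package targets:
24/41/14 patients in the NR/TCMR/CR groups, 96 ROIs in total (about 1.2
per patient, with the extra ROIs assigned deterministically to the first
patients of each group), 1 mm² ROIs with Poisson-distributed cell counts
of mean 4,800, and the 41-label composition with hepatocytes around 62%
of all cells, macrophages around 10%, and group-dependent shifts (larger
CD8 T-cell, PD1+ T-cell, Treg and HLADR+ M2 macrophage fractions in
TCMR; intermediate shifts in CR).

* **Expression** is log-normal per marker per type — right-skewed and
  strictly positive by construction, mimicking the raw intensities that
  motivate the arcsinh transform. Template locations are derived from the
  gating ruleset itself (`templatesFromRules`): markers required positive
  along a label's gating path get location 60 (600 for high-positivity
  terms), all others the background location 1, with log-scale noise 0.25
  by default. On the arcsinh scale this puts positive and negative
  populations roughly ten noise standard deviations apart — the
  "well-separated templates" regime in which gating recovery is asserted.
* **Space**: background cells follow a homogeneous point process in the
  ROI square; each planted attraction pair is a Neyman-Scott process in
  which both member types are offspring of a shared Poisson parent set
  with Gaussian offsets (the simplest process with tunable attraction);
  planted motif blocks are vertical strips with their own composition,
  which produce recoverable higher-order neighbourhood motifs. Offspring
  coordinates are clipped to the ROI, so coordinates are always in
  bounds.
* **Reproducibility**: a single master seed; each ROI draws from its own
  deterministically derived stream, so cohorts are byte-identical across
  runs and insensitive to generation order.
* An optional per-patient multiplicative intensity factor (off by
  default) emulates staining batch variation.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: segmentation errors and doublets,
spillover between channels, spatially varying background, marker
co-expression beyond the gating hierarchy, and within-patient
heterogeneity between multiple ROIs of one patient (a patient's ROIs are
i.i.d. draws, as nothing in the emulated design constrains their
dependence). Results on real cohorts depend on threshold calibration and
panel quality in ways the synthetic tests cannot probe.

Patient-level generators complement the cell-level one:
`generateFeatureCohort` produces feature matrices with a controlled
standardized effect size for the modeling recipe, and
`generateTrajectoryCohort` produces cells along a latent 1-D gradient
(markers monotone in the latent coordinate, NR probability decreasing
along it) for trajectory recovery.

# Numerical choices and degenerate inputs

* kNN ties break by (distance, cell index); duplicate coordinates are
  legal and deterministic.
* Permutation p-values use the add-one estimator in sampled mode and
  exact proportions in exhaustive mode.
* Constant channels standardize to zero with a warning; constant
  features give empty bootstrap selections with a warning; constant
  predictions give a missing Spearman correlation.
* Identical neighbourhood profiles collapse into one populated CN with
  the remaining centroids flagged empty.
* ROIs with fewer than 2 cells are skipped (with a warning) by graph
  construction; metaclusters with fewer than 10 cells are skipped by the
  trajectory stage of the pipeline.
* Interaction strength for a degenerate (zero-variance) null is defined
  as 0.

# Problem sizes used by the test suite

The suite exercises the full pipeline at desk scale, chosen to keep the
statistical assertions well-powered: gating recovery on a ~10,000-cell
cohort; interaction-test calibration over 507 pair-tests (3 groups × 13
labels squared) at 200 permutations plus 50 planted-pair cohorts of 400
cells; CN recovery on ~8,000 cells across two planted blocks; trajectory
recovery on 2,000 cells; the modeling recipe on cohorts of 24-100
patients with 200 bootstrap iterations and 200 evaluation splits; and a
bit-stability check of the full pipeline on a 6-patients-per-group,
500-cells-per-ROI smoke cohort. Study-scale defaults (5,000 bootstrap
iterations, 1,000 permutations and splits, 4,800 cells per ROI) remain
the function defaults.

# Known limitations

* Gating quality on real data is bounded by threshold calibration;
  the shipped thresholds are a documented default, not a calibrated
  panel.
* The trajectory module orders cells along piecewise-linear centroid
  paths; curvature within clusters is flattened, and pseudotime is only
  meaningful up to monotone transformation.
* The interaction test conditions on the per-ROI label multiset; it does
  not model patient-level random effects, and group-level calls pool
  ROIs with equal weight.
* The predictive recipe evaluates on cohorts of the given contrast only;
  no external validation, calibration of predicted probabilities, or
  multi-class extension is attempted.
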