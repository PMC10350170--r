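#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

VALID_GROUPS <- c("NR", "TCMR", "CR")
CELLTABLE_SCHEMA <- "imcNiche/cell_table/v1"

#' CellTable: per-cell spatial and expression records
#'
#' The universal substrate of the pipeline: one column per segmented cell,
#' one assay row per marker, with ROI, patient, clinical group and centroid
#' coordinates (micrometres, image convention: origin top-left, y increasing
#' downward) in \code{colData}. Extends
#' \linkS4class{SingleCellExperiment}; the single assay \code{"intensity"}
#' holds raw, arcsinh-transformed or channel-standardized values according
#' to the processing-state flag (see \code{\link{processingState}}).
#'
#' @slot state processing state, one of \code{"raw"}, \code{"transformed"},
#'   \code{"standardized"}. Raw intensities must be nonnegative.
#' @seealso \code{\link{CellTable}} (constructor),
#'   \code{\link{transformIntensities}}, \code{\link{standardizeChannels}}
#' @export
setClass("CellTable",
         contains = "SingleCellExperiment",
         slots = c(state = "character"))

setValidity("CellTable", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  req <- c("cell_id", "roi", "patient", "group", "x", "y")
  miss <- setdiff(req, colnames(cd))
  if (length(miss))
    return(paste("missing colData column(s):", paste(miss, collapse = ", ")))
  if (!object@state %in% c("raw", "transformed", "standardized"))
    msg <- c(msg, "state must be raw, transformed or standardized")
  key <- paste(cd$roi, cd$cell_id, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "(roi, cell_id) pairs must be unique")
  if (!all(as.character(cd$group) %in% VALID_GROUPS))
    msg <- c(msg, paste("group labels must be among:",
                        paste(VALID_GROUPS, collapse = ", ")))
  pg <- unique(data.frame(patient = as.character(cd$patient),
                          group = as.character(cd$group)))
  if (anyDuplicated(pg$patient))
    msg <- c(msg, "each patient must map to exactly one clinical group")
  if (!all(is.finite(cd$x)) || !all(is.finite(cd$y)))
    msg <- c(msg, "coordinates must be finite")
  if (object@state == "raw" && ncol(object) > 0) {
    a <- SummarizedExperiment::assay(object, "intensity")
    if (any(a < 0)) msg <- c(msg, "raw intensities must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' MarkerPanel: the antibody panel
#'
#' Ordered marker names with a role per marker (\code{nuclear},
#' \code{structural}, \code{lineage} or \code{functional}). The study
#' default (\code{\link{defaultMarkerPanel}}) is a 22-marker liver
#' allograft panel.
#'
#' @slot markers character vector of unique marker names.
#' @slot role character vector of roles, parallel to \code{markers}.
#' @export
setClass("MarkerPanel", slots = c(markers = "character", role = "character"))

setValidity("MarkerPanel", function(object) {
  msg <- character()
  if (length(object@markers) == 0L || anyDuplicated(object@markers) ||
      any(!nzchar(object@markers)))
    msg <- c(msg, "marker names must be unique and nonempty")
  if (length(object@role) != length(object@markers))
    msg <- c(msg, "one role per marker required")
  if (!all(object@role %in% c("nuclear", "structural", "lineage", "functional")))
    msg <- c(msg, "roles must be nuclear/structural/lineage/functional")
  if (length(msg)) msg else TRUE
})

#' GatingRuleSet: declarative hierarchical gating rules
#'
#' An ordered list of marker-threshold rules on the standardized expression
#' scale. Metacluster rules are evaluated first-match-wins over all cells;
#' cells matching no rule receive the fallback label. Subcluster rules are
#' evaluated first-match-wins within their parent metacluster only.
#'
#' @slot rules data.frame with columns \code{level} (\code{"metacluster"} or
#'   \code{"subcluster"}), \code{parent} (\code{NA} for metacluster rules),
#'   \code{target} (label assigned) and \code{predicate} (conjunction of
#'   terms such as \code{"CD3>=0.5;CD8<0.5"}).
#' @slot fallback metacluster label for cells matching no metacluster rule.
#' @slot immune character vector of metacluster labels regarded as immune;
#'   used by the label accounting accessors and the default pipeline.
#' @seealso \code{\link{defaultGatingRules}}, \code{\link{readGatingRules}}
#' @export
setClass("GatingRuleSet",
         slots = c(rules = "data.frame", fallback = "character",
                   immune = "character"))

setValidity("GatingRuleSet", function(object) {
  msg <- character()
  r <- object@rules
  req <- c("level", "parent", "target", "predicate")
  if (!all(req %in% colnames(r)))
    return("rules must have columns level, parent, target, predicate")
  if (nrow(r)) {
    if (!all(r$level %in% c("metacluster", "subcluster")))
      msg <- c(msg, "rule level must be metacluster or subcluster")
    meta <- r$target[r$level == "metacluster"]
    if (anyDuplicated(meta))
      msg <- c(msg, "metacluster targets must be unique")
    sub <- r[r$level == "subcluster", , drop = FALSE]
    if (anyDuplicated(sub$target))
      msg <- c(msg, "subcluster targets must be unique")
    known <- c(meta, object@fallback)
    bad <- setdiff(unique(sub$parent), known)
    if (length(bad))
      msg <- c(msg, paste("subcluster parent(s) not a metacluster target:",
                          paste(bad, collapse = ", ")))
    thr <- unlist(lapply(r$predicate, function(p) {
      vapply(parsePredicate(p), `[[`, numeric(1), "threshold")
    }))
    if (length(thr) && any(!is.finite(thr)))
      msg <- c(msg, "all rule thresholds must be finite")
  }
  if (length(object@fallback) != 1L || !nzchar(object@fallback))
    msg <- c(msg, "a single nonempty fallback label is required")
  if (length(msg)) msg else TRUE
})

#' PhenotypeAssignment: per-cell hierarchical labels
#'
#' @slot assignment data.frame with one row per cell: \code{roi},
#'   \code{cell_id}, \code{metacluster}, \code{subcluster} (\code{NA} when
#'   the parent has no subcluster rules) and \code{final} (subcluster if
#'   present, else metacluster).
#' @export
setClass("PhenotypeAssignment", slots = c(assignment = "data.frame"))

setValidity("PhenotypeAssignment", function(object) {
  a <- object@assignment
  req <- c("roi", "cell_id", "metacluster", "subcluster", "final")
  if (!all(req %in% colnames(a)))
    return("assignment needs columns roi, cell_id, metacluster, subcluster, final")
  if (any(is.na(a$metacluster)))
    return("every cell must carry exactly one metacluster label")
  TRUE
})

#' SpatialGraph: per-ROI directed k-nearest-neighbour graph
#'
#' @slot roi ROI identifier.
#' @slot cellIds cell identifiers, in table order for this ROI.
#' @slot edges data.frame of out-edges with integer indices into
#'   \code{cellIds}: \code{from}, \code{to}, \code{dist} (micrometres) and
#'   \code{rank} (1 = nearest). Neighbours of a cell are sorted by ascending
#'   distance with ties broken by cell index.
#' @slot k neighbourhood size requested (out-degree is \code{min(k, n - 1)}).
#' @export
setClass("SpatialGraph",
         slots = c(roi = "character", cellIds = "character",
                   edges = "data.frame", k = "integer"))

setValidity("SpatialGraph", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "dist", "rank") %in% colnames(e)))
    return("edges must have columns from, to, dist, rank")
  if (nrow(e) && any(e$from == e$to)) return("self-edges are not allowed")
  n <- length(object@cellIds)
  if (n >= 2L) {
    deg <- tabulate(e$from, n)
    if (!all(deg == min(object@k, n - 1L)))
      return("out-degree must equal min(k, n - 1) for every cell")
  }
  TRUE
})

#' CNModel: cellular-neighbourhood clustering of neighbour profiles
#'
#' @slot nCN number of cellular neighbourhoods.
#' @slot centroids matrix (CN x cell labels) of mean neighbour composition;
#'   each populated row is a valid composition vector.
#' @slot assignment integer CN id per cell.
#' @slot cells data.frame (\code{roi}, \code{cell_id}) parallel to
#'   \code{assignment}.
#' @slot cnNames display names, defaults \code{CN1..CNk}.
#' @slot empty logical; \code{TRUE} for centroids with no assigned cells
#'   (degenerate inputs only).
#' @export
setClass("CNModel",
         slots = c(nCN = "integer", centroids = "matrix",
                   assignment = "integer", cells = "data.frame",
                   cnNames = "character", empty = "logical"))

#' TrajectoryResult: oriented pseudotime for one metacluster
#'
#' @slot metacluster the metacluster analysed.
#' @slot embedding n x 2 matrix of embedding coordinates.
#' @slot coarse integer coarse k-means cluster per cell.
#' @slot initial id of the initial (root) coarse cluster, chosen as the
#'   cluster with the highest fraction of cells from NR samples.
#' @slot lineages list of integer vectors; each is a root-to-leaf path of
#'   coarse-cluster ids in the centroid minimum spanning tree.
#' @slot centroids coarse-cluster centroid coordinates (k x 2).
#' @slot pseudotime nonnegative arc-length pseudotime per cell (root at 0).
#' @slot lineageAssignment index of the lineage each cell projects onto.
#' @slot group clinical group per cell.
#' @export
setClass("TrajectoryResult",
         slots = c(metacluster = "character", embedding = "matrix",
                   coarse = "integer", initial = "integer",
                   lineages = "list", centroids = "matrix",
                   pseudotime = "numeric", lineageAssignment = "integer",
                   group = "character"))

#' BootstrapSelection: feature selection frequencies
#'
#' @slot frequency named numeric in [0, 1]: fraction of bootstrap
#'   iterations in which each feature had a non-zero LASSO coefficient.
#' @slot nIterations number of bootstrap iterations.
#' @slot threshold selection threshold on the frequency (default 0.5).
#' @slot selected features with frequency >= threshold.
#' @export
setClass("BootstrapSelection",
         slots = c(frequency = "numeric", nIterations = "integer",
                   threshold = "numeric", selected = "character"))

setValidity("BootstrapSelection", function(object) {
  f <- object@frequency
  if (length(f) && (any(f < 0) || any(f > 1)))
    return("frequencies must lie in [0, 1]")
  if (!setequal(object@selected, names(f)[f >= object@threshold]))
    return("selected set must be exactly the features at/above threshold")
  TRUE
})

#' ModelReport: repeated-split evaluation of the final model
#'
#' @slot metrics data.frame with one row per evaluation iteration:
#'   \code{sensitivity}, \code{specificity}, \code{accuracy}, \code{auc}.
#' @slot summary data.frame of mean and SD per metric.
#' @slot coefficients averaged final coefficients (including intercept),
#'   averaged over all evaluation iterations.
#' @slot medianPrediction data.frame per patient: \code{patient},
#'   \code{outcome}, \code{median_pred} (median validation-set predicted
#'   probability over iterations), \code{n_validation}.
#' @slot roc data.frame of ROC points (fpr, tpr) from median predictions.
#' @slot aucMedian AUC of the median predictions.
#' @slot spearmanRho,spearmanP Spearman correlation between median
#'   prediction and outcome, and the companion two-sided Wilcoxon rank-sum
#'   p-value comparing median predictions between outcome classes.
#' @export
setClass("ModelReport",
         slots = c(metrics = "data.frame", summary = "data.frame",
                   coefficients = "numeric", medianPrediction = "data.frame",
                   roc = "data.frame", aucMedian = "numeric",
                   spearmanRho = "numeric", spearmanP = "numeric"))

#' GroundTruth: generator-side truth for a synthetic cohort
#'
#' @slot cells data.frame per cell: \code{roi}, \code{cell_id},
#'   \code{true_label}, \code{motif_block} (0 = background).
#' @slot attractionPairs data.frame of planted co-aggregation pairs.
#' @slot outcome data.frame per patient: \code{patient}, \code{group}.
#' @export
setClass("GroundTruth",
         slots = c(cells = "data.frame", attractionPairs = "data.frame",
                   outcome = "data.frame"))

## ---- show methods ---------------------------------------------------------

setMethod("show", "CellTable", function(object) {
  cat("CellTable:", ncol(object), "cells x", nrow(object), "markers\n")
  cat("  state:", object@state, "\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  ROIs:", length(unique(cd$roi)),
      " patients:", length(unique(cd$patient)),
      " groups:", paste(levels(factor(cd$group)), collapse = "/"), "\n")
  invisible(NULL)
})

setMethod("show", "GatingRuleSet", function(object) {
  r <- object@rules
  cat("GatingRuleSet: ", sum(r$level == "metacluster") + 1L,
      " metaclusters (incl. fallback '", object@fallback, "'), ",
      sum(r$level == "subcluster"), " subcluster rules\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SpatialGraph", function(object) {
  cat("SpatialGraph roi=", object@roi, ": ", length(object@cellIds),
      " cells, k=", object@k, ", ", nrow(object@edges), " edges\n", sep = "")
  invisible(NULL)
})

setMethod("show", "CNModel", function(object) {
  cat("CNModel:", object@nCN, "cellular neighbourhoods over",
      length(object@assignment), "cells\n")
  if (any(object@empty))
    cat("  empty centroids:", sum(object@empty), "\n")
  invisible(NULL)
})

setMethod("show", "TrajectoryResult", function(object) {
  cat("TrajectoryResult for", object@metacluster, "\n")
  cat("  ", length(object@pseudotime), "cells,",
      nrow(object@centroids), "coarse clusters, root =", object@initial,
      ",", length(object@lineages), "lineage(s)\n")
  invisible(NULL)
})

setMethod("show", "BootstrapSelection", function(object) {
  cat("BootstrapSelection:", object@nIterations, "iterations, threshold",
      object@threshold, "\n")
  cat("  selected:", if (length(object@selected))
    paste(object@selected, collapse = ", ") else "(none)", "\n")
  invisible(NULL)
})

setMethod("show", "ModelReport", function(object) {
  cat("ModelReport:", nrow(object@metrics), "evaluation iterations\n")
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  cat(sprintf("  median-prediction AUC %.3f, Spearman rho %.3f (p %.3g)\n",
              object@aucMedian, object@spearmanRho, object@spearmanP))
  invisible(NULL)
})
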