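#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor generics used across the package instead of direct slot
#' access: \code{processingState} returns the processing-state flag of a
#' \linkS4class{CellTable}; \code{markerNames} the panel markers;
#' \code{metaclusterLabels}, \code{subclusterLabels} and \code{finalLabels}
#' the per-cell labels of a \linkS4class{PhenotypeAssignment};
#' \code{nMetaclusters}, \code{nSubclusters} and \code{nFinalLabels} the
#' label accounting of a \linkS4class{GatingRuleSet};
#' \code{cnAssignment} the per-cell cellular-neighbourhood ids of a
#' \linkS4class{CNModel}; \code{pseudotime} the per-cell pseudotime of a
#' \linkS4class{TrajectoryResult}; \code{selectedFeatures} and
#' \code{selectionFrequency} the outcome of a
#' \linkS4class{BootstrapSelection}.
#'
#' For a \linkS4class{GatingRuleSet}, \code{nSubclusters} counts subcluster
#' targets whose parent is an immune metacluster (the convention of the
#' study design this package emulates: the parenchymal Ki67/HLADR phenotype
#' splits are accounted among the non-immune final labels instead), and
#' \code{finalLabels} returns the complete set of terminal labels a cohort
#' can receive: subcluster targets of subclustered metaclusters plus the
#' remaining metacluster labels.
#'
#' @param x the object.
#' @return the accessed component; see Details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("processingState", function(x) standardGeneric("processingState"))
#' @rdname accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
#' @rdname accessors
#' @export
setGeneric("metaclusterLabels",
           function(x) standardGeneric("metaclusterLabels"))
#' @rdname accessors
#' @export
setGeneric("subclusterLabels", function(x) standardGeneric("subclusterLabels"))
#' @rdname accessors
#' @export
setGeneric("finalLabels", function(x) standardGeneric("finalLabels"))
#' @rdname accessors
#' @export
setGeneric("nMetaclusters", function(x) standardGeneric("nMetaclusters"))
#' @rdname accessors
#' @export
setGeneric("nSubclusters", function(x) standardGeneric("nSubclusters"))
#' @rdname accessors
#' @export
setGeneric("nFinalLabels", function(x) standardGeneric("nFinalLabels"))
#' @rdname accessors
#' @export
setGeneric("cnAssignment", function(x) standardGeneric("cnAssignment"))
#' @rdname accessors
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("selectionFrequency",
           function(x) standardGeneric("selectionFrequency"))

#' @rdname accessors
#' @export
setMethod("processingState", "CellTable", function(x) x@state)

#' @rdname accessors
#' @export
setMethod("markerNames", "CellTable", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("markerNames", "MarkerPanel", function(x) x@markers)

#' @rdname accessors
#' @export
setMethod("metaclusterLabels", "PhenotypeAssignment",
          function(x) x@assignment$metacluster)

#' @rdname accessors
#' @export
setMethod("subclusterLabels", "PhenotypeAssignment",
          function(x) x@assignment$subcluster)

#' @rdname accessors
#' @export
setMethod("finalLabels", "PhenotypeAssignment",
          function(x) x@assignment$final)

#' @rdname accessors
#' @export
setMethod("nMetaclusters", "GatingRuleSet", function(x) {
  length(unique(c(x@rules$target[x@rules$level == "metacluster"], x@fallback)))
})

#' @rdname accessors
#' @export
setMethod("nSubclusters", "GatingRuleSet", function(x) {
  sub <- x@rules[x@rules$level == "subcluster", , drop = FALSE]
  length(unique(sub$target[sub$parent %in% x@immune]))
})

#' @rdname accessors
#' @export
setMethod("finalLabels", "GatingRuleSet", function(x) {
  meta <- c(x@rules$target[x@rules$level == "metacluster"], x@fallback)
  sub <- x@rules[x@rules$level == "subcluster", , drop = FALSE]
  parents <- unique(sub$parent)
  c(sub$target, setdiff(meta, parents))
})

#' @rdname accessors
#' @export
setMethod("nFinalLabels", "GatingRuleSet",
          function(x) length(finalLabels(x)))

#' @rdname accessors
#' @export
setMethod("cnAssignment", "CNModel", function(x) x@assignment)

#' @rdname accessors
#' @export
setMethod("pseudotime", "TrajectoryResult", function(x) x@pseudotime)

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "BootstrapSelection", function(x) x@selected)

#' @rdname accessors
#' @export
setMethod("selectionFrequency", "BootstrapSelection", function(x) x@frequency)
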