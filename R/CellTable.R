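#' @include AllClasses.R
NULL

#' Construct a CellTable
#'
#' Bundles a marker-by-cell intensity matrix with the per-cell annotation
#' required throughout the pipeline. Coordinates are micrometres in the
#' ROI-local frame (origin top-left, y increasing downward).
#'
#' @param intensities numeric matrix, markers in rows, cells in columns.
#'   Row names are the marker names.
#' @param cell_id,roi,patient,group,x,y per-cell annotation vectors.
#'   \code{group} must take values in \code{NR}, \code{TCMR}, \code{CR};
#'   each patient must belong to exactly one group.
#' @param state processing state of \code{intensities}; new tables are
#'   normally \code{"raw"} (all values nonnegative).
#' @return a \linkS4class{CellTable}.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("CD3", "CD8"), NULL))
#' ct <- CellTable(m, cell_id = c("c1", "c2"), roi = "r1",
#'                 patient = "p1", group = "NR", x = c(0, 10), y = c(0, 5))
#' processingState(ct)
#' @export
CellTable <- function(intensities, cell_id, roi, patient, group, x, y,
                      state = "raw") {
  intensities <- as.matrix(intensities)
  n <- ncol(intensities)
  if (is.null(rownames(intensities)))
    stop("'intensities' must carry marker names as row names", call. = FALSE)
  cd <- S4Vectors::DataFrame(
    cell_id = as.character(cell_id),
    roi = as.character(rep_len(roi, n)),
    patient = as.character(rep_len(patient, n)),
    group = as.character(rep_len(group, n)),
    x = as.numeric(rep_len(x, n)),
    y = as.numeric(rep_len(y, n)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(intensity = intensities), colData = cd)
  colnames(sce) <- paste(cd$roi, cd$cell_id, sep = ":")
  new("CellTable", sce, state = state)
}

#' Per-cell annotation and expression accessors
#'
#' \code{cellData} returns the per-cell annotation (cell_id, roi, patient,
#' group, x, y) as a plain data.frame; \code{exprMatrix} the cells x
#' markers expression matrix in the table's current processing state.
#'
#' @param x a \linkS4class{CellTable}.
#' @return a data.frame (\code{cellData}) or numeric matrix
#'   (\code{exprMatrix}).
#' @export
cellData <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @rdname cellData
#' @export
exprMatrix <- function(x) {
  t(SummarizedExperiment::assay(x, "intensity"))
}

#' Subset a CellTable to one ROI
#'
#' @param x a \linkS4class{CellTable}.
#' @param roi ROI identifier.
#' @return the \linkS4class{CellTable} slice for that ROI, column order
#'   preserved.
#' @export
roiSlice <- function(x, roi) {
  stopIfNot(is(x, "CellTable"), "'x' must be a CellTable")
  x[, cellData(x)$roi == roi]
}
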