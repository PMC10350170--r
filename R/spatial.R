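#' @include AllClasses.R CellTable.R
NULL

#' Build a per-ROI directed k-nearest-neighbour graph
#'
#' Euclidean distances on cell centroids; each cell gets out-edges to its
#' \code{min(k, n - 1)} nearest neighbours, sorted by ascending distance
#' with ties broken deterministically by cell index. The graph is directed
#' (asymmetric), as in the classic histoCAT-style construction.
#'
#' @param roiCells a \linkS4class{CellTable} slice containing exactly one
#'   ROI with at least 2 cells.
#' @param k neighbourhood size (default 10).
#' @return a \linkS4class{SpatialGraph}.
#' @examples
#' m <- matrix(1, 1, 3, dimnames = list("CD3", NULL))
#' ct <- CellTable(m, cell_id = c("a", "b", "c"), roi = "r", patient = "p",
#'                 group = "NR", x = c(0, 1, 3), y = 0)
#' buildKnnGraph(ct, k = 1)@edges
#' @export
buildKnnGraph <- function(roiCells, k = 10) {
  stopIfNot(is(roiCells, "CellTable"), "'roiCells' must be a CellTable")
  cd <- cellData(roiCells)
  stopIfNot(length(unique(cd$roi)) == 1L,
            "'roiCells' must contain exactly one ROI")
  n <- nrow(cd)
  stopIfNot(n >= 2L, "ROI must contain at least 2 cells")
  stopIfNot(all(is.finite(cd$x)) && all(is.finite(cd$y)),
            "coordinates must be finite")
  kk <- as.integer(min(k, n - 1L))
  D <- as.matrix(dist(cbind(cd$x, cd$y)))
  from <- rep(seq_len(n), each = kk)
  to <- integer(n * kk)
  dd <- numeric(n * kk)
  for (i in seq_len(n)) {
    o <- order(D[i, ], seq_len(n))       # distance, then cell index
    o <- o[o != i][seq_len(kk)]
    idx <- ((i - 1L) * kk + 1L):(i * kk)
    to[idx] <- o
    dd[idx] <- D[i, o]
  }
  new("SpatialGraph", roi = as.character(cd$roi[1L]),
      cellIds = cd$cell_id,
      edges = data.frame(from = from, to = to, dist = dd,
                         rank = rep(seq_len(kk), n)),
      k = as.integer(k))
}

#' Build kNN graphs for every ROI of a table
#'
#' ROIs with fewer than 2 cells are skipped with a warning.
#'
#' @param table a \linkS4class{CellTable}.
#' @param k neighbourhood size (default 10).
#' @return named list of \linkS4class{SpatialGraph}, one per retained ROI.
#' @export
buildKnnGraphs <- function(table, k = 10) {
  cd <- cellData(table)
  rois <- unique(cd$roi)
  out <- list()
  for (r in rois) {
    if (sum(cd$roi == r) < 2L) {
      warning("ROI '", r, "' has fewer than 2 cells; skipped",
              call. = FALSE)
      next
    }
    out[[r]] <- buildKnnGraph(roiSlice(table, r), k = k)
  }
  out
}

## label vector for the cells of one graph, in graph order
.graphLabels <- function(graph, assignment, level) {
  a <- assignment@assignment
  idx <- match(paste(graph@roi, graph@cellIds, sep = "\r"),
               paste(a$roi, a$cell_id, sep = "\r"))
  if (anyNA(idx))
    stop("assignment does not cover all cells of ROI '", graph@roi, "'",
         call. = FALSE)
  switch(level, metacluster = a$metacluster[idx], final = a$final[idx])
}

## edge-label cross-tabulation: pair statistic matrix S[a, b] =
## (# edges from a-cells to b-cells) / (# a-cells)  = mean count of
## b-neighbours per a-cell. Rows with no a-cells are NA.
.pairStat <- function(graph, lab, levels) {
  tab <- base::table(factor(lab[graph@edges$from], levels = levels),
                     factor(lab[graph@edges$to], levels = levels))
  nfrom <- base::table(factor(lab, levels = levels))
  S <- unclass(tab) / as.numeric(nfrom)
  S[as.numeric(nfrom) == 0L, ] <- NA_real_
  S
}

## all distinct permutations of an index multiset (for the exhaustive test)
.distinctPerms <- function(lab) {
  uq <- unique(lab)
  rec <- function(remaining) {
    if (!length(remaining)) return(list(character(0)))
    out <- list()
    for (u in unique(remaining)) {
      rest <- remaining[-match(u, remaining)]
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(u, tail)
    }
    out
  }
  rec(lab)
}

#' Permutation test for pairwise cell-type attraction and avoidance
#'
#' For every ordered label pair (from, to) within one clinical group, the
#' observed statistic is the across-ROI mean of the mean number of
#' to-labelled out-neighbours per from-labelled cell. The null is built by
#' shuffling labels independently within each ROI (stratified permutation)
#' and recomputing the across-ROI statistic; p-values use the add-one
#' estimator \eqn{(1 + \#\{null \ge obs\})/(1 + n_{perm})} (attraction)
#' and its \eqn{\le} analogue (avoidance), so they are never exactly 0. A
#' pair is called \code{attraction} if the attraction p-value is at most
#' \code{alpha}, \code{avoidance} analogously, otherwise \code{none}.
#' Pairs whose from-label occurs in no ROI are reported with missing
#' statistics.
#'
#' With \code{method = "exhaustive"} (single-ROI graphs only) the null is
#' the complete set of distinct labelings of the ROI's label multiset and
#' p-values are exact proportions over that set, the small-sample oracle
#' for the sampled test.
#'
#' @param graphs list of \linkS4class{SpatialGraph} for the ROIs of one
#'   clinical group.
#' @param assignment a \linkS4class{PhenotypeAssignment} covering those
#'   ROIs.
#' @param group clinical group label to record in the output.
#' @param level \code{"metacluster"} or \code{"final"} labels.
#' @param nPerm number of permutations (default 1000).
#' @param alpha per-test significance level (default 0.01).
#' @param seed RNG seed for the permutations.
#' @param method \code{"sample"} (default) or \code{"exhaustive"}.
#' @return data.frame with one row per ordered pair: \code{group},
#'   \code{from_label}, \code{to_label}, \code{observed}, \code{null_mean},
#'   \code{null_sd}, \code{p_attraction}, \code{p_avoidance}, \code{call},
#'   \code{n_perm}, \code{alpha}.
#' @export
testCellInteractions <- function(graphs, assignment, group,
                                 level = c("final", "metacluster"),
                                 nPerm = 1000, alpha = 0.01, seed = 1L,
                                 method = c("sample", "exhaustive")) {
  level <- match.arg(level)
  method <- match.arg(method)
  stopIfNot(is.numeric(alpha) && length(alpha) == 1L &&
            alpha > 0 && alpha < 1, "'alpha' must lie in (0, 1)")
  if (is(graphs, "SpatialGraph")) graphs <- list(graphs)
  stopIfNot(length(graphs) >= 1L, "at least one graph required")
  labs <- lapply(graphs, .graphLabels, assignment = assignment,
                 level = level)
  levelsAll <- sort(unique(unlist(labs)))
  obs <- .acrossRoiStat(graphs, labs, levelsAll)

  if (method == "exhaustive") {
    stopIfNot(length(graphs) == 1L,
              "exhaustive enumeration supports a single ROI")
    perms <- .distinctPerms(labs[[1L]])
    null <- vapply(perms, function(p)
      .pairStat(graphs[[1L]], p, levelsAll), obs$stat)
    nPerm <- length(perms)
    pAtt <- apply(sweep(null, c(1, 2), obs$stat, function(a, b) a >= b),
                  c(1, 2), mean)
    pAvd <- apply(sweep(null, c(1, 2), obs$stat, function(a, b) a <= b),
                  c(1, 2), mean)
    nullMean <- apply(null, c(1, 2), mean)
    nullSd <- apply(null, c(1, 2), sd)
  } else {
    dims <- c(length(levelsAll), length(levelsAll), nPerm)
    null <- withSeed(seed, {
      arr <- array(NA_real_, dims)
      for (b in seq_len(nPerm)) {
        plabs <- lapply(labs, sample)
        arr[, , b] <- .acrossRoiStat(graphs, plabs, levelsAll)$stat
      }
      arr
    })
    ge <- sweep(null, c(1, 2), obs$stat, `>=`)
    le <- sweep(null, c(1, 2), obs$stat, `<=`)
    pAtt <- (1 + apply(ge, c(1, 2), sum, na.rm = TRUE)) / (1 + nPerm)
    pAvd <- (1 + apply(le, c(1, 2), sum, na.rm = TRUE)) / (1 + nPerm)
    nullMean <- apply(null, c(1, 2), mean, na.rm = TRUE)
    nullSd <- apply(null, c(1, 2), sd, na.rm = TRUE)
  }

  grid <- expand.grid(from_label = levelsAll, to_label = levelsAll,
                      stringsAsFactors = FALSE)
  i <- match(grid$from_label, levelsAll)
  j <- match(grid$to_label, levelsAll)
  res <- data.frame(
    group = group,
    from_label = grid$from_label, to_label = grid$to_label,
    observed = obs$stat[cbind(i, j)],
    null_mean = nullMean[cbind(i, j)],
    null_sd = nullSd[cbind(i, j)],
    p_attraction = pAtt[cbind(i, j)],
    p_avoidance = pAvd[cbind(i, j)],
    n_perm = nPerm, alpha = alpha,
    stringsAsFactors = FALSE)
  miss <- is.na(res$observed)
  res$p_attraction[miss] <- NA_real_
  res$p_avoidance[miss] <- NA_real_
  res$call <- ifelse(miss, NA_character_,
              ifelse(res$p_attraction <= alpha, "attraction",
              ifelse(res$p_avoidance <= alpha, "avoidance", "none")))
  res
}

## across-ROI mean of per-ROI pair statistics (ROIs lacking the from-label
## are excluded pairwise)
.acrossRoiStat <- function(graphs, labs, levels) {
  mats <- mapply(function(g, l) .pairStat(g, l, levels), graphs, labs,
                 SIMPLIFY = FALSE)
  arr <- array(unlist(mats), c(length(levels), length(levels),
                               length(mats)))
  stat <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  list(stat = stat)
}

#' Interaction network edges
#'
#' Reduces interaction results to the edges a spatial correlation network
#' plot would draw: one edge per non-\code{none} call, with a strength
#' \eqn{|observed - null\ mean| / null\ SD} (0 for a degenerate null).
#'
#' @param results data.frame from \code{\link{testCellInteractions}}.
#' @return data.frame with \code{group}, \code{from_label},
#'   \code{to_label}, \code{call}, \code{strength}.
#' @export
interactionNetwork <- function(results) {
  keep <- !is.na(results$call) & results$call != "none"
  r <- results[keep, , drop = FALSE]
  strength <- ifelse(is.na(r$null_sd) | r$null_sd == 0, 0,
                     abs(r$observed - r$null_mean) / r$null_sd)
  data.frame(group = r$group, from_label = r$from_label,
             to_label = r$to_label, call = r$call, strength = strength,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cell neighbourhood composition profiles
#'
#' For every cell, the fraction of its out-neighbours bearing each label.
#' Fractions (not counts) keep boundary cells with out-degree below k
#' comparable. Profiles sum to 1 per cell.
#'
#' @param graphs list of \linkS4class{SpatialGraph}.
#' @param assignment a \linkS4class{PhenotypeAssignment}.
#' @param level \code{"final"} or \code{"metacluster"}.
#' @return list with \code{profiles} (cells x labels matrix) and
#'   \code{cells} (data.frame roi, cell_id, in matching order).
#' @export
neighborhoodProfiles <- function(graphs, assignment,
                                 level = c("final", "metacluster")) {
  level <- match.arg(level)
  if (is(graphs, "SpatialGraph")) graphs <- list(graphs)
  labs <- lapply(graphs, .graphLabels, assignment = assignment,
                 level = level)
  levelsAll <- sort(unique(unlist(labs)))
  profs <- list(); cells <- list()
  for (g in seq_along(graphs)) {
    gr <- graphs[[g]]
    n <- length(gr@cellIds)
    counts <- unclass(base::table(
      factor(gr@edges$from, levels = seq_len(n)),
      factor(labs[[g]][gr@edges$to], levels = levelsAll)))
    profs[[g]] <- counts / rowSums(counts)
    cells[[g]] <- data.frame(roi = gr@roi, cell_id = gr@cellIds,
                             stringsAsFactors = FALSE)
  }
  profiles <- do.call(rbind, profs)
  dimnames(profiles) <- list(NULL, levelsAll)
  list(profiles = profiles, cells = do.call(rbind, cells))
}

#' Cluster neighbourhood profiles into cellular neighbourhoods
#'
#' k-means (k-means++ seeding, best of 10 restarts by within-cluster sum of
#' squares, fixed seed) on the per-cell neighbour composition profiles,
#' yielding recurring local composition motifs ("cellular neighbourhoods").
#' If the input holds fewer distinct profiles than \code{nCN}, each
#' distinct profile forms its own populated CN and the remaining centroids
#' are flagged empty.
#'
#' @param profiles output of \code{\link{neighborhoodProfiles}}.
#' @param nCN number of neighbourhoods (default 9).
#' @param seed RNG seed.
#' @return a \linkS4class{CNModel}.
#' @export
clusterNeighborhoods <- function(profiles, nCN = 9, seed = 1L) {
  x <- profiles$profiles
  stopIfNot(nrow(x) >= nCN,
            "fewer cells (", nrow(x), ") than requested neighbourhoods")
  fit <- kmeansPP(x, centers = as.integer(nCN), nstart = 10L, seed = seed)
  cents <- fit$centers
  if (is.null(colnames(cents))) colnames(cents) <- colnames(x)
  new("CNModel", nCN = as.integer(nCN), centroids = cents,
      assignment = as.integer(fit$cluster), cells = profiles$cells,
      cnNames = paste0("CN", seq_len(nCN)), empty = fit$empty)
}

#' Per-patient cellular-neighbourhood proportions
#'
#' @param model a \linkS4class{CNModel}.
#' @param table the matching \linkS4class{CellTable}.
#' @return data.frame \code{patient}, \code{group}, \code{label} (CN name),
#'   \code{proportion}; proportions sum to 1 per patient.
#' @export
cnProportions <- function(model, table) {
  cd <- cellData(table)
  key <- paste(model@cells$roi, model@cells$cell_id, sep = "\r")
  idx <- match(key, paste(cd$roi, cd$cell_id, sep = "\r"))
  stopIfNot(!anyNA(idx), "CN model cells not found in table")
  df <- data.frame(patient = cd$patient[idx], group = cd$group[idx],
                   cn = model@cnNames[model@assignment],
                   stringsAsFactors = FALSE)
  pg <- unique(df[, c("patient", "group")])
  out <- lapply(seq_len(nrow(pg)), function(i) {
    sel <- df$patient == pg$patient[i]
    counts <- base::table(factor(df$cn[sel], levels = model@cnNames))
    data.frame(patient = pg$patient[i], group = pg$group[i],
               label = model@cnNames,
               proportion = as.numeric(counts) / sum(sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Distance of every cell to the nearest reference-type cell
#'
#' Within each ROI, the Euclidean distance from each non-reference cell to
#' its nearest cell of the reference label (endothelial cells in the
#' study's usage, reflecting the vascular focus of rejection grading).
#' ROIs without any reference cell contribute missing distances.
#'
#' @param table a \linkS4class{CellTable}.
#' @param assignment a \linkS4class{PhenotypeAssignment}.
#' @param referenceLabel reference label (matched against the given level).
#' @param level \code{"metacluster"} or \code{"final"}.
#' @return list with \code{distances} (data.frame per non-reference cell:
#'   roi, cell_id, group, label, distance) and \code{medians} (data.frame
#'   per group x label median distance).
#' @export
distanceToReference <- function(table, assignment, referenceLabel,
                                level = c("metacluster", "final")) {
  level <- match.arg(level)
  a <- assignment@assignment
  lab <- if (level == "metacluster") a$metacluster else a$final
  stopIfNot(referenceLabel %in% lab,
            "reference label '", referenceLabel,
            "' absent from the assignment")
  cd <- cellData(table)
  stopIfNot(nrow(cd) == nrow(a), "assignment does not cover the table")
  out <- list()
  for (r in unique(cd$roi)) {
    sel <- cd$roi == r
    isRef <- lab[sel] == referenceLabel
    xy <- cbind(cd$x[sel], cd$y[sel])
    dvec <- rep(NA_real_, sum(sel))
    if (any(isRef)) {
      ref <- xy[isRef, , drop = FALSE]
      for (i in which(!isRef))
        dvec[i] <- sqrt(min((ref[, 1] - xy[i, 1])^2 +
                            (ref[, 2] - xy[i, 2])^2))
    }
    keep <- !isRef
    out[[r]] <- data.frame(roi = r, cell_id = cd$cell_id[sel][keep],
                           group = cd$group[sel][keep],
                           label = lab[sel][keep],
                           distance = dvec[keep],
                           stringsAsFactors = FALSE)
  }
  distances <- do.call(rbind, out)
  rownames(distances) <- NULL
  meds <- stats::aggregate(distance ~ group + label, data = distances,
                           FUN = median, na.action = stats::na.omit)
  list(distances = distances, medians = meds)
}
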