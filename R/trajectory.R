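#' @include AllClasses.R CellTable.R
NULL

#' Embed one metacluster's cells in two dimensions
#'
#' Deterministic principal-component projection of the standardized
#' expression matrix onto its first two components (any 2-D embedding is
#' acceptable plumbing for trajectory orientation; PCA is used for its
#' determinism). The sign of each component is fixed so that its largest
#' absolute loading is positive.
#'
#' @param cells a standardized \linkS4class{CellTable} slice (one
#'   metacluster), at least 10 cells.
#' @return an n x 2 matrix of embedding coordinates.
#' @export
embedMetacluster <- function(cells) {
  stopIfNot(is(cells, "CellTable"), "'cells' must be a CellTable")
  stopIfNot(ncol(cells) >= 10L, "at least 10 cells required for embedding")
  x <- exprMatrix(cells)
  keep <- apply(x, 2L, function(v) sd(v) > 0)
  p <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
              rank. = 2L)
  emb <- p$x[, seq_len(min(2L, ncol(p$x))), drop = FALSE]
  if (ncol(emb) < 2L) emb <- cbind(emb, 0)
  for (j in 1:2) {
    if (j <= ncol(p$rotation)) {
      l <- p$rotation[, j]
      if (l[which.max(abs(l))] < 0) emb[, j] <- -emb[, j]
    }
  }
  dimnames(emb) <- list(NULL, c("dim1", "dim2"))
  emb
}

#' Choose the initial (root) coarse cluster
#'
#' Coarse k-means clustering of the embedding (k-means++ seeding, 10
#' restarts, fixed seed); the cluster with the highest fraction of cells
#' from NR samples becomes the initial cluster of the trajectory, with
#' ties broken by the lowest cluster id. The default coarse k is 2; the
#' CD8 T-cell metacluster conventionally uses k = 5.
#'
#' @param embedding n x 2 embedding matrix.
#' @param group per-cell clinical group; at least one NR cell is required
#'   (otherwise orientation is undefined).
#' @param coarseK number of coarse clusters (>= 2).
#' @param seed RNG seed.
#' @return list with \code{coarse} (integer cluster per cell) and
#'   \code{initial} (root cluster id).
#' @export
orientTrajectory <- function(embedding, group, coarseK = 2, seed = 1L) {
  stopIfNot(coarseK >= 2, "'coarseK' must be at least 2")
  stopIfNot(length(group) == nrow(embedding),
            "one group label per embedded cell required")
  if (!any(group == "NR"))
    stop("no NR cells; trajectory orientation is undefined", call. = FALSE)
  fit <- kmeansPP(embedding, centers = as.integer(coarseK), nstart = 10L,
                  seed = seed)
  cl <- as.integer(fit$cluster)
  frac <- vapply(seq_len(coarseK), function(k) {
    n <- sum(cl == k)
    if (n == 0L) -Inf else sum(group[cl == k] == "NR") / n
  }, numeric(1))
  list(coarse = cl, initial = which.max(frac))  # which.max = lowest id tie
}

#' Infer lineages and pseudotime from coarse clusters
#'
#' A documented simplification of principal-curve lineage inference that
#' keeps its scientific content (branching order plus data-driven root):
#' the minimum spanning tree over coarse-cluster centroids is rooted at the
#' initial cluster; lineages are the root-to-leaf paths; each cell is
#' assigned to the lineage whose piecewise-linear centroid path it is
#' closest to, and its pseudotime is the arc-length position of its
#' orthogonal projection onto that path (root centroid at 0). With a
#' single coarse cluster, pseudotime is the cell's position along the
#' first principal axis of the embedding, shifted to start at 0.
#'
#' @param embedding n x 2 embedding matrix.
#' @param coarse integer coarse-cluster id per cell.
#' @param initial root cluster id.
#' @param metacluster label recorded in the result.
#' @param group per-cell clinical group (for density summaries).
#' @return a \linkS4class{TrajectoryResult}.
#' @export
inferLineages <- function(embedding, coarse, initial,
                          metacluster = "metacluster", group = NULL) {
  ids <- sort(unique(coarse))
  k <- length(ids)
  cents <- t(vapply(ids, function(i)
    colMeans(embedding[coarse == i, , drop = FALSE]), numeric(2)))
  rownames(cents) <- ids
  if (is.null(group)) group <- rep(NA_character_, nrow(embedding))

  if (k == 1L) {
    ctr <- sweep(embedding, 2L, colMeans(embedding))
    v <- prcomp(ctr, rank. = 1L)$rotation[, 1L]
    proj <- as.numeric(ctr %*% v)
    pt <- proj - min(proj)
    return(new("TrajectoryResult", metacluster = metacluster,
               embedding = embedding, coarse = as.integer(coarse),
               initial = as.integer(initial), lineages = list(ids),
               centroids = cents, pseudotime = pt,
               lineageAssignment = rep(1L, nrow(embedding)),
               group = as.character(group)))
  }

  g <- igraph::graph_from_adjacency_matrix(
    as.matrix(dist(cents)), mode = "undirected", weighted = TRUE)
  mst <- igraph::mst(g)
  root <- match(initial, ids)
  deg <- igraph::degree(mst)
  leaves <- setdiff(which(deg == 1L), root)
  if (!length(leaves)) leaves <- setdiff(seq_len(k), root)
  paths <- igraph::shortest_paths(mst, from = root, to = leaves,
                                  weights = igraph::E(mst)$weight)$vpath
  lineages <- lapply(paths, function(p) ids[as.integer(p)])

  ## project every cell onto each lineage's piecewise-linear path
  best_d <- rep(Inf, nrow(embedding))
  best_t <- rep(0, nrow(embedding))
  best_l <- rep(1L, nrow(embedding))
  for (li in seq_along(lineages)) {
    path <- cents[as.character(lineages[[li]]), , drop = FALSE]
    pr <- .projectPolyline(embedding, path)
    upd <- pr$dist < best_d
    best_d[upd] <- pr$dist[upd]
    best_t[upd] <- pr$arclen[upd]
    best_l[upd] <- li
  }
  new("TrajectoryResult", metacluster = metacluster, embedding = embedding,
      coarse = as.integer(coarse), initial = as.integer(initial),
      lineages = lineages, centroids = cents, pseudotime = best_t,
      lineageAssignment = best_l, group = as.character(group))
}

## orthogonal projection of points onto a polyline; returns per-point
## distance to the polyline and arc length of the projection foot
.projectPolyline <- function(pts, path) {
  n <- nrow(pts)
  nseg <- nrow(path) - 1L
  seglen <- sqrt(rowSums((path[-1L, , drop = FALSE] -
                          path[-nrow(path), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  bd <- rep(Inf, n); bt <- rep(0, n)
  for (s in seq_len(nseg)) {
    a <- path[s, ]; b <- path[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, n)
         else pmin(pmax(((pts[, 1] - a[1]) * ab[1] +
                         (pts[, 2] - a[2]) * ab[2]) / len2, 0), 1)
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
    d <- sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
    upd <- d < bd
    bd[upd] <- d[upd]
    bt[upd] <- cum[s] + t[upd] * seglen[s]
  }
  list(dist = bd, arclen = bt)
}

#' Full trajectory analysis for one metacluster
#'
#' Convenience wrapper: embed, orient (max-NR-fraction root rule), infer
#' lineages and pseudotime.
#'
#' @param cells a standardized \linkS4class{CellTable} slice.
#' @param metacluster label recorded in the result.
#' @param coarseK coarse k-means k (default 2; use 5 for CD8 T-cells).
#' @param seed RNG seed.
#' @return a \linkS4class{TrajectoryResult}.
#' @export
analyzeTrajectory <- function(cells, metacluster = "metacluster",
                              coarseK = 2, seed = 1L) {
  emb <- embedMetacluster(cells)
  grp <- cellData(cells)$group
  ori <- orientTrajectory(emb, grp, coarseK = coarseK, seed = seed)
  inferLineages(emb, ori$coarse, ori$initial, metacluster = metacluster,
                group = grp)
}

#' Per-group pseudotime density summaries
#'
#' Kernel density of pseudotime within each clinical group (each density
#' integrates to 1); groups with fewer than 5 cells are flagged and get no
#' density.
#'
#' @param result a \linkS4class{TrajectoryResult}.
#' @param n number of evaluation points.
#' @return list per group: \code{list(density=, flagged=, n=)} where
#'   \code{density} is a data.frame (x, y) or \code{NULL} when flagged.
#' @export
pseudotimeDensityByGroup <- function(result, n = 256) {
  pt <- result@pseudotime
  out <- list()
  for (g in unique(result@group)) {
    sel <- result@group == g
    if (sum(sel) < 5L) {
      out[[g]] <- list(density = NULL, flagged = TRUE, n = sum(sel))
    } else {
      d <- density(pt[sel], n = n)
      out[[g]] <- list(density = data.frame(x = d$x, y = d$y),
                       flagged = FALSE, n = sum(sel))
    }
  }
  out
}
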