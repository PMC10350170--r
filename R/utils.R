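#' @importFrom methods new is validObject slot show
#' @importFrom stats aov cor cor.test density dist kmeans
#'   kruskal.test median p.adjust prcomp quantile rbinom rlnorm rnorm rpois
#'   runif sd setNames shapiro.test t.test wilcox.test
#' @importFrom utils head write.csv read.csv combn
NULL

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic operations in the package funnel through this so that a
## single integer argument makes them reproducible without touching the
## session RNG.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("'seed' must be a single finite number", call. = FALSE)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Deterministically derive a child seed (< 2^31) from a master seed and one
## or more stream indices, so that e.g. each ROI gets its own RNG stream.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483629
  for (i in idx) s <- (s * 48271 + as.numeric(i) * 7919 + 1) %% 2147483629
  as.integer(s + 1)
}

## k-means with k-means++ seeding, best of `nstart` restarts by total
## within-cluster sum of squares. stats::kmeans does the Lloyd iterations;
## only the seeding is implemented here (kmeans++ spreads the initial
## centers, which stabilises recovery of well separated motifs).
kmeansPP <- function(x, centers, nstart = 10L, seed = NULL, iter.max = 100L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < centers)
    stop("fewer observations (", n, ") than requested clusters (", centers, ")",
         call. = FALSE)
  ux <- unique(x)
  if (nrow(ux) < centers) {
    ## Degenerate input: fewer distinct profiles than clusters. Assign each
    ## distinct profile its own cluster; remaining centroids are empty.
    key <- apply(x, 1L, paste, collapse = "\r")
    ukey <- apply(ux, 1L, paste, collapse = "\r")
    cl <- match(key, ukey)
    cents <- matrix(NA_real_, centers, ncol(x),
                    dimnames = list(NULL, colnames(x)))
    cents[seq_len(nrow(ux)), ] <- ux
    return(list(cluster = cl, centers = cents,
                empty = seq_len(centers) > nrow(ux), tot.withinss = 0))
  }
  withSeed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      init <- .kppInit(x, centers)
      fit <- suppressWarnings(
        kmeans(x, centers = x[init, , drop = FALSE], iter.max = iter.max))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    list(cluster = best$cluster, centers = best$centers,
         empty = tabulate(best$cluster, centers) == 0L,
         tot.withinss = best$tot.withinss)
  })
}

.kppInit <- function(x, k) {
  n <- nrow(x)
  ids <- integer(k)
  ids[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[ids[1L], ], "-")^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      ids[j + 1L] <- sample.int(n, 1L)
    } else {
      ids[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[ids[j + 1L], ], "-")^2))
  }
  ids
}

## Stratified fold assignment: within each class, folds are dealt round-robin
## after a random shuffle, so every fold keeps both classes whenever the
## class sizes allow it.
stratifiedFolds <- function(y, nfolds, seed = NULL) {
  y <- as.integer(factor(y))
  withSeed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
    fold
  })
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}
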