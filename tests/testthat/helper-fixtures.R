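# Small builders shared across the test files. Everything is generated in
# code; no fixture files.

# one-marker CellTable at given coordinates (single ROI)
pointTable <- function(x, y, roi = "r1", group = "NR", patient = "p1",
                       marker = "CD3", values = 1) {
  n <- length(x)
  m <- matrix(rep_len(values, n), 1, n, dimnames = list(marker, NULL))
  CellTable(m, cell_id = sprintf("c%03d", seq_len(n)), roi = roi,
            patient = patient, group = group, x = x, y = rep_len(y, n))
}

# direct label assignment for a single ROI, bypassing gating
labelAssignment <- function(labels, roi = "r1",
                            cell_id = sprintf("c%03d", seq_along(labels))) {
  new("PhenotypeAssignment",
      assignment = data.frame(roi = roi, cell_id = cell_id,
                              metacluster = labels,
                              subcluster = NA_character_, final = labels,
                              stringsAsFactors = FALSE))
}

# standardized CellTable straight from a cells x markers matrix
exprTable <- function(X, group = "NR", patient = NULL, roi = "r1",
                      x = NULL, y = NULL) {
  n <- nrow(X)
  if (is.null(patient)) patient <- paste0(rep_len(group, n), "_p",
                                          seq_len(n))
  CellTable(t(X), cell_id = sprintf("c%05d", seq_len(n)), roi = roi,
            patient = patient, group = rep_len(group, n),
            x = if (is.null(x)) seq_len(n) else x,
            y = if (is.null(y)) rep(0, n) else y,
            state = "standardized")
}

# independent multiset-permutation enumeration (test-side oracle; kept
# deliberately naive and separate from the package implementation)
oracleArrangements <- function(labels) {
  if (length(labels) == 1L) return(list(labels))
  out <- list()
  for (i in seq_along(unique(labels))) {
    u <- unique(labels)[i]
    rest <- labels[-match(u, labels)]
    for (tl in oracleArrangements(rest)) out[[length(out) + 1L]] <- c(u, tl)
  }
  out
}

# naive per-ROI pair statistic: mean count of to-labelled out-neighbours
# per from-labelled cell, via an explicit double loop
oraclePairStat <- function(graph, labels, from, to) {
  cells <- which(labels == from)
  if (!length(cells)) return(NA_real_)
  counts <- vapply(cells, function(i) {
    nb <- graph@edges$to[graph@edges$from == i]
    sum(labels[nb] == to)
  }, numeric(1))
  mean(counts)
}

# brute-force AUC by pairwise concordance counting
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive two-sided Wilcoxon rank-sum p-value for tie-free samples
oracleWilcoxP <- function(a, b) {
  v <- c(a, b)
  stopifnot(!anyDuplicated(v))
  na <- length(a)
  W <- apply(combn(length(v), na), 2, function(idx) sum(rank(v)[idx]))
  wobs <- sum(rank(v)[seq_len(na)])
  min(1, 2 * min(mean(W <= wobs), mean(W >= wobs)))
}
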