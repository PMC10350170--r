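test_that("kNN graph matches hand geometry and tie-break contract", {
  # 3 cells, k larger than n-1: complete digraph
  ct <- pointTable(x = c(0, 1, 2), y = 0)
  g <- buildKnnGraph(ct, k = 10)
  expect_true(all(tabulate(g@edges$from, 3) == 2L))
  # line geometry 0, 1, 3 with k = 1
  ct2 <- pointTable(x = c(0, 1, 3), y = 0)
  g2 <- buildKnnGraph(ct2, k = 1)
  expect_identical(g2@edges$to, c(2L, 1L, 2L))
  expect_equal(g2@edges$dist, c(1, 1, 2))
  # duplicate coordinates: deterministic id tie-break
  ct3 <- pointTable(x = c(0, 0, 0, 5), y = 0)
  g3a <- buildKnnGraph(ct3, k = 2)
  g3b <- buildKnnGraph(ct3, k = 2)
  expect_identical(g3a@edges, g3b@edges)
  expect_identical(g3a@edges$to[g3a@edges$from == 1L], c(2L, 3L))
  # too-small ROIs are skipped with a warning by the multi-ROI builder
  small <- pointTable(x = c(0, 1, 0), y = 0, roi = c("a", "a", "b"))
  expect_warning(gs <- buildKnnGraphs(small, k = 1), "skipped")
  expect_named(gs, "a")
})

test_that("single-label ROIs give degenerate permutation nulls", {
  ct <- pointTable(x = runif(12, 0, 10), y = runif(12, 0, 10))
  g <- buildKnnGraph(ct, k = 3)
  asg <- labelAssignment(rep("A", 12))
  res <- testCellInteractions(g, asg, group = "NR", nPerm = 50, seed = 1L)
  expect_equal(res$observed, 3)
  expect_equal(res$p_attraction, 1)
  expect_equal(res$p_avoidance, 1)
  expect_identical(res$call, "none")
})

test_that("planted disjoint clusters are called avoidance", {
  set.seed(10)
  xa <- runif(30, 0, 80); ya <- runif(30, 0, 80)
  xb <- runif(30, 700, 780); yb <- runif(30, 700, 780)
  ct <- pointTable(x = c(xa, xb), y = c(ya, yb))
  g <- buildKnnGraph(ct, k = 10)
  asg <- labelAssignment(rep(c("A", "B"), each = 30))
  res <- testCellInteractions(g, asg, group = "NR", nPerm = 200,
                              alpha = 0.01, seed = 2L)
  ab <- res[res$from_label == "A" & res$to_label == "B", ]
  expect_identical(ab$call, "avoidance")
  aa <- res[res$from_label == "A" & res$to_label == "A", ]
  expect_identical(aa$call, "attraction")
})

test_that("exhaustive permutation p-values match the enumeration oracle", {
  # 4-cell AABB, k = 1
  ct <- pointTable(x = c(0, 1, 10, 11), y = 0)
  g <- buildKnnGraph(ct, k = 1)
  labs <- c("A", "A", "B", "B")
  asg <- labelAssignment(labs)
  res <- testCellInteractions(g, asg, group = "NR", method = "exhaustive")
  arr <- oracleArrangements(labs)
  expect_length(arr, 6)
  for (pair in list(c("A", "A"), c("A", "B"), c("B", "A"), c("B", "B"))) {
    obs <- oraclePairStat(g, labs, pair[1], pair[2])
    null <- vapply(arr, oraclePairStat, numeric(1), graph = g,
                   from = pair[1], to = pair[2])
    row <- res[res$from_label == pair[1] & res$to_label == pair[2], ]
    expect_equal(row$p_attraction, mean(null >= obs))
    expect_equal(row$p_avoidance, mean(null <= obs))
  }
  # a random 6-cell, 3-label instance
  set.seed(4)
  ct6 <- pointTable(x = runif(6, 0, 50), y = runif(6, 0, 50))
  g6 <- buildKnnGraph(ct6, k = 2)
  labs6 <- c("A", "A", "B", "B", "C", "C")
  res6 <- testCellInteractions(g6, labelAssignment(labs6), group = "NR",
                               method = "exhaustive")
  arr6 <- oracleArrangements(labs6)
  for (i in sample(nrow(res6), 5)) {
    fr <- res6$from_label[i]; to <- res6$to_label[i]
    obs <- oraclePairStat(g6, labs6, fr, to)
    null <- vapply(arr6, oraclePairStat, numeric(1), graph = g6,
                   from = fr, to = to)
    expect_equal(res6$p_attraction[i], mean(null >= obs))
    expect_equal(res6$p_avoidance[i], mean(null <= obs))
  }
})

test_that("interaction networks keep only calls, with relabel-invariant strength", {
  ct <- pointTable(x = c(runif(20, 0, 40), runif(20, 500, 540)),
                   y = runif(40, 0, 40))
  g <- buildKnnGraph(ct, k = 5)
  labs <- rep(c("A", "B"), each = 20)
  res <- testCellInteractions(g, labelAssignment(labs), group = "NR",
                              nPerm = 100, seed = 3L)
  net <- interactionNetwork(res)
  expect_true(all(net$call != "none"))
  expect_true(all(net$strength >= 0))
  # relabeling the types permutes but preserves strengths
  labs2 <- c(A = "Z", B = "Q")[labs]
  res2 <- testCellInteractions(g, labelAssignment(labs2), group = "NR",
                               nPerm = 100, seed = 3L)
  net2 <- interactionNetwork(res2)
  key1 <- paste(c(A = "Z", B = "Q")[net$from_label],
                c(A = "Z", B = "Q")[net$to_label])
  expect_setequal(paste(net2$from_label, net2$to_label), key1)
  expect_equal(sort(net2$strength), sort(net$strength))
  # all-none results give an empty edge list
  none <- res; none$call <- "none"
  expect_identical(nrow(interactionNetwork(none)), 0L)
})

test_that("neighbourhood profiles are per-cell label fractions", {
  # cell 1 surrounded by A, A, B, C at equal distance ranks
  ct <- pointTable(x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1))
  g <- buildKnnGraph(ct, k = 4)
  labs <- c("X", "A", "A", "B", "C")
  pr <- neighborhoodProfiles(g, labelAssignment(labs))
  expect_equal(rowSums(pr$profiles), rep(1, 5), ignore_attr = TRUE)
  expect_equal(pr$profiles[1, c("A", "B", "C")], c(A = .5, B = .25, C = .25))
  # homogeneous ROI: profiles are the single-label indicator
  prh <- neighborhoodProfiles(g, labelAssignment(rep("A", 5)))
  expect_true(all(prh$profiles[, "A"] == 1))
})

test_that("CN clustering recovers planted motif blocks", {
  tmpl <- matrix(1, 4, 1, dimnames = list(c("A", "B", "C", "D"), "m1"))
  cfg <- cohortConfig(
    nPatientsPerGroup = c(NR = 2L), roisPerPatient = 1,
    roiSize = 1000, cellsPerRoi = 1500,
    composition = list(NR = c(A = 1)),
    templates = tmpl,
    attractionPairs = data.frame(a = character(), b = character(),
                                 sd = numeric(), parents = numeric()),
    motifBlocks = list(
      list(fraction = 0.5, composition = c(A = 1)),
      list(fraction = 0.5, composition = c(C = 0.5, D = 0.5))),
    seed = 31L)
  co <- generateCohort(cfg)
  graphs <- buildKnnGraphs(co$table, k = 10)
  tr <- co$truth@cells
  asg <- new("PhenotypeAssignment",
             assignment = data.frame(roi = tr$roi, cell_id = tr$cell_id,
                                     metacluster = tr$true_label,
                                     subcluster = NA_character_,
                                     final = tr$true_label,
                                     stringsAsFactors = FALSE))
  pr <- neighborhoodProfiles(graphs, asg)
  cn <- clusterNeighborhoods(pr, nCN = 2, seed = 1L)
  # compare against truth away from the block boundary
  key <- paste(pr$cells$roi, pr$cells$cell_id)
  tkey <- paste(tr$roi, tr$cell_id)
  block <- tr$motif_block[match(key, tkey)]
  cd <- cellData(co$table)
  xpos <- cd$x[match(key, paste(cd$roi, cd$cell_id))]
  interior <- abs(xpos - 500) > 60
  ari <- mclust::adjustedRandIndex(cnAssignment(cn)[interior],
                                   block[interior])
  expect_gte(ari, 0.9)
  # determinism
  cn2 <- clusterNeighborhoods(pr, nCN = 2, seed = 1L)
  expect_identical(cnAssignment(cn), cnAssignment(cn2))
})

test_that("degenerate identical profiles occupy a single CN", {
  pr <- list(profiles = matrix(rep(c(1, 0), each = 20), 20, 2,
                               dimnames = list(NULL, c("A", "B"))),
             cells = data.frame(roi = "r1",
                                cell_id = sprintf("c%03d", 1:20)))
  cn <- clusterNeighborhoods(pr, nCN = 3, seed = 1L)
  expect_identical(length(unique(cnAssignment(cn))), 1L)
  expect_identical(sum(cn@empty), 2L)
  expect_error(clusterNeighborhoods(
    list(profiles = pr$profiles[1:2, ], cells = pr$cells[1:2, ]), nCN = 3),
    "fewer cells")
})

test_that("CN proportions sum to 1 per patient and pool as expected", {
  ct <- pointTable(x = 1:20, y = 0,
                   patient = rep(c("p1", "p2"), each = 10))
  model <- new("CNModel", nCN = 2L,
               centroids = matrix(c(1, 0, 0, 1), 2, 2,
                                  dimnames = list(NULL, c("A", "B"))),
               assignment = rep(c(1L, 2L), each = 10),
               cells = data.frame(roi = "r1",
                                  cell_id = sprintf("c%03d", 1:20)),
               cnNames = c("CN1", "CN2"), empty = c(FALSE, FALSE))
  cp <- cnProportions(model, ct)
  sums <- tapply(cp$proportion, cp$patient, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_equal(cp$proportion[cp$patient == "p1" & cp$label == "CN1"], 1)
  # cohort mean over the two equal-size single-CN patients
  expect_equal(mean(cp$proportion[cp$label == "CN1"]), 0.5)
})

test_that("distance to reference cells is exact and invariant to rigid motion", {
  ct <- pointTable(x = c(0, 3, 0), y = c(0, 4, 0))
  labs <- c("endothelial", "CD8 T-cell", "CD4 T-cell")
  dp <- distanceToReference(ct, labelAssignment(labs), "endothelial")
  expect_equal(dp$distances$distance[dp$distances$label == "CD8 T-cell"], 5)
  expect_equal(dp$distances$distance[dp$distances$label == "CD4 T-cell"], 0)
  # median definition
  expect_equal(median(c(1, 3, 5)), 3)
  # translation + rotation invariance
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- cbind(c(0, 3, 0), c(0, 4, 0)) %*% t(R)
  ct2 <- pointTable(x = xy[, 1] + 100, y = xy[, 2] - 50)
  dp2 <- distanceToReference(ct2, labelAssignment(labs), "endothelial")
  expect_equal(dp2$distances$distance, dp$distances$distance,
               tolerance = 1e-9)
  # missing reference in an ROI yields NA distances
  ct3 <- pointTable(x = 1:4, y = 0, roi = c("a", "a", "b", "b"))
  labs3 <- c("endothelial", "CD8 T-cell", "CD8 T-cell", "CD4 T-cell")
  dp3 <- distanceToReference(ct3, labelAssignment(labs3,
                                                  roi = c("a", "a", "b", "b"),
                                                  cell_id = sprintf("c%03d", 1:4)),
                             "endothelial")
  expect_true(all(is.na(dp3$distances$distance[dp3$distances$roi == "b"])))
})
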