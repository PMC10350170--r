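test_that("arcsinh transform matches its closed forms", {
  m <- matrix(c(0, 5, 12), 1, 3, dimnames = list("CD3", NULL))
  ct <- CellTable(m, cell_id = c("a", "b", "c"), roi = "r1",
                  patient = "p1", group = "NR", x = 1:3, y = 0)
  tr <- transformIntensities(ct, cofactor = 5)
  v <- as.numeric(SummarizedExperiment::assay(tr))
  expect_equal(v[1], 0, tolerance = 1e-12)
  expect_equal(v[2], log(1 + sqrt(2)), tolerance = 1e-12)
  expect_equal(v[3], log(5), tolerance = 1e-12)
  expect_identical(processingState(tr), "transformed")
  # monotone
  expect_true(all(diff(v) > 0))
  expect_error(transformIntensities(tr), "raw")
  expect_error(transformIntensities(ct, cofactor = 0), "positive")
})

test_that("channel standardization yields mean 0, sd 1 and flags constants", {
  X <- cbind(a = c(1, 2, 3), b = c(4, 4, 4))
  ct <- exprTable(X)
  ct@state <- "transformed"
  expect_warning(std <- standardizeChannels(ct), "constant")
  Z <- exprMatrix(std)
  expect_equal(Z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(Z[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_identical(processingState(std), "standardized")
})

test_that("transform/standardize pipeline is stable under row permutation", {
  set.seed(1)
  m <- matrix(rexp(5 * 40), 5, 40,
              dimnames = list(paste0("mk", 1:5), NULL))
  ct <- CellTable(m, cell_id = sprintf("c%02d", 1:40), roi = "r1",
                  patient = "p1", group = "NR", x = 1:40, y = 0)
  perm <- sample(40)
  out1 <- exprMatrix(standardizeChannels(transformIntensities(ct)))
  out2 <- exprMatrix(standardizeChannels(transformIntensities(ct[, perm])))
  expect_equal(out2[order(perm), ], out1, ignore_attr = TRUE)
})

test_that("the default ruleset carries the study label accounting", {
  rs <- defaultGatingRules()
  acc <- labelAccounting(rs)
  expect_identical(acc$n_metaclusters, 10L)
  expect_identical(acc$n_subclusters, 30L)
  expect_identical(acc$n_final, 41L)
  expect_identical(acc$n_immune_final, 32L)
  expect_identical(acc$n_nonimmune_final, 9L)
})

test_that("metacluster gating follows first-match rules with fallback", {
  rs <- defaultGatingRules()
  mk <- markerNames(defaultMarkerPanel())
  mkcell <- function(pos, hi = character()) {
    v <- setNames(rep(-0.5, length(mk)), mk)
    v[pos] <- 1; v[hi] <- 3
    v
  }
  X <- rbind(cd4 = mkcell(c("CD45", "CD3", "CD4")),
             hep = mkcell(character()),
             cd8 = mkcell(c("CD45", "CD3", "CD8")))
  ct <- exprTable(X)
  asg <- assignMetaclusters(ct, rs)
  expect_identical(metaclusterLabels(asg),
                   c("CD4 T-cell", "hepatocyte", "CD8 T-cell"))
  # empty ruleset: everything falls back
  empty <- GatingRuleSet(data.frame(level = character(),
                                    parent = character(),
                                    target = character(),
                                    predicate = character()),
                         fallback = "hepatocyte")
  expect_true(all(metaclusterLabels(assignMetaclusters(ct, empty)) ==
                  "hepatocyte"))
  # unknown marker errors
  bad <- GatingRuleSet(data.frame(level = "metacluster",
                                  parent = NA_character_,
                                  target = "x", predicate = "NOPE>=0.5"),
                       fallback = "hepatocyte")
  expect_error(assignMetaclusters(ct, bad), "absent from the panel")
})

test_that("subcluster gating is parent-restricted with generic fallback", {
  rs <- defaultGatingRules()
  mk <- markerNames(defaultMarkerPanel())
  mkcell <- function(pos) {
    v <- setNames(rep(-0.5, length(mk)), mk); v[pos] <- 1; v
  }
  X <- rbind(prolifCD8 = mkcell(c("CD45", "CD3", "CD8", "Ki67")),
             hladrM2 = mkcell(c("CD45", "CD68", "CD163", "HLADR")),
             neut = mkcell(c("CD45", "CD15")),
             genericCD8 = mkcell(c("CD45", "CD3", "CD8")))
  ct <- exprTable(X)
  asg <- assignPhenotypes(ct, rs)
  expect_identical(finalLabels(asg),
                   c("Proliferating CD8 T-cell", "HLADR+ M2 macrophage",
                     "neutrophil", "CD3+CD8+ T-cell"))
  # neutrophil has no subcluster rules: subcluster stays NA
  expect_true(is.na(subclusterLabels(asg)[3]))
  # subcluster parents match the metacluster
  expect_identical(metaclusterLabels(asg)[1], "CD8 T-cell")
})

test_that("gating is deterministic and recovers synthetic ground truth", {
  cfg <- cohortConfig(nPatientsPerGroup = c(NR = 3L, TCMR = 3L, CR = 3L),
                      roisPerPatient = 1, cellsPerRoi = 1200, seed = 21L)
  co <- generateCohort(cfg)
  std <- standardizeChannels(transformIntensities(co$table))
  rs <- defaultGatingRules()
  a1 <- assignPhenotypes(std, rs)
  a2 <- assignPhenotypes(std, rs)
  expect_identical(a1@assignment, a2@assignment)
  expect_gte(ncol(co$table), 1e4 * 0.9)
  expect_gte(mean(finalLabels(a1) == co$truth@cells$true_label), 0.95)
})

test_that("per-patient proportions partition correctly", {
  labs <- c(rep("CD8 T-cell", 4), rep("hepatocyte", 6))
  asg <- labelAssignment(labs)
  ct <- pointTable(x = 1:10, y = 0)
  pr <- computeProportions(asg, ct, level = "metacluster")
  expect_equal(pr$proportion[pr$label == "CD8 T-cell"], 0.4)
  expect_equal(sum(pr$proportion), 1, tolerance = 1e-9)

  # subcluster fractions over the parent denominator: 2 of 5 CD8 cells
  labs5 <- c(rep("CD8 T-cell", 5), rep("hepatocyte", 5))
  a <- data.frame(roi = "r1", cell_id = sprintf("c%03d", 1:10),
                  metacluster = labs5,
                  subcluster = c(rep("PD1+CD8 T-cell", 2),
                                 rep("CD3+CD8+ T-cell", 3),
                                 rep(NA_character_, 5)),
                  stringsAsFactors = FALSE)
  a$final <- ifelse(is.na(a$subcluster), a$metacluster, a$subcluster)
  asg2 <- new("PhenotypeAssignment", assignment = a)
  pr2 <- computeProportions(asg2, ct, level = "subcluster",
                            denominator = "parent_metacluster")
  expect_equal(pr2$proportion[pr2$label == "PD1+CD8 T-cell"], 0.4)

  # a patient with no cells of the parent yields NA, not zero
  ct2 <- pointTable(x = 1:10, y = 0, patient = c(rep("p1", 5), rep("p2", 5)))
  labs2 <- c(rep("CD8 T-cell", 5), rep("hepatocyte", 5))
  a3 <- data.frame(roi = "r1", cell_id = sprintf("c%03d", 1:10),
                   metacluster = labs2,
                   subcluster = c(rep("PD1+CD8 T-cell", 5),
                                  rep(NA_character_, 5)),
                   stringsAsFactors = FALSE)
  a3$final <- ifelse(is.na(a3$subcluster), a3$metacluster, a3$subcluster)
  pr3 <- computeProportions(new("PhenotypeAssignment", assignment = a3),
                            ct2, level = "subcluster",
                            denominator = "parent_metacluster")
  expect_true(is.na(pr3$proportion[pr3$patient == "p2"]))
  expect_equal(pr3$proportion[pr3$patient == "p1"], 1)
})

test_that("gating rule files round-trip", {
  rs <- defaultGatingRules()
  f <- tempfile(fileext = ".csv")
  writeGatingRules(rs, f)
  back <- readGatingRules(f)
  expect_identical(back@rules$target, rs@rules$target)
  expect_identical(back@rules$predicate, rs@rules$predicate)
  expect_identical(back@fallback, rs@fallback)
  expect_identical(back@immune, rs@immune)
  # schema rejection
  bad <- tempfile(fileext = ".csv")
  writeLines(c("# schema=imcNiche/gating_rules/v999", "x"), bad)
  expect_error(readGatingRules(bad), "schema")
})
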