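test_that("degenerate single-type composition labels every cell", {
  tmpl <- matrix(10, 1, 3,
                 dimnames = list("hepatocyte", c("DNA1", "CD3", "CD45")))
  cfg <- cohortConfig(nPatientsPerGroup = c(NR = 2L), roisPerPatient = 1,
                      cellsPerRoi = 100,
                      composition = list(NR = c(hepatocyte = 1)),
                      templates = tmpl,
                      attractionPairs = data.frame(a = character(),
                                                   b = character(),
                                                   sd = numeric(),
                                                   parents = numeric()),
                      motifBlocks = list(), seed = 1L)
  co <- generateCohort(cfg)
  expect_true(all(co$truth@cells$true_label == "hepatocyte"))
})

test_that("empirical type fractions recover the configured composition", {
  tmpl <- matrix(c(10, 1, 1, 10), 2, 2,
                 dimnames = list(c("A", "B"), c("m1", "m2")))
  cfg <- cohortConfig(nPatientsPerGroup = c(NR = 50L), roisPerPatient = 1,
                      cellsPerRoi = 2000,
                      composition = list(NR = c(A = 0.7, B = 0.3)),
                      templates = tmpl,
                      attractionPairs = data.frame(a = character(),
                                                   b = character(),
                                                   sd = numeric(),
                                                   parents = numeric()),
                      motifBlocks = list(), seed = 2L)
  co <- generateCohort(cfg)
  fracA <- mean(co$truth@cells$true_label == "A")
  expect_gt(nrow(co$truth@cells), 9e4)
  expect_lt(abs(fracA - 0.7), 0.02)
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohortConfig(nPatientsPerGroup = c(NR = 2L, TCMR = 2L),
                      roisPerPatient = 1, cellsPerRoi = 300, seed = 5L)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(SummarizedExperiment::assay(a$table),
                   SummarizedExperiment::assay(b$table))
  expect_identical(cellData(a$table), cellData(b$table))
})

test_that("coordinates stay inside the ROI and intensities are nonnegative", {
  cfg <- cohortConfig(nPatientsPerGroup = c(NR = 2L, TCMR = 2L),
                      roisPerPatient = 2, roiSize = 800,
                      cellsPerRoi = 400, seed = 3L)
  co <- generateCohort(cfg)
  cd <- cellData(co$table)
  expect_true(all(cd$x >= 0 & cd$x <= 800))
  expect_true(all(cd$y >= 0 & cd$y <= 800))
  expect_true(all(SummarizedExperiment::assay(co$table) >= 0))
  expect_true(all(co$truth@cells$true_label %in%
                  rownames(cfg@templates)))
  expect_identical(nrow(co$truth@cells), ncol(co$table))
})

test_that("invalid configurations are rejected", {
  tmpl <- matrix(1, 1, 1, dimnames = list("A", "m1"))
  expect_error(cohortConfig(nPatientsPerGroup = c(NR = 2L),
                            composition = list(NR = c(A = 0.5, B = 0.6)),
                            templates = tmpl, motifBlocks = list(),
                            attractionPairs = data.frame(a = character(),
                                                         b = character(),
                                                         sd = numeric(),
                                                         parents = numeric())),
               "template")
  expect_error(cohortConfig(nPatientsPerGroup = c(NR = 2L),
                            composition = list(NR = c(A = 1)),
                            templates = tmpl, motifBlocks = list(),
                            attractionPairs = data.frame(a = "A", b = "Z",
                                                         sd = 10,
                                                         parents = 3)),
               "unknown type")
})

test_that("planted attraction pairs pull cross-type neighbours closer", {
  tmpl <- matrix(1, 3, 1, dimnames = list(c("A", "B", "C"), "m1"))
  cfg <- cohortConfig(nPatientsPerGroup = c(NR = 1L), roisPerPatient = 1,
                      roiSize = 1000, cellsPerRoi = 600,
                      composition = list(NR = c(A = .3, B = .3, C = .4)),
                      templates = tmpl,
                      attractionPairs = data.frame(a = "A", b = "B",
                                                   sd = 15, parents = 5),
                      motifBlocks = list(), seed = 8L)
  co <- generateCohort(cfg)
  cd <- cellData(co$table)
  lab <- co$truth@cells$true_label
  nnCross <- function(lab) {
    a <- which(lab == "A"); b <- which(lab == "B")
    vapply(a, function(i)
      min(sqrt((cd$x[b] - cd$x[i])^2 + (cd$y[b] - cd$y[i])^2)),
      numeric(1))
  }
  obs <- nnCross(lab)
  set.seed(1)
  shuf <- replicate(20, median(nnCross(sample(lab))))
  expect_lt(median(obs), min(shuf))
})

test_that("feature cohorts separate classes by the requested effect size", {
  fc <- generateFeatureCohort(200, 10, informative = 1L, effectSize = 3,
                              seed = 1L)
  expect_identical(dim(fc$X), c(200L, 10L))
  expect_setequal(unique(fc$y), c(0L, 1L))
  # informative feature dominates the noise features across seeds
  wins <- vapply(1:100, function(s) {
    fc <- generateFeatureCohort(200, 10, informative = 1L, effectSize = 3,
                                seed = s)
    tstat <- apply(fc$X, 2, function(v)
      abs(t.test(v[fc$y == 1], v[fc$y == 0])$statistic))
    which.max(tstat) == 1L
  }, logical(1))
  expect_gte(mean(wins), 0.95)
  # null generator is exchangeable and reproducible
  n1 <- generateFeatureCohort(40, 5, effectSize = 0, seed = 7L)
  n2 <- generateFeatureCohort(40, 5, effectSize = 0, seed = 7L)
  expect_identical(n1, n2)
  # tiny cohorts are valid iff both classes occur
  expect_silent(generateFeatureCohort(3, 2, classBalance = 1 / 3, seed = 1L))
  expect_error(generateFeatureCohort(3, 2, classBalance = 0, seed = 1L),
               "both outcome classes")
})
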