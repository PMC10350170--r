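test_that("CV lambda selection is deterministic with sane limits", {
  fc <- generateFeatureCohort(60, 5, informative = 1L, effectSize = 3,
                              seed = 1L)
  s1 <- cvSelectLambda(fc$X, fc$y, seed = 4L)
  s2 <- cvSelectLambda(fc$X, fc$y, seed = 4L)
  expect_identical(s1$lambda, s2$lambda)
  expect_identical(s1$coefficients, s2$coefficients)
  # the separating feature carries a non-zero coefficient
  expect_true(s1$coefficients["feature_01"] != 0)
  # a lambda above the analytic maximum shrinks everything to zero
  big <- cvSelectLambda(fc$X, fc$y, lambda = c(1e3, 999), seed = 4L)
  expect_true(all(big$coefficients[-1] == 0))
})

test_that("bootstrap selection frequencies behave at the extremes", {
  fc <- generateFeatureCohort(40, 4, informative = 1L, effectSize = 3,
                              seed = 2L)
  one <- bootstrapFeatureFrequency(fc$X, fc$y, nBoot = 1, seed = 3L)
  expect_true(all(selectionFrequency(one) %in% c(0, 1)))
  expect_identical(one@nIterations, 1L)
  # constant features cannot be selected
  Xc <- matrix(1, 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  expect_warning(sel <- bootstrapFeatureFrequency(Xc, rep(0:1, 10),
                                                  nBoot = 5, seed = 1L),
                 "constant")
  expect_true(all(selectionFrequency(sel) == 0))
  expect_length(selectedFeatures(sel), 0)
  # determinism of the whole recipe under the master seed
  a <- bootstrapFeatureFrequency(fc$X, fc$y, nBoot = 20, seed = 7L)
  b <- bootstrapFeatureFrequency(fc$X, fc$y, nBoot = 20, seed = 7L)
  expect_identical(selectionFrequency(a), selectionFrequency(b))
})

test_that("an outcome-defining feature is selected, noise less so", {
  fc <- generateFeatureCohort(100, 10, informative = 1L, effectSize = 3,
                              seed = 5L)
  sig <- bootstrapFeatureFrequency(fc$X, fc$y, nBoot = 60, seed = 6L)
  expect_gte(selectionFrequency(sig)["feature_01"], 0.5)
  expect_true("feature_01" %in% selectedFeatures(sig))
  null <- generateFeatureCohort(100, 10, effectSize = 0, seed = 5L)
  noise <- bootstrapFeatureFrequency(null$X, null$y, nBoot = 60, seed = 6L)
  expect_lt(mean(selectionFrequency(noise)),
            selectionFrequency(sig)["feature_01"])
})

test_that("AUC matches the pairwise-concordance oracle", {
  expect_equal(computeRocAuc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc,
               0.75)
  expect_equal(computeRocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(computeRocAuc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(computeRocAuc(1:3, c(1, 1, 1)), "both classes")
  set.seed(12)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(round(runif(n), 2))   # ties likely
    expect_equal(computeRocAuc(s, y)$auc, oracleAuc(s, y))
  }
  # ROC endpoints
  roc <- computeRocAuc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
})

test_that("Spearman association handles signal, null and degenerate input", {
  # perfectly separated predictions: exact extreme-arrangement Wilcoxon p
  pred <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05)
  out <- c(1, 1, 1, 0, 0, 0)
  sp <- spearmanAssociation(pred, out)
  expect_equal(sp$rho, cor(pred, out, method = "spearman"))
  expect_gt(sp$rho, 0.8)
  expect_equal(sp$p, oracleWilcoxP(pred[out == 1], pred[out == 0]))
  # anti-ranked predictions give a negative rho
  expect_lt(spearmanAssociation(rev(pred), out)$rho, 0)
  # constant predictions: rho missing
  expect_true(is.na(spearmanAssociation(rep(0.4, 6), out)$rho))
  # independence: mean rho near zero
  set.seed(3)
  rhos <- replicate(200, {
    p <- runif(12); y <- rep(0:1, each = 6)
    spearmanAssociation(p, y)$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("a feature identical to the outcome yields perfect metrics", {
  fc <- generateFeatureCohort(24, 3, seed = 8L)
  X <- fc$X
  X[, 1] <- fc$y
  rep <- evaluateModel(X, fc$y, "feature_01", nIter = 25, seed = 9L)
  expect_equal(rep@summary$mean, rep(1, 4))
  expect_identical(nrow(rep@metrics), 25L)
  expect_equal(rep@aucMedian, 1)
  # averaged coefficient of the defining feature is positive
  expect_gt(rep@coefficients["feature_01"], 0)
  # every patient eventually reaches a validation set here
  expect_true(all(rep@medianPrediction$n_validation > 0))
})

test_that("repeated splits are stratified and deterministic", {
  fc <- generateFeatureCohort(20, 2, informative = 1L, effectSize = 2,
                              classBalance = 0.3, seed = 10L)
  r1 <- evaluateModel(fc$X, fc$y, colnames(fc$X), nIter = 15, seed = 11L)
  r2 <- evaluateModel(fc$X, fc$y, colnames(fc$X), nIter = 15, seed = 11L)
  expect_identical(r1@metrics, r2@metrics)
  expect_identical(r1@coefficients, r2@coefficients)
  # metrics are all well-defined, which requires both classes in every
  # training and validation split
  expect_true(all(is.finite(as.matrix(r1@metrics))))
  expect_error(evaluateModel(fc$X, fc$y, character(0), nIter = 2),
               "nonempty")
})
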