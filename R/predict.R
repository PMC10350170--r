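#' @include AllClasses.R
NULL

## glmnet needs >= 2 columns; a constant zero dummy column (coefficient
## always 0) lets single-feature models go through the same code path.
.padX <- function(X) {
  if (ncol(X) >= 2L) return(X)
  cbind(X, .dummy = 0)
}

## one L1-penalized logistic fit with internal CV lambda selection;
## returns named coefficients (intercept first) at lambda.min.
## Cross-validated lambda selection needs at least 3 members per class
## (every fold complement must keep both classes twice over); smaller
## samples -- possible in bootstrap resamples of tiny cohorts -- fall back
## to the unpenalized logistic fit.
.lassoFit <- function(X, y, nfolds = 5, seed = NULL) {
  if (min(base::table(y)) < 3L) {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                           family = stats::binomial()))
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    names(cf) <- c("(Intercept)", colnames(X))
    return(cf)
  }
  Xp <- .padX(X)
  foldid <- stratifiedFolds(y, nfolds, seed = seed)
  ## glmnet emits convergence chatter on tiny folds and separable fits;
  ## both are expected in bootstrap resamples of small cohorts
  fit <- suppressWarnings(
    glmnet::cv.glmnet(Xp, y, family = "binomial",
                      type.measure = "deviance", foldid = foldid,
                      nlambda = 100, lambda.min.ratio = 1e-4,
                      standardize = TRUE))
  cf <- as.numeric(stats::coef(fit, s = "lambda.min"))
  names(cf) <- c("(Intercept)", colnames(Xp))
  cf[names(cf) != ".dummy"]
}

#' Select the LASSO penalty by cross-validation
#'
#' Stratified k-fold cross-validation (default 5 folds) of the L1-penalized
#' logistic model over a descending lambda grid (100 log-spaced values from
#' the data-derived maximum down to 1e-4 of it); returns the lambda
#' minimizing mean cross-validated binomial deviance. Deterministic under
#' the seed.
#'
#' @param X patients x features matrix.
#' @param y binary outcome (0/1), both classes present.
#' @param folds number of CV folds.
#' @param lambda optional explicit descending lambda grid.
#' @param seed RNG seed (controls fold assignment).
#' @return list with \code{lambda} (selected value), \code{coefficients}
#'   at that lambda, and the fitted \code{cv.glmnet} object.
#' @export
cvSelectLambda <- function(X, y, folds = 5, lambda = NULL, seed = 1L) {
  X <- as.matrix(X)
  stopIfNot(length(unique(y)) == 2L, "both outcome classes required")
  if (min(base::table(y)) < folds && min(base::table(y)) < 2L)
    stop("a class is too small to stratify into folds", call. = FALSE)
  Xp <- .padX(X)
  foldid <- stratifiedFolds(y, folds, seed = seed)
  fit <- glmnet::cv.glmnet(Xp, y, family = "binomial",
                           type.measure = "deviance", foldid = foldid,
                           lambda = lambda, nlambda = 100,
                           lambda.min.ratio = 1e-4, standardize = TRUE)
  cf <- as.numeric(stats::coef(fit, s = "lambda.min"))
  names(cf) <- c("(Intercept)", colnames(Xp))
  list(lambda = fit$lambda.min, coefficients = cf[names(cf) != ".dummy"],
       fit = fit)
}

#' Bootstrap feature-selection frequencies
#'
#' Resamples patients with replacement (iterations drawing a single-class
#' resample are redrawn, keeping the iteration count exact), selects the
#' penalty by internal cross-validation, fits the L1-penalized logistic
#' model and records which features have non-zero coefficients. A
#' feature's frequency is the fraction of iterations in which it was
#' selected; the final feature set is all features at or above the
#' threshold (default 50 percent).
#'
#' @param X patients x features matrix.
#' @param y binary outcome (0/1).
#' @param nBoot bootstrap iterations (study default 5000).
#' @param threshold selection frequency threshold (default 0.5).
#' @param seed RNG seed.
#' @return a \linkS4class{BootstrapSelection}.
#' @export
bootstrapFeatureFrequency <- function(X, y, nBoot = 5000, threshold = 0.5,
                                      seed = 1L) {
  X <- as.matrix(X)
  stopIfNot(nBoot >= 1, "'nBoot' must be at least 1")
  stopIfNot(length(unique(y)) == 2L, "both outcome classes required")
  feats <- colnames(X)
  if (is.null(feats)) feats <- colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (all(apply(X, 2L, sd) == 0)) {
    warning("all features are constant; nothing can be selected",
            call. = FALSE)
    freq <- setNames(rep(0, length(feats)), feats)
    return(new("BootstrapSelection", frequency = freq,
               nIterations = as.integer(nBoot), threshold = threshold,
               selected = character()))
  }
  n <- nrow(X)
  counts <- setNames(rep(0, length(feats)), feats)
  for (b in seq_len(nBoot)) {
    bs <- deriveSeed(seed, b)
    idx <- withSeed(bs, {
      repeat {
        cand <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[cand])) == 2L) break
      }
      cand
    })
    cf <- .lassoFit(X[idx, , drop = FALSE], y[idx],
                    seed = deriveSeed(seed, b, 2L))
    nz <- names(cf)[-1L][cf[-1L] != 0]
    counts[nz] <- counts[nz] + 1
  }
  freq <- counts / nBoot
  new("BootstrapSelection", frequency = freq,
      nIterations = as.integer(nBoot), threshold = threshold,
      selected = names(freq)[freq >= threshold])
}

#' AUC and ROC by the Mann-Whitney identity
#'
#' AUC is the probability that a random positive outscores a random
#' negative, ties counting one half (the Mann-Whitney U identity); the ROC
#' curve is the threshold sweep over the observed scores.
#'
#' @param scores numeric predicted scores.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return list with \code{auc} and \code{roc} (data.frame fpr, tpr).
#' @examples
#' computeRocAuc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc  # 0.75
#' @export
computeRocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (!length(pos) || !length(neg))
    stop("both classes required to compute AUC", call. = FALSE)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) -
          length(pos) * (length(pos) + 1) / 2) /
         (length(pos) * length(neg))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)))
  list(auc = auc, roc = roc)
}

#' Spearman association of median predictions with outcome
#'
#' Spearman rank correlation between per-patient median predicted
#' probabilities and the binary outcome, with a companion two-sided
#' Wilcoxon rank-sum p-value comparing the predictions between outcome
#' classes. Constant predictions give a missing correlation.
#'
#' @param predictions per-patient median predicted probabilities.
#' @param outcomes binary outcomes (0/1), both classes present, >= 3
#'   patients.
#' @return list with \code{rho} and \code{p}.
#' @export
spearmanAssociation <- function(predictions, outcomes) {
  keep <- !is.na(predictions)
  predictions <- predictions[keep]; outcomes <- as.integer(outcomes[keep])
  stopIfNot(length(predictions) >= 3L, "at least 3 patients required")
  stopIfNot(length(unique(outcomes)) == 2L, "both outcome classes required")
  rho <- if (sd(predictions) == 0) NA_real_
         else suppressWarnings(cor(predictions, outcomes,
                                   method = "spearman"))
  p <- suppressWarnings(
    wilcox.test(predictions[outcomes == 1L],
                predictions[outcomes == 0L])$p.value)
  list(rho = rho, p = p)
}

#' Repeated-split evaluation of the selected model
#'
#' Repeatedly splits the patients into stratified training and validation
#' sets (default 75/25, 1000 iterations). Each iteration fits the
#' L1-penalized logistic model (penalty by internal cross-validation) on
#' the training split restricted to the selected features, predicts
#' validation probabilities, and records sensitivity, specificity and
#' accuracy at the 0.5 probability cutoff plus the AUC. Final coefficients
#' are the average over all iterations; each patient's median validation
#' prediction feeds the median-prediction ROC and the Spearman association
#' with outcome.
#'
#' @param X patients x features matrix (row names are patient ids).
#' @param y binary outcome (0/1).
#' @param features selected feature names (nonempty).
#' @param nIter number of train/validation iterations.
#' @param trainFrac training fraction (default 0.75).
#' @param seed RNG seed.
#' @return a \linkS4class{ModelReport}.
#' @export
evaluateModel <- function(X, y, features, nIter = 1000, trainFrac = 0.75,
                          seed = 1L) {
  X <- as.matrix(X)
  stopIfNot(length(features) >= 1L, "selected feature set must be nonempty")
  stopIfNot(all(features %in% colnames(X)),
            "unknown feature(s) in selection")
  stopIfNot(length(unique(y)) == 2L, "both outcome classes required")
  if (is.null(rownames(X))) rownames(X) <- paste0("p", seq_len(nrow(X)))
  n <- nrow(X)
  Xs <- X[, features, drop = FALSE]

  metrics <- data.frame(sensitivity = numeric(nIter),
                        specificity = numeric(nIter),
                        accuracy = numeric(nIter), auc = numeric(nIter))
  coefSum <- NULL
  preds <- vector("list", n)           # validation predictions per patient

  for (it in seq_len(nIter)) {
    tridx <- withSeed(deriveSeed(seed, it), {
      tr <- unlist(lapply(split(seq_len(n), y), function(idx) {
        ntr <- max(1L, round(length(idx) * trainFrac))
        ntr <- min(ntr, length(idx) - 1L)   # keep both classes in validation
        sample(idx, ntr)
      }))
      sort(tr)
    })
    val <- setdiff(seq_len(n), tridx)
    cf <- .lassoFit(Xs[tridx, , drop = FALSE], y[tridx],
                    seed = deriveSeed(seed, it, 2L))
    coefSum <- if (is.null(coefSum)) cf else coefSum + cf
    eta <- cf[1L] + Xs[val, , drop = FALSE] %*% cf[-1L]
    prob <- as.numeric(1 / (1 + exp(-eta)))
    yv <- y[val]
    pred <- as.integer(prob >= 0.5)
    metrics$sensitivity[it] <- sum(pred == 1L & yv == 1L) / sum(yv == 1L)
    metrics$specificity[it] <- sum(pred == 0L & yv == 0L) / sum(yv == 0L)
    metrics$accuracy[it] <- mean(pred == yv)
    metrics$auc[it] <- computeRocAuc(prob, yv)$auc
    for (j in seq_along(val))
      preds[[val[j]]] <- c(preds[[val[j]]], prob[j])
  }

  med <- vapply(preds, function(p)
    if (is.null(p)) NA_real_ else median(p), numeric(1))
  nev <- vapply(preds, length, integer(1))
  if (any(nev == 0L))
    warning(sum(nev == 0L), " patient(s) never entered a validation set; ",
            "median prediction missing", call. = FALSE)
  mp <- data.frame(patient = rownames(X), outcome = y, median_pred = med,
                   n_validation = nev, stringsAsFactors = FALSE)
  keep <- !is.na(med)
  rocAuc <- computeRocAuc(med[keep], y[keep])
  sp <- spearmanAssociation(med[keep], y[keep])
  summ <- data.frame(metric = colnames(metrics),
                     mean = vapply(metrics, mean, numeric(1)),
                     sd = vapply(metrics, sd, numeric(1)),
                     row.names = NULL)
  new("ModelReport", metrics = metrics, summary = summ,
      coefficients = coefSum / nIter, medianPrediction = mp,
      roc = rocAuc$roc, aucMedian = rocAuc$auc,
      spearmanRho = sp$rho, spearmanP = sp$p)
}
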