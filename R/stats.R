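#' @include AllClasses.R
NULL

#' Choose parametric vs nonparametric test family
#'
#' Shapiro-Wilk normality gate: the parametric family (one-way ANOVA /
#' two-sample t) is used only when every group passes Shapiro-Wilk at
#' p > 0.05; otherwise (or when any group is too small for the test, n < 3)
#' the rank-based family (Kruskal-Wallis / Wilcoxon rank-sum) is used.
#'
#' @param values named list of numeric vectors, one per group.
#' @return \code{"parametric"} or \code{"nonparametric"}.
#' @export
selectTestFamily <- function(values) {
  stopIfNot(is.list(values) && length(values) >= 1L,
            "'values' must be a list of per-group numeric vectors")
  for (g in seq_along(values)) {
    v <- values[[g]][!is.na(values[[g]])]
    if (length(v) == 0L)
      stop("empty group in test-family selection", call. = FALSE)
    if (length(v) < 3L) return("nonparametric")
    if (length(unique(v)) == 1L) return("nonparametric")
    if (shapiro.test(v)$p.value <= 0.05) return("nonparametric")
  }
  "parametric"
}

#' Holm step-down adjustment
#'
#' Multiplies the i-th smallest of m p-values by (m - i + 1), enforces the
#' running maximum, caps at 1 and restores the input order (delegating to
#' \code{stats::p.adjust} after validation).
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return adjusted p-values in the input order.
#' @examples
#' holmAdjust(c(0.01, 0.04))        # 0.02, 0.04
#' holmAdjust(c(0.03, 0.03, 0.03))  # 0.09, 0.09, 0.09
#' @export
holmAdjust <- function(p) {
  stopIfNot(is.numeric(p), "'p' must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "holm")
}

#' Compare one feature across clinical groups
#'
#' Runs the overall test across all groups (one-way ANOVA or
#' Kruskal-Wallis, per the selected family) plus all pairwise tests
#' (two-sample t or Wilcoxon rank-sum) with Holm adjustment over the
#' pairwise family within this feature. Rank tests use exact enumeration
#' for small tie-free samples and mid-ranks with a normal approximation in
#' the presence of ties (the stats-package convention). Pairwise
#' comparisons involving a group with fewer than 2 values are reported
#' missing.
#'
#' @param values named list of numeric vectors, one per group (>= 2
#'   groups).
#' @param family \code{"auto"} (Shapiro-Wilk gate), \code{"parametric"} or
#'   \code{"nonparametric"}.
#' @param feature feature name recorded in the output.
#' @return list with \code{feature}, \code{family}, \code{overall_test},
#'   \code{overall_p} and \code{pairwise} (data.frame: group1, group2,
#'   test, p_raw, p_holm, significant at 0.05).
#' @export
compareGroups <- function(values, family = c("auto", "parametric",
                                             "nonparametric"),
                          feature = "feature") {
  family <- match.arg(family)
  stopIfNot(is.list(values) && length(values) >= 2L,
            "need at least 2 groups")
  if (is.null(names(values)))
    names(values) <- paste0("group", seq_along(values))
  values <- lapply(values, function(v) v[!is.na(v)])
  if (family == "auto") family <- selectTestFamily(values)

  y <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)), levels = names(values))
  if (family == "parametric") {
    overall_test <- "one-way ANOVA"
    overall_p <- summary(aov(y ~ g))[[1L]][["Pr(>F)"]][1L]
  } else {
    overall_test <- "Kruskal-Wallis"
    overall_p <- suppressWarnings(kruskal.test(y, g)$p.value)
  }
  if (is.na(overall_p) && length(unique(y)) == 1L) overall_p <- 1

  pairs <- combn(names(values), 2L)
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   test = if (family == "parametric") "two-sample t"
                          else "Wilcoxon rank-sum",
                   p_raw = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- values[[pairs[1L, i]]]; b <- values[[pairs[2L, i]]]
    if (length(a) < 2L || length(b) < 2L) next
    pw$p_raw[i] <- if (family == "parametric") {
      if (sd(c(a, b)) == 0) 1 else t.test(a, b)$p.value
    } else {
      if (length(unique(c(a, b))) == 1L) 1
      else suppressWarnings(wilcox.test(a, b, exact = NULL)$p.value)
    }
  }
  pw$p_holm <- holmAdjust(pw$p_raw)
  pw$significant <- !is.na(pw$p_holm) & pw$p_holm < 0.05
  list(feature = feature, family = family, overall_test = overall_test,
       overall_p = overall_p, pairwise = pw)
}

#' Group-difference testing over a proportion table
#'
#' Applies \code{\link{compareGroups}} to every label of a per-patient
#' proportion table (from \code{\link{computeProportions}} or
#' \code{\link{cnProportions}}), with the Holm family being the pairwise
#' comparisons within each label. Patients are the observational unit.
#'
#' @param proportions data.frame with columns \code{patient},
#'   \code{group}, \code{label}, \code{proportion}.
#' @param family test family, as in \code{\link{compareGroups}}.
#' @return tidy data.frame: \code{feature}, \code{comparison},
#'   \code{family}, \code{test}, \code{overall_p}, \code{p_raw},
#'   \code{p_holm}, \code{significant}.
#' @export
testProportionDifferences <- function(proportions,
                                      family = c("auto", "parametric",
                                                 "nonparametric")) {
  family <- match.arg(family)
  out <- list()
  for (lab in unique(proportions$label)) {
    d <- proportions[proportions$label == lab & !is.na(proportions$proportion),
                     , drop = FALSE]
    groups <- split(d$proportion, d$group)
    groups <- groups[lengths(groups) > 0L]
    if (length(groups) < 2L) next
    res <- compareGroups(groups, family = family, feature = lab)
    pw <- res$pairwise
    out[[lab]] <- data.frame(
      feature = lab,
      comparison = paste(pw$group1, "vs", pw$group2),
      family = res$family, test = pw$test,
      overall_p = res$overall_p, p_raw = pw$p_raw, p_holm = pw$p_holm,
      significant = pw$significant, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
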