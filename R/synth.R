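#' @include AllClasses.R CellTable.R phenotype.R
NULL

#' Cohort generator configuration
#'
#' Describes a synthetic IMC cohort: patient counts per clinical group,
#' ROIs per patient, ROI geometry, expected cells per ROI, per-group
#' composition over cell types, per-type expression templates, planted
#' spatial co-aggregation pairs and planted neighbourhood motif blocks.
#'
#' Spatial model: background cells follow a homogeneous (binomial) point
#' process over the ROI; each planted attraction pair is realised as a
#' Neyman-Scott process in which both member types are offspring of a
#' shared set of Poisson parent points with isotropic Gaussian offsets, the
#' simplest process with tunable attraction. Motif blocks are vertical
#' strips of the ROI (tiling from the left, the remainder being background)
#' with their own composition, which plants recoverable higher-order
#' neighbourhood motifs. Expression is log-normal per marker per type
#' (right-skewed, strictly positive, mimicking the raw IMC intensities that
#' motivate the arcsinh transform), with location given by the template and
#' a common log-scale noise \code{noiseSd}.
#'
#' @slot nPatientsPerGroup named integer, patients per clinical group.
#' @slot roisPerPatient average ROIs per patient; fractional values assign
#'   the extra ROIs deterministically to the first patients of each group.
#' @slot roiSize width/height of the square ROI in micrometres.
#' @slot cellsPerRoi expected (Poisson mean) cell count per ROI.
#' @slot composition list: group -> named probability vector over types.
#' @slot templates matrix (type x marker) of raw-intensity locations
#'   (log-normal medians).
#' @slot attractionPairs data.frame with columns \code{a}, \code{b},
#'   \code{sd} (offspring dispersion, um) and \code{parents} (expected
#'   parent count per ROI).
#' @slot motifBlocks list of blocks, each \code{list(fraction=, composition=)}
#'   with a named composition vector.
#' @slot noiseSd log-scale expression noise.
#' @slot patientEffectSd log-scale SD of an optional per-patient
#'   multiplicative intensity factor (0 = off, the default).
#' @slot seed master seed; per-ROI streams are derived deterministically.
#' @seealso \code{\link{cohortConfig}}, \code{\link{generateCohort}}
#' @export
setClass("CohortConfig",
         slots = c(nPatientsPerGroup = "integer", roisPerPatient = "numeric",
                   roiSize = "numeric", cellsPerRoi = "numeric",
                   composition = "list", templates = "matrix",
                   attractionPairs = "data.frame", motifBlocks = "list",
                   noiseSd = "numeric", patientEffectSd = "numeric",
                   seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (any(object@nPatientsPerGroup <= 0L))
    msg <- c(msg, "patient counts must be strictly positive")
  if (!all(names(object@nPatientsPerGroup) %in% VALID_GROUPS))
    msg <- c(msg, "group names must be among NR/TCMR/CR")
  if (object@roiSize <= 0 || object@cellsPerRoi <= 0 ||
      object@roisPerPatient <= 0)
    msg <- c(msg, "roiSize, cellsPerRoi and roisPerPatient must be positive")
  types <- rownames(object@templates)
  for (g in names(object@composition)) {
    p <- object@composition[[g]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, paste0("composition for group ", g,
                           " must be nonnegative and sum to 1"))
    unk <- setdiff(names(p), types)
    if (length(unk))
      msg <- c(msg, paste0("composition type(s) without expression template: ",
                           paste(unk, collapse = ", ")))
  }
  if (nrow(object@attractionPairs)) {
    unk <- setdiff(unique(c(object@attractionPairs$a,
                            object@attractionPairs$b)), types)
    if (length(unk))
      msg <- c(msg, paste0("unknown type(s) in attraction pairs: ",
                           paste(unk, collapse = ", ")))
  }
  bf <- vapply(object@motifBlocks, function(b) b$fraction, numeric(1))
  if (length(bf) && (any(bf <= 0) || sum(bf) > 1))
    msg <- c(msg, "motif block fractions must be positive and sum to <= 1")
  for (b in object@motifBlocks) {
    p <- b$composition
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, "motif block compositions must be nonnegative and sum to 1")
    if (length(setdiff(names(p), types)))
      msg <- c(msg, "motif block composition uses unknown type(s)")
  }
  if (length(msg)) msg else TRUE
})

#' Derive expression templates from a gating ruleset
#'
#' For every final label of the ruleset, markers required positive along
#' its gating path (metacluster predicate plus subcluster predicate) get a
#' raw-intensity location of 60 (600 for high-positivity terms with
#' standardized threshold >= 2), all other markers the background location
#' 1. Both nuclear intercalators are positive in every cell and CD45 in
#' every immune type. The resulting templates are well separated on the
#' arcsinh scale, so gating recovers the generating label.
#'
#' @param rules a \linkS4class{GatingRuleSet}.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param base,positive,high raw-intensity locations for background,
#'   positive and high-positive markers.
#' @return matrix of locations, final labels x markers.
#' @export
templatesFromRules <- function(rules, panel = defaultMarkerPanel(),
                               base = 1, positive = 60, high = 600) {
  mk <- markerNames(panel)
  fin <- finalLabels(rules)
  r <- rules@rules
  sub <- r[r$level == "subcluster", , drop = FALSE]
  meta <- r[r$level == "metacluster", , drop = FALSE]
  tmpl <- matrix(base, length(fin), length(mk),
                 dimnames = list(fin, mk))
  setPos <- function(row, predicate) {
    for (tm in parsePredicate(predicate)) {
      if (tm$comparator == ">=" && tm$marker %in% mk)
        tmpl[row, tm$marker] <<- if (tm$threshold >= 2) high else positive
    }
  }
  for (lab in fin) {
    if (lab %in% sub$target) {
      parent <- sub$parent[match(lab, sub$target)]
      setPos(lab, sub$predicate[match(lab, sub$target)])
    } else {
      parent <- lab                      # unsubclustered metacluster
    }
    if (parent %in% meta$target)
      setPos(lab, meta$predicate[match(parent, meta$target)])
    if (parent %in% rules@immune && "CD45" %in% mk &&
        tmpl[lab, "CD45"] == base)
      tmpl[lab, "CD45"] <- positive
  }
  for (d in intersect(c("DNA1", "DNA2"), mk)) tmpl[, d] <- positive
  tmpl
}

#' Default cohort configuration
#'
#' The default emulates the study design this package targets: 24/41/14
#' patients in the NR/TCMR/CR groups, 96 ROIs in total (about 1.2 per
#' patient), 1 mm square ROIs with on average 4,800 cells, the 41-label
#' composition with hepatocytes about 62 percent of all cells and
#' group-dependent shifts (more CD8 T-cells, PD1+ T-cell and HLADR+ M2
#' fractions in TCMR), one planted attraction pair and two planted motif
#' blocks (a CD8-enriched infiltrate and a bile-duct region).
#'
#' @param nPatientsPerGroup,roisPerPatient,roiSize,cellsPerRoi,noiseSd,seed
#'   overrides of the study-scale defaults; see \linkS4class{CohortConfig}.
#' @param composition optional list group -> named probability vector; the
#'   default is the built-in 41-label composition.
#' @param templates optional type x marker location matrix; defaults to
#'   \code{\link{templatesFromRules}} on the default ruleset.
#' @param attractionPairs,motifBlocks optional overrides.
#' @param patientEffectSd per-patient batch effect (default 0 = off).
#' @return a validated \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(nPatientsPerGroup = c(NR = 24L, TCMR = 41L,
                                               CR = 14L),
                         roisPerPatient = 96 / 79,
                         roiSize = 1000, cellsPerRoi = 4800,
                         composition = NULL, templates = NULL,
                         attractionPairs = NULL, motifBlocks = NULL,
                         noiseSd = 0.25, patientEffectSd = 0,
                         seed = 1L) {
  if (is.null(composition)) composition <- defaultComposition()
  composition <- lapply(composition, function(p) p / sum(p))
  if (is.null(templates))
    templates <- templatesFromRules(defaultGatingRules())
  if (is.null(attractionPairs))
    attractionPairs <- data.frame(a = "CD3+CD8+ T-cell",
                                  b = "M1 macrophage",
                                  sd = 25, parents = 6)
  if (is.null(motifBlocks)) motifBlocks <- defaultMotifBlocks()
  obj <- new("CohortConfig",
             nPatientsPerGroup =
               setNames(as.integer(nPatientsPerGroup),
                        names(nPatientsPerGroup)),
             roisPerPatient = roisPerPatient, roiSize = roiSize,
             cellsPerRoi = cellsPerRoi, composition = composition,
             templates = templates,
             attractionPairs = attractionPairs,
             motifBlocks = motifBlocks, noiseSd = noiseSd,
             patientEffectSd = patientEffectSd, seed = as.integer(seed))
  validObject(obj)
  obj
}

## Metacluster fractions and within-parent splits for the default cohort.
## Values follow the reported overall composition (hepatocytes ~62.6%,
## macrophages 9.9%, cholangiocytes 1.8%, B cells 1.0%) with the
## group-dependent enrichments described for TCMR and CR.
defaultComposition <- function() {
  metaFrac <- list(
    NR   = c(hepatocyte = .661, endothelial = .07, cholangiocyte = .018,
             macrophage = .099, "CD4 T-cell" = .048, "CD8 T-cell" = .042,
             monocyte = .011, neutrophil = .03, "plasma cell" = .011,
             "B cell" = .01),
    TCMR = c(hepatocyte = .601, endothelial = .07, cholangiocyte = .018,
             macrophage = .099, "CD4 T-cell" = .06, "CD8 T-cell" = .08,
             monocyte = .016, neutrophil = .03, "plasma cell" = .014,
             "B cell" = .012),
    CR   = c(hepatocyte = .631, endothelial = .07, cholangiocyte = .018,
             macrophage = .099, "CD4 T-cell" = .055, "CD8 T-cell" = .065,
             monocyte = .012, neutrophil = .03, "plasma cell" = .008,
             "B cell" = .012))
  splits <- list(
    "CD4 T-cell" = rbind(
      NR   = c("Resident memory CD4 T-cell" = .30, "CD3+CD4+ T-cell" = .25,
               "Activated CD4 T-cell" = .08, "CD16+CD4 T-cell" = .08,
               "Naive CD4 T-cell" = .10, "HLADR+ Treg" = .03,
               "HLADR- Treg" = .05, "PD1+CD4 T-cell" = .05,
               "Proliferating CD4 T-cell" = .06),
      TCMR = c(.10, .30, .12, .04, .12, .08, .07, .12, .05),
      CR   = c(.15, .32, .12, .05, .08, .05, .06, .08, .09)),
    "CD8 T-cell" = rbind(
      NR   = c("CD3+CD8+ T-cell" = .55, "Proliferating CD8 T-cell" = .10,
               "Cytotoxic CD8 T-cell" = .20, "PD1+CD8 T-cell" = .08,
               "PD1+CD28+ CD8 T-cell" = .07),
      TCMR = c(.35, .20, .20, .15, .10),
      CR   = c(.45, .13, .22, .12, .08)),
    macrophage = rbind(
      NR   = c("M1 macrophage" = .18, "M2 macrophage" = .18,
               "Proliferating M1 macrophage" = .05,
               "Proliferating M2 macrophage" = .05,
               "CD11b+ M1 macrophage" = .10, "CD11b+ M2 macrophage" = .10,
               "CD16+ M1 macrophage" = .12, "CD16+ M2 macrophage" = .15,
               "HLADR+ M2 macrophage" = .07),
      TCMR = c(.16, .16, .10, .06, .10, .10, .12, .05, .15),
      CR   = c(.16, .16, .05, .06, .10, .10, .06, .08, .23)),
    monocyte = rbind(
      NR   = c("Classical monocyte" = .40, "Non-classical monocyte" = .25,
               "Intermediate monocyte" = .25, "Activated monocyte" = .10),
      TCMR = c(.50, .15, .15, .20),
      CR   = c(.50, .15, .15, .20)),
    "B cell" = rbind(
      NR   = c("CD20+ B cell" = .70, "Proliferating B cell" = .15,
               "CD11b+ B cell" = .15),
      TCMR = c(.60, .25, .15),
      CR   = c(.65, .20, .15)),
    hepatocyte = rbind(
      NR   = c("Hepatocyte" = .92, "Proliferating hepatocyte" = .04,
               "HLADR+ hepatocyte" = .04),
      TCMR = c(.82, .08, .10),
      CR   = c(.84, .05, .11)),
    cholangiocyte = rbind(
      NR   = c("Cholangiocyte" = .90, "Proliferating cholangiocyte" = .04,
               "HLADR+ cholangiocyte" = .06),
      TCMR = c(.78, .06, .16),
      CR   = c(.78, .06, .16)),
    endothelial = rbind(
      NR   = c("Endothelial" = .90, "Proliferating endothelial" = .04,
               "HLADR+ endothelial" = .06),
      TCMR = c(.82, .06, .12),
      CR   = c(.84, .05, .11)))
  unsplit_types <- c(neutrophil = "neutrophil", "plasma cell" = "plasma cell")
  lapply(setNames(nm = c("NR", "TCMR", "CR")), function(g) {
    parts <- lapply(names(metaFrac[[g]]), function(mc) {
      f <- metaFrac[[g]][[mc]]
      if (mc %in% names(splits)) {
        s <- splits[[mc]][g, ]
        names(s) <- colnames(splits[[mc]])
        f * s / sum(s)
      } else setNames(f, mc)
    })
    p <- unlist(parts)
    p / sum(p)
  })
}

defaultMotifBlocks <- function() {
  list(list(fraction = 0.15,
            composition = c("CD3+CD8+ T-cell" = .25,
                            "Proliferating CD8 T-cell" = .10,
                            "PD1+CD8 T-cell" = .10, "HLADR+ Treg" = .05,
                            "M1 macrophage" = .15, "Hepatocyte" = .35)),
       list(fraction = 0.10,
            composition = c(Cholangiocyte = .50,
                            "HLADR+ cholangiocyte" = .10,
                            Hepatocyte = .30, Endothelial = .10)))
}

## ---- cohort generation ----------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws a full synthetic cohort under the configuration: per-ROI cell
#' counts are Poisson, truth labels are drawn from the group (or motif
#' block) composition, planted attraction pairs are co-placed as offspring
#' of shared Neyman-Scott parents, all coordinates lie inside the ROI
#' square, and raw intensities are log-normal draws around the type
#' template (strictly positive). Identical configurations with identical
#' seeds produce identical output; each ROI has its own deterministic RNG
#' stream, derived from the master seed.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return list with \code{table} (a raw \linkS4class{CellTable}) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @examples
#' cfg <- cohortConfig(nPatientsPerGroup = c(NR = 2L, TCMR = 2L),
#'                     cellsPerRoi = 200, roisPerPatient = 1)
#' cohort <- generateCohort(cfg)
#' cohort$table
#' @export
generateCohort <- function(config) {
  stopIfNot(is(config, "CohortConfig"), "'config' must be a CohortConfig")
  validObject(config)
  groups <- names(config@nPatientsPerGroup)
  W <- config@roiSize
  blocks <- config@motifBlocks
  bfrac <- vapply(blocks, function(b) b$fraction, numeric(1))
  cuts <- cumsum(c(0, bfrac))            # block strips tile from the left
  tm <- config@templates
  markers <- colnames(tm)

  ## patient / ROI bookkeeping (deterministic)
  plan <- list()
  for (g in groups) {
    np <- config@nPatientsPerGroup[[g]]
    nroi_total <- round(np * config@roisPerPatient)
    base <- nroi_total %/% np
    extra <- nroi_total - base * np
    for (i in seq_len(np)) {
      pid <- sprintf("%s_p%02d", g, i)
      nroi <- base + as.integer(i <= extra)
      for (j in seq_len(max(nroi, 0L)))
        plan[[length(plan) + 1L]] <-
          list(group = g, patient = pid,
               roi = sprintf("%s_r%d", pid, j))
    }
  }

  pts <- unique(vapply(plan, `[[`, character(1), "patient"))
  pgrp <- vapply(plan, `[[`, character(1), "group")[
    match(pts, vapply(plan, `[[`, character(1), "patient"))]
  pfactor <- setNames(rep(1, length(pts)), pts)
  if (config@patientEffectSd > 0)
    pfactor <- withSeed(deriveSeed(config@seed, 999983),
                        setNames(exp(rnorm(length(pts), 0,
                                           config@patientEffectSd)), pts))

  rois <- vector("list", length(plan))
  for (r in seq_along(plan)) {
    info <- plan[[r]]
    rois[[r]] <- withSeed(deriveSeed(config@seed, r), {
      .generateRoi(info, config, cuts, W, pfactor[[info$patient]])
    })
  }
  cells <- do.call(rbind, lapply(rois, `[[`, "cells"))
  expr <- do.call(rbind, lapply(rois, `[[`, "expr"))

  table <- CellTable(t(expr),
                     cell_id = cells$cell_id, roi = cells$roi,
                     patient = cells$patient, group = cells$group,
                     x = cells$x, y = cells$y, state = "raw")
  truth <- new("GroundTruth",
               cells = cells[, c("roi", "cell_id", "true_label",
                                 "motif_block")],
               attractionPairs = config@attractionPairs,
               outcome = data.frame(patient = pts, group = pgrp,
                                    stringsAsFactors = FALSE))
  list(table = table, truth = truth)
}

## one ROI under an already-seeded RNG stream
.generateRoi <- function(info, config, cuts, W, pfac) {
  n <- max(1L, rpois(1L, config@cellsPerRoi))
  comp <- config@composition[[info$group]]
  blocks <- config@motifBlocks
  nb <- length(blocks)
  widths <- c(diff(cuts), 1 - cuts[length(cuts)])   # blocks..., background
  region <- sample.int(nb + 1L, n, replace = TRUE, prob = widths)

  lab <- character(n)
  x <- numeric(n); y <- runif(n, 0, W)
  for (b in seq_len(nb)) {
    idx <- which(region == b)
    if (!length(idx)) next
    p <- blocks[[b]]$composition
    lab[idx] <- names(p)[sample.int(length(p), length(idx),
                                    replace = TRUE, prob = p)]
    x[idx] <- runif(length(idx), cuts[b] * W, cuts[b + 1L] * W)
  }
  bg <- which(region == nb + 1L)
  x0 <- cuts[length(cuts)] * W
  if (length(bg)) {
    lab[bg] <- names(comp)[sample.int(length(comp), length(bg),
                                      replace = TRUE, prob = comp)]
    x[bg] <- runif(length(bg), x0, W)
  }

  ## Neyman-Scott co-placement of planted attraction pairs (background only)
  ap <- config@attractionPairs
  for (i in seq_len(nrow(ap))) {
    members <- bg[lab[bg] %in% c(ap$a[i], ap$b[i])]
    if (!length(members)) next
    npar <- max(1L, rpois(1L, ap$parents[i]))
    px <- runif(npar, x0, W); py <- runif(npar, 0, W)
    par <- sample.int(npar, length(members), replace = TRUE)
    x[members] <- pmin(pmax(px[par] + rnorm(length(members), 0, ap$sd[i]),
                            x0), W)
    y[members] <- pmin(pmax(py[par] + rnorm(length(members), 0, ap$sd[i]),
                            0), W)
  }

  loc <- config@templates[lab, , drop = FALSE]
  expr <- matrix(rlnorm(length(loc), meanlog = log(loc) + log(pfac),
                        sdlog = config@noiseSd),
                 nrow = n, dimnames = list(NULL, colnames(loc)))
  cells <- data.frame(cell_id = sprintf("c%05d", seq_len(n)),
                      roi = info$roi, patient = info$patient,
                      group = info$group, x = x, y = y,
                      true_label = lab,
                      motif_block = ifelse(region > length(blocks), 0L,
                                           region),
                      stringsAsFactors = FALSE)
  list(cells = cells, expr = expr)
}

## ---- patient-level feature cohorts ---------------------------------------

#' Generate a patient-level feature cohort
#'
#' Produces a patients x features matrix with a binary outcome for testing
#' the predictive-modeling recipe: informative features differ between the
#' outcome classes by \code{effectSize} standard deviations, all others
#' are exchangeable standard-normal noise.
#'
#' @param nPatients number of patients (split into the two outcome classes
#'   by \code{classBalance}); both classes must be nonempty.
#' @param nFeatures number of candidate features.
#' @param informative integer indices of informative features (may be
#'   empty).
#' @param effectSize standardized mean difference of informative features.
#' @param classBalance fraction of patients in the positive class.
#' @param seed RNG seed.
#' @return list with \code{X} (matrix with patient row names) and \code{y}
#'   (0/1 outcome vector).
#' @export
generateFeatureCohort <- function(nPatients, nFeatures, informative =
                                    integer(), effectSize = 0,
                                  classBalance = 0.5, seed = 1L) {
  stopIfNot(all(informative %in% seq_len(nFeatures)),
            "'informative' must be a subset of the feature indices")
  n1 <- round(nPatients * classBalance)
  n0 <- nPatients - n1
  if (n0 < 1L || n1 < 1L)
    stop("both outcome classes must be present", call. = FALSE)
  withSeed(seed, {
    y <- c(rep(0L, n0), rep(1L, n1))
    X <- matrix(rnorm(nPatients * nFeatures), nPatients, nFeatures,
                dimnames = list(sprintf("p%03d", seq_len(nPatients)),
                                sprintf("feature_%02d", seq_len(nFeatures))))
    for (j in informative) X[y == 1L, j] <- X[y == 1L, j] + effectSize
    list(X = X, y = y)
  })
}

#' Generate cells along a latent differentiation gradient
#'
#' Emits a standardized-state \linkS4class{CellTable} whose marker values
#' are monotone linear functions of a latent pseudotime \eqn{t \sim U(0,1)}
#' plus Gaussian noise, with the probability of the NR group decreasing in
#' \eqn{t} (so the orientation rule can anchor the root at low \eqn{t}).
#' Used to test trajectory recovery.
#'
#' @param nCells number of cells.
#' @param nMarkers number of markers (half increasing, half decreasing in
#'   \eqn{t}).
#' @param noiseSd Gaussian noise SD on the marker scale.
#' @param seed RNG seed.
#' @return list with \code{table} (standardized \linkS4class{CellTable})
#'   and \code{latent} (the true gradient per cell).
#' @export
generateTrajectoryCohort <- function(nCells = 2000, nMarkers = 8,
                                     noiseSd = 0.4, seed = 1L) {
  withSeed(seed, {
    t <- runif(nCells)
    beta <- rep(c(2, -2), length.out = nMarkers)
    X <- outer(t, beta) + matrix(rnorm(nCells * nMarkers, 0, noiseSd),
                                 nCells, nMarkers)
    colnames(X) <- sprintf("M%02d", seq_len(nMarkers))
    grp <- ifelse(runif(nCells) < 0.9 - 0.8 * t, "NR", "TCMR")
    tab <- CellTable(t(X),
                     cell_id = sprintf("c%05d", seq_len(nCells)),
                     roi = "r1",
                     patient = paste0(grp, "_", sprintf("p%05d",
                                                        seq_len(nCells))),
                     group = grp,
                     x = runif(nCells, 0, 1000), y = runif(nCells, 0, 1000),
                     state = "standardized")
    list(table = tab, latent = t)
  })
}
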