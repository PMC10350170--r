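#' @include AllClasses.R CellTable.R phenotype.R spatial.R stats.R predict.R
NULL

#' Read and write cell tables
#'
#' Comma-separated UTF-8 text with a schema header comment, fixed header
#' names (\code{cell_id}, \code{roi}, \code{patient}, \code{group},
#' \code{x}, \code{y}, one column per marker) and "." as the decimal
#' separator; write then read is value-identical with row order preserved.
#' Readers reject files declaring a different schema version; files
#' without a schema line (external upstream exports) are accepted.
#'
#' @param table a \linkS4class{CellTable}.
#' @param path file path.
#' @param markers optional explicit marker column names for reading; by
#'   default every column beyond the required six is a marker.
#' @param state processing state to record on the table read (default
#'   \code{"raw"}).
#' @return \code{readCellTable} returns a \linkS4class{CellTable};
#'   \code{writeCellTable} returns \code{path} invisibly.
#' @export
writeCellTable <- function(table, path) {
  stopIfNot(is(table, "CellTable"), "'table' must be a CellTable")
  cd <- cellData(table)
  df <- cbind(cd[, c("cell_id", "roi", "patient", "group", "x", "y")],
              as.data.frame(exprMatrix(table)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# schema=", CELLTABLE_SCHEMA),
               paste0("# state=", processingState(table))), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path, markers = NULL, state = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  schema <- sub("^# schema=", "", grep("^# schema=", hdr, value = TRUE))
  if (length(schema) && !identical(schema, CELLTABLE_SCHEMA))
    stop("unsupported cell table schema: ", schema, call. = FALSE)
  fstate <- sub("^# state=", "", grep("^# state=", hdr, value = TRUE))
  if (is.null(state))
    state <- if (length(fstate) == 1L) fstate else "raw"
  df <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                 stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("cell_id", "roi", "patient", "group", "x", "y")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("cell table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(markers)) markers <- setdiff(colnames(df), req)
  badg <- !df$group %in% VALID_GROUPS
  if (any(badg))
    stop("unknown group label(s) at row(s): ",
         paste(head(which(badg), 5L), collapse = ", "), call. = FALSE)
  m <- t(as.matrix(df[, markers, drop = FALSE]))
  if (state == "raw" && any(m < 0))
    stop("negative raw intensity at row(s): ",
         paste(head(which(colSums(m < 0) > 0), 5L), collapse = ", "),
         call. = FALSE)
  CellTable(m, cell_id = as.character(df$cell_id), roi = df$roi,
            patient = df$patient, group = df$group, x = df$x, y = df$y,
            state = state)
}

#' Pipeline configuration
#'
#' Assembles and validates the parameters of \code{\link{runPipeline}}.
#' Defaults are the study settings: arcsinh cofactor 5, kNN k = 10, 1000
#' permutations at alpha 0.01, 9 cellular neighbourhoods, coarse k-means
#' k = 2 (5 for CD8 T-cells), 5000 bootstrap iterations with a 0.5
#' selection threshold, and 1000 75/25 evaluation splits.
#'
#' @param stages character vector of stages to run, a subset of
#'   \code{c("phenotype", "stats", "spatial", "trajectory", "predict")};
#'   later stages require the earlier ones they consume.
#' @param cofactor,k,nPerm,alpha,nCN,coarseK,nBoot,selectionThreshold,nIter,trainFrac
#'   stage parameters (see the stage functions).
#' @param trajectoryMetaclusters metaclusters to run trajectories on.
#' @param predictContrast two groups to contrast in the predictive model.
#' @param seed master seed for all stochastic stages.
#' @return a validated named list with class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(stages = c("phenotype", "stats", "spatial",
                                      "trajectory", "predict"),
                           cofactor = 5, k = 10, nPerm = 1000,
                           alpha = 0.01, nCN = 9,
                           coarseK = c("CD4 T-cell" = 2, "CD8 T-cell" = 5),
                           trajectoryMetaclusters = c("CD4 T-cell",
                                                      "CD8 T-cell"),
                           predictContrast = c("NR", "TCMR"),
                           nBoot = 5000, selectionThreshold = 0.5,
                           nIter = 1000, trainFrac = 0.75, seed = 1L) {
  stopIfNot(all(stages %in% c("phenotype", "stats", "spatial",
                              "trajectory", "predict")),
            "unknown stage name(s)")
  stopIfNot(cofactor > 0, "'cofactor' must be positive")
  stopIfNot(k >= 1, "'k' must be at least 1")
  stopIfNot(alpha > 0 && alpha < 1, "'alpha' must lie in (0,1)")
  stopIfNot(nPerm >= 1 && nCN >= 1 && nBoot >= 1 && nIter >= 1,
            "iteration counts must be positive")
  stopIfNot(selectionThreshold > 0 && selectionThreshold <= 1,
            "'selectionThreshold' must lie in (0,1]")
  stopIfNot(trainFrac > 0 && trainFrac < 1, "'trainFrac' must lie in (0,1)")
  structure(list(stages = stages, cofactor = cofactor, k = k,
                 nPerm = nPerm, alpha = alpha, nCN = nCN,
                 coarseK = coarseK,
                 trajectoryMetaclusters = trajectoryMetaclusters,
                 predictContrast = predictContrast, nBoot = nBoot,
                 selectionThreshold = selectionThreshold, nIter = nIter,
                 trainFrac = trainFrac, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   \code{\link{pipelineConfig}}.
#' @return a validated \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$coarseK)) vals$coarseK <- unlist(vals$coarseK)
  do.call(pipelineConfig, vals)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order on a raw cell table: transform and
#' standardize, gate phenotypes, per-patient proportions and group
#' statistics, spatial graphs with interaction tests, CN discovery and CN
#' proportions plus distance-to-endothelial profiles, per-metacluster
#' trajectories, and the predictive recipe on the contrast's significant
#' proportion features (falling back to all features when none reach
#' significance, so that small smoke cohorts still yield a model report).
#' Writes per-stage result tables, a parameter log and a deterministic
#' machine-readable run manifest into \code{outDir}; a rerun with the same
#' configuration and seed is bit-stable for all outputs.
#'
#' @param table a raw \linkS4class{CellTable}.
#' @param config a \code{"PipelineConfig"} from \code{\link{pipelineConfig}}.
#' @param rules a \linkS4class{GatingRuleSet}.
#' @param outDir output directory (created if needed).
#' @return (invisibly) list with the in-memory stage results and
#'   \code{outDir}.
#' @export
runPipeline <- function(table, config = pipelineConfig(),
                        rules = defaultGatingRules(), outDir) {
  stopIfNot(inherits(config, "PipelineConfig"),
            "'config' must come from pipelineConfig()")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- c("imcNiche pipeline run",
                paste0("seed=", config$seed),
                paste0("stages=", paste(config$stages, collapse = ",")),
                vapply(setdiff(names(config), c("stages", "coarseK",
                                                "trajectoryMetaclusters",
                                                "predictContrast")),
                       function(nm) paste0(nm, "=", config[[nm]]),
                       character(1)))
  results <- list()
  files <- character()
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }
  runStage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## phenotype ---------------------------------------------------------------
  std <- runStage("phenotype", {
    standardizeChannels(transformIntensities(table,
                                             cofactor = config$cofactor))
  })
  assignment <- NULL
  if ("phenotype" %in% config$stages) {
    assignment <- runStage("phenotype", assignPhenotypes(std, rules))
    results$assignment <- assignment
    emit(assignment@assignment, "phenotype_assignment.csv")
    props <- computeProportions(assignment, std, level = "metacluster")
    fprops <- computeProportions(assignment, std, level = "final")
    results$proportions <- props
    results$finalProportions <- fprops
    emit(props, "metacluster_proportions.csv")
    emit(fprops, "final_proportions.csv")
  }

  ## stats -------------------------------------------------------------------
  if ("stats" %in% config$stages) {
    stopIfNot(!is.null(assignment), "stats stage requires phenotype stage")
    results$stats <- runStage("stats",
      testProportionDifferences(results$finalProportions))
    emit(results$stats, "group_tests.csv")
  }

  ## spatial -----------------------------------------------------------------
  if ("spatial" %in% config$stages) {
    stopIfNot(!is.null(assignment), "spatial stage requires phenotype stage")
    runStage("spatial", {
      graphs <- buildKnnGraphs(std, k = config$k)
      cdg <- cellData(std)
      roiGroup <- vapply(graphs, function(g)
        cdg$group[match(g@roi, cdg$roi)], character(1))
      inter <- list()
      for (g in unique(roiGroup)) {
        inter[[g]] <- testCellInteractions(
          graphs[roiGroup == g], assignment, group = g, level = "final",
          nPerm = config$nPerm, alpha = config$alpha,
          seed = deriveSeed(config$seed, 101L, match(g, VALID_GROUPS)))
      }
      results$interactions <- do.call(rbind, inter)
      rownames(results$interactions) <- NULL
      emit(results$interactions, "interactions.csv")
      emit(interactionNetwork(results$interactions), "interaction_network.csv")
      prof <- neighborhoodProfiles(graphs, assignment, level = "final")
      cn <- clusterNeighborhoods(prof, nCN = config$nCN,
                                 seed = deriveSeed(config$seed, 202L))
      results$cn <- cn
      cnp <- cnProportions(cn, std)
      results$cnProportions <- cnp
      emit(data.frame(prof$cells, cn = cn@cnNames[cn@assignment]),
           "cn_assignment.csv")
      emit(cnp, "cn_proportions.csv")
      if ("endothelial" %in% metaclusterLabels(assignment)) {
        dp <- distanceToReference(std, assignment, "endothelial",
                                  level = "metacluster")
        results$distances <- dp
        emit(dp$medians, "distance_to_endothelial_medians.csv")
      }
      graphs
    })
  }

  ## trajectory --------------------------------------------------------------
  if ("trajectory" %in% config$stages) {
    stopIfNot(!is.null(assignment),
              "trajectory stage requires phenotype stage")
    results$trajectories <- list()
    for (mc in config$trajectoryMetaclusters) {
      sel <- metaclusterLabels(assignment) == mc
      if (sum(sel) < 10L) next
      ck <- if (mc %in% names(config$coarseK)) config$coarseK[[mc]] else 2
      tr <- runStage("trajectory",
        analyzeTrajectory(std[, sel], metacluster = mc, coarseK = ck,
                          seed = deriveSeed(config$seed, 303L,
                                            which(mc == config$trajectoryMetaclusters))))
      results$trajectories[[mc]] <- tr
      emit(data.frame(roi = cellData(std)$roi[sel],
                      cell_id = cellData(std)$cell_id[sel],
                      lineage = tr@lineageAssignment,
                      pseudotime = tr@pseudotime),
           paste0("trajectory_", gsub("[^A-Za-z0-9]+", "_", mc), ".csv"))
    }
  }

  ## predict -----------------------------------------------------------------
  if ("predict" %in% config$stages) {
    stopIfNot(!is.null(results$stats) || !is.null(results$finalProportions),
              "predict stage requires phenotype stage")
    runStage("predict", {
      contrast <- config$predictContrast
      fp <- results$finalProportions
      fp <- fp[fp$group %in% contrast, , drop = FALSE]
      wide <- stats::reshape(
        fp[, c("patient", "group", "label", "proportion")],
        idvar = c("patient", "group"), timevar = "label",
        direction = "wide")
      fn <- sub("^proportion\\.", "", colnames(wide)[-(1:2)])
      colnames(wide)[-(1:2)] <- fn
      X <- as.matrix(wide[, fn, drop = FALSE])
      X[is.na(X)] <- 0
      rownames(X) <- wide$patient
      y <- as.integer(wide$group == contrast[2L])
      cand <- fn
      if (!is.null(results$stats)) {
        st <- results$stats
        sig <- unique(st$feature[st$significant &
                                 st$comparison %in%
                                   c(paste(contrast[1L], "vs", contrast[2L]),
                                     paste(contrast[2L], "vs", contrast[1L]))])
        if (length(sig)) cand <- sig
        else logLines <- c(logLines,
                           "predict: no significant features; using all")
      }
      sel <- bootstrapFeatureFrequency(X[, cand, drop = FALSE], y,
                                       nBoot = config$nBoot,
                                       threshold = config$selectionThreshold,
                                       seed = deriveSeed(config$seed, 404L))
      results$selection <- sel
      feats <- selectedFeatures(sel)
      if (!length(feats))           # keep the report computable
        feats <- names(sort(selectionFrequency(sel),
                            decreasing = TRUE))[seq_len(min(3L,
                                                            length(cand)))]
      report <- evaluateModel(X, y, feats, nIter = config$nIter,
                              trainFrac = config$trainFrac,
                              seed = deriveSeed(config$seed, 505L))
      results$model <- report
      emit(data.frame(feature = names(selectionFrequency(sel)),
                      frequency = selectionFrequency(sel),
                      selected = names(selectionFrequency(sel)) %in%
                        selectedFeatures(sel)),
           "bootstrap_selection.csv")
      emit(report@summary, "model_metrics.csv")
      emit(report@medianPrediction, "median_predictions.csv")
    })
  }

  writeLines(logLines, file.path(outDir, "run_log.txt"))
  manifest <- list(
    package = "imcNiche",
    schema = "imcNiche/run_manifest/v1",
    seed = config$seed,
    stages = config$stages,
    parameters = config[setdiff(names(config), "stages")],
    files = lapply(sort(files), function(f)
      list(name = f, md5 = unname(tools::md5sum(file.path(outDir, f))))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$outDir <- outDir
  invisible(results)
}
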