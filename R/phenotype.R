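#' @include AllClasses.R CellTable.R
NULL

#' The default 22-marker liver allograft panel
#'
#' Two nuclear intercalators, three structural markers (collagen, CD31 for
#' vascular endothelium, CK7 for bile ducts), immune lineage markers and
#' functional/phenotypic markers.
#'
#' @return a \linkS4class{MarkerPanel} with 22 markers.
#' @export
defaultMarkerPanel <- function() {
  new("MarkerPanel",
      markers = c("DNA1", "DNA2",
                  "Collagen1", "CD31", "CK7",
                  "CD45", "CD3", "CD4", "CD8", "CD20", "CD68", "CD11b",
                  "CD15", "CD138",
                  "PD1", "FoxP3", "Ki67", "GranzymeB", "CD16", "CD28",
                  "CD163", "HLADR"),
      role = c("nuclear", "nuclear",
               rep("structural", 3L),
               rep("lineage", 9L),
               rep("functional", 8L)))
}

#' Arcsinh-transform raw marker intensities
#'
#' Applies the standard cytometry variance-stabilizing transform
#' \eqn{x \mapsto \mathrm{asinh}(x / c)} with cofactor \eqn{c} (default 5)
#' to every marker intensity. Strictly monotone; 0 maps to 0.
#'
#' @param table a \linkS4class{CellTable} in the \code{raw} state.
#' @param cofactor positive cofactor (default 5).
#' @return the table with transformed intensities, state
#'   \code{"transformed"}.
#' @examples
#' m <- matrix(c(0, 5, 12), 1, 3, dimnames = list("CD3", NULL))
#' ct <- CellTable(m, cell_id = as.character(1:3), roi = "r", patient = "p",
#'                 group = "NR", x = 1:3, y = 0)
#' SummarizedExperiment::assay(transformIntensities(ct))  # 0, asinh(1), ln 5
#' @export
transformIntensities <- function(table, cofactor = 5) {
  stopIfNot(is(table, "CellTable"), "'table' must be a CellTable")
  stopIfNot(processingState(table) == "raw",
            "intensities are already '", processingState(table),
            "'; transform expects the raw state")
  stopIfNot(is.numeric(cofactor) && length(cofactor) == 1L && cofactor > 0,
            "'cofactor' must be a single positive number")
  a <- SummarizedExperiment::assay(table, "intensity")
  if (any(a < 0)) stop("negative raw intensities found", call. = FALSE)
  SummarizedExperiment::assay(table, "intensity") <- asinh(a / cofactor)
  table@state <- "transformed"
  validObject(table)
  table
}

#' Standardize each marker channel
#'
#' Centers and scales every channel to mean 0 and sample standard deviation
#' 1 across all cells, so that gating thresholds are comparable between
#' markers with different signal intensities. Constant channels become
#' all-zero with a warning (dropped markers and degenerate synthetic inputs
#' should not abort a run).
#'
#' @param table a \linkS4class{CellTable} in the \code{transformed} state.
#' @return the table with standardized intensities, state
#'   \code{"standardized"}.
#' @export
standardizeChannels <- function(table) {
  stopIfNot(is(table, "CellTable"), "'table' must be a CellTable")
  stopIfNot(processingState(table) == "transformed",
            "standardization expects the 'transformed' state, got '",
            processingState(table), "'")
  if (ncol(table) == 0L) stop("empty table", call. = FALSE)
  a <- SummarizedExperiment::assay(table, "intensity")
  mu <- rowMeans(a)
  sdev <- apply(a, 1L, sd)
  const <- sdev == 0 | !is.finite(sdev)
  if (any(const)) {
    warning("constant channel(s) standardized to zero: ",
            paste(rownames(a)[const], collapse = ", "), call. = FALSE)
    sdev[const] <- 1
  }
  z <- (a - mu) / sdev
  z[const, ] <- 0
  SummarizedExperiment::assay(table, "intensity") <- z
  table@state <- "standardized"
  table
}

## ---- gating predicates ----------------------------------------------------

## Parse "CD3>=0.5;CD8<0.5" into a list of terms
## list(marker=, comparator=, threshold=).
parsePredicate <- function(predicate) {
  if (is.na(predicate) || !nzchar(predicate)) return(list())
  terms <- strsplit(predicate, ";", fixed = TRUE)[[1L]]
  lapply(terms, function(tm) {
    tm <- gsub(" ", "", tm)
    m <- regmatches(tm, regexec("^([^<>=]+)(>=|<)(-?[0-9.eE+-]+)$", tm))[[1L]]
    if (length(m) != 4L)
      stop("cannot parse gating term '", tm,
           "'; expected MARKER>=THRESHOLD or MARKER<THRESHOLD",
           call. = FALSE)
    list(marker = m[2L], comparator = m[3L],
         threshold = as.numeric(m[4L]))
  })
}

## Evaluate one predicate over a cells x markers matrix -> logical vector.
evalPredicate <- function(predicate, expr) {
  terms <- parsePredicate(predicate)
  hit <- rep(TRUE, nrow(expr))
  for (tm in terms) {
    if (!tm$marker %in% colnames(expr))
      stop("gating rule references unknown marker '", tm$marker, "'",
           call. = FALSE)
    v <- expr[, tm$marker]
    hit <- hit & if (tm$comparator == ">=") v >= tm$threshold
                 else v < tm$threshold
  }
  hit
}

## ---- rulesets -------------------------------------------------------------

#' Construct a gating ruleset
#'
#' @param rules data.frame with columns \code{level}, \code{parent},
#'   \code{target}, \code{predicate}; see \linkS4class{GatingRuleSet}.
#'   Row order is the evaluation order (first match wins).
#' @param fallback metacluster label for cells matching no metacluster rule.
#' @param immune metacluster labels regarded as immune.
#' @return a \linkS4class{GatingRuleSet}.
#' @export
GatingRuleSet <- function(rules, fallback, immune = character()) {
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  rules$parent <- as.character(rules$parent)
  obj <- new("GatingRuleSet", rules = rules, fallback = fallback,
             immune = immune)
  validObject(obj)
  obj
}

#' The default study gating hierarchy
#'
#' Reconstructs the semi-supervised gating used for liver allograft IMC:
#' 10 metaclusters (7 immune, 3 parenchymal, with hepatocyte as the
#' exclusion fallback), 30 immune subclusters on the five subclustered
#' immune metaclusters (9 CD4 T-cell, 5 CD8 T-cell, 9 macrophage with an
#' initial CD163 M1/M2 split, 4 monocyte, 3 B cell) and the Ki67/HLADR
#' phenotype splits of the three parenchymal metaclusters, for 41 final
#' labels (32 immune + 9 non-immune). All thresholds are on the
#' standardized expression scale; the default positivity cut is 0.5 and
#' every threshold can be overridden in the rule file.
#'
#' @return a \linkS4class{GatingRuleSet}.
#' @examples
#' rs <- defaultGatingRules()
#' c(nMetaclusters(rs), nSubclusters(rs), nFinalLabels(rs))
#' @export
defaultGatingRules <- function() {
  M <- function(target, predicate)
    data.frame(level = "metacluster", parent = NA_character_,
               target = target, predicate = predicate)
  S <- function(parent, target, predicate)
    data.frame(level = "subcluster", parent = parent, target = target,
               predicate = predicate)
  rules <- rbind(
    ## -- metaclusters (order matters: structural lineages first, then
    ##    T cells before B/myeloid so doubly stained cells resolve by
    ##    hierarchy; hepatocyte is the fallback by exclusion)
    M("endothelial",  "CD31>=0.5"),
    M("cholangiocyte", "CK7>=0.5"),
    M("CD4 T-cell",   "CD3>=0.5;CD4>=0.5;CD8<0.5"),
    M("CD8 T-cell",   "CD3>=0.5;CD8>=0.5"),
    M("B cell",       "CD20>=0.5;CD3<0.5"),
    M("plasma cell",  "CD138>=0.5;CD3<0.5"),
    M("neutrophil",   "CD15>=0.5"),
    M("macrophage",   "CD68>=0.5"),
    M("monocyte",     "CD11b>=0.5;CD68<0.5"),
    ## -- CD4 T-cell subclusters (9)
    S("CD4 T-cell", "HLADR+ Treg",                "FoxP3>=0.5;HLADR>=0.5"),
    S("CD4 T-cell", "HLADR- Treg",                "FoxP3>=0.5"),
    S("CD4 T-cell", "PD1+CD4 T-cell",             "PD1>=0.5"),
    S("CD4 T-cell", "Proliferating CD4 T-cell",   "Ki67>=0.5"),
    S("CD4 T-cell", "Activated CD4 T-cell",       "HLADR>=0.5"),
    S("CD4 T-cell", "CD16+CD4 T-cell",            "CD16>=0.5"),
    S("CD4 T-cell", "Naive CD4 T-cell",           "CD45>=2"),
    S("CD4 T-cell", "Resident memory CD4 T-cell", "CD28>=0.5"),
    S("CD4 T-cell", "CD3+CD4+ T-cell",            ""),
    ## -- CD8 T-cell subclusters (5)
    S("CD8 T-cell", "PD1+CD28+ CD8 T-cell",       "PD1>=0.5;CD28>=0.5"),
    S("CD8 T-cell", "PD1+CD8 T-cell",             "PD1>=0.5"),
    S("CD8 T-cell", "Proliferating CD8 T-cell",   "Ki67>=0.5"),
    S("CD8 T-cell", "Cytotoxic CD8 T-cell",       "GranzymeB>=0.5"),
    S("CD8 T-cell", "CD3+CD8+ T-cell",            ""),
    ## -- macrophage subclusters (9): CD163 low = M1, CD163 high = M2
    S("macrophage", "Proliferating M1 macrophage", "CD163<0.5;Ki67>=0.5"),
    S("macrophage", "CD16+ M1 macrophage",         "CD163<0.5;CD16>=0.5"),
    S("macrophage", "CD11b+ M1 macrophage",        "CD163<0.5;CD11b>=0.5"),
    S("macrophage", "M1 macrophage",               "CD163<0.5"),
    S("macrophage", "Proliferating M2 macrophage", "CD163>=0.5;Ki67>=0.5"),
    S("macrophage", "HLADR+ M2 macrophage",        "CD163>=0.5;HLADR>=0.5"),
    S("macrophage", "CD16+ M2 macrophage",         "CD163>=0.5;CD16>=0.5"),
    S("macrophage", "CD11b+ M2 macrophage",        "CD163>=0.5;CD11b>=0.5"),
    S("macrophage", "M2 macrophage",               "CD163>=0.5"),
    ## -- monocyte subclusters (4)
    S("monocyte", "Intermediate monocyte",  "CD16>=0.5;HLADR>=0.5"),
    S("monocyte", "Activated monocyte",     "HLADR>=0.5"),
    S("monocyte", "Classical monocyte",     "CD16>=0.5"),
    S("monocyte", "Non-classical monocyte", ""),
    ## -- B cell subclusters (3)
    S("B cell", "Proliferating B cell", "Ki67>=0.5"),
    S("B cell", "CD11b+ B cell",        "CD11b>=0.5"),
    S("B cell", "CD20+ B cell",         ""),
    ## -- parenchymal phenotype splits (9 non-immune final labels)
    S("hepatocyte",    "Proliferating hepatocyte",    "Ki67>=0.5"),
    S("hepatocyte",    "HLADR+ hepatocyte",           "HLADR>=0.5"),
    S("hepatocyte",    "Hepatocyte",                  ""),
    S("cholangiocyte", "Proliferating cholangiocyte", "Ki67>=0.5"),
    S("cholangiocyte", "HLADR+ cholangiocyte",        "HLADR>=0.5"),
    S("cholangiocyte", "Cholangiocyte",               ""),
    S("endothelial",   "Proliferating endothelial",   "Ki67>=0.5"),
    S("endothelial",   "HLADR+ endothelial",          "HLADR>=0.5"),
    S("endothelial",   "Endothelial",                 ""))
  GatingRuleSet(rules, fallback = "hepatocyte",
                immune = c("CD4 T-cell", "CD8 T-cell", "B cell",
                           "plasma cell", "neutrophil", "macrophage",
                           "monocyte"))
}

## Generic within-parent label for subclustered parents whose rules do not
## cover a cell (e.g. "CD3+CD8+ T-cells" within the CD8 metacluster).
genericSubLabel <- function(parent) {
  switch(parent,
         "CD4 T-cell" = "CD3+CD4+ T-cell",
         "CD8 T-cell" = "CD3+CD8+ T-cell",
         paste0(parent, " (other)"))
}

#' Label accounting of a ruleset
#'
#' @param rules a \linkS4class{GatingRuleSet}.
#' @return list with the number of metaclusters, immune subclusters, final
#'   labels, and the immune / non-immune split of the final labels.
#' @export
labelAccounting <- function(rules) {
  fin <- finalLabels(rules)
  sub <- rules@rules[rules@rules$level == "subcluster", , drop = FALSE]
  parent_of <- setNames(sub$parent, sub$target)
  meta <- c(rules@rules$target[rules@rules$level == "metacluster"],
            rules@fallback)
  immune_fin <- vapply(fin, function(l) {
    p <- if (l %in% names(parent_of)) parent_of[[l]] else l
    p %in% rules@immune
  }, logical(1))
  list(n_metaclusters = nMetaclusters(rules),
       n_subclusters = nSubclusters(rules),
       n_final = length(fin),
       n_immune_final = sum(immune_fin),
       n_nonimmune_final = sum(!immune_fin))
}

## ---- label assignment -----------------------------------------------------

#' Assign metacluster labels by hierarchical gating
#'
#' Evaluates the metacluster rules in file order over the standardized
#' expression matrix; the first rule whose predicate holds assigns the
#' label and cells matching no rule receive the fallback (classification
#' by exclusion, hepatocyte in the default ruleset). Fully deterministic.
#'
#' @param table a \linkS4class{CellTable} in the \code{standardized} state.
#' @param rules a \linkS4class{GatingRuleSet}.
#' @return a \linkS4class{PhenotypeAssignment} with metacluster labels set
#'   and subcluster labels \code{NA}.
#' @export
assignMetaclusters <- function(table, rules) {
  stopIfNot(is(table, "CellTable"), "'table' must be a CellTable")
  stopIfNot(is(rules, "GatingRuleSet"), "'rules' must be a GatingRuleSet")
  stopIfNot(processingState(table) == "standardized",
            "gating expects standardized intensities")
  expr <- exprMatrix(table)
  mr <- rules@rules[rules@rules$level == "metacluster", , drop = FALSE]
  ruleMarkers <- unique(unlist(lapply(
    rules@rules$predicate, function(p)
      vapply(parsePredicate(p), `[[`, character(1), "marker"))))
  missing <- setdiff(ruleMarkers, colnames(expr))
  if (length(missing))
    stop("ruleset references marker(s) absent from the panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  lab <- rep(NA_character_, nrow(expr))
  for (i in seq_len(nrow(mr))) {
    hit <- is.na(lab) & evalPredicate(mr$predicate[i], expr)
    lab[hit] <- mr$target[i]
  }
  lab[is.na(lab)] <- rules@fallback
  cd <- cellData(table)
  new("PhenotypeAssignment",
      assignment = data.frame(roi = cd$roi, cell_id = cd$cell_id,
                              metacluster = lab,
                              subcluster = NA_character_,
                              final = lab,
                              stringsAsFactors = FALSE))
}

#' Refine metaclusters into subclusters
#'
#' Subcluster rules are evaluated first-match-wins, each only on cells of
#' its parent metacluster. Cells of a subclustered parent matching no rule
#' keep a parent-level generic label (e.g. \code{"CD3+CD8+ T-cell"});
#' cells of parents without subcluster rules keep their metacluster as the
#' final label. In the default ruleset the macrophage rules realise the
#' study's two-step scheme (first a CD163 M1/M2 split, then the remaining
#' markers within each branch) through branch-conditioned predicates.
#'
#' @param table a standardized \linkS4class{CellTable}.
#' @param assignment a \linkS4class{PhenotypeAssignment} with metaclusters
#'   assigned.
#' @param rules a \linkS4class{GatingRuleSet}.
#' @return the updated \linkS4class{PhenotypeAssignment}.
#' @export
assignSubclusters <- function(table, assignment, rules) {
  stopIfNot(is(assignment, "PhenotypeAssignment"),
            "'assignment' must be a PhenotypeAssignment")
  a <- assignment@assignment
  stopIfNot(nrow(a) == ncol(table),
            "assignment does not cover the table (row count mismatch)")
  expr <- exprMatrix(table)
  sub <- rules@rules[rules@rules$level == "subcluster", , drop = FALSE]
  for (parent in unique(sub$parent)) {
    inParent <- a$metacluster == parent
    if (!any(inParent)) next
    pr <- sub[sub$parent == parent, , drop = FALSE]
    lab <- rep(NA_character_, sum(inParent))
    pe <- expr[inParent, , drop = FALSE]
    for (i in seq_len(nrow(pr))) {
      hit <- is.na(lab) & evalPredicate(pr$predicate[i], pe)
      lab[hit] <- pr$target[i]
    }
    lab[is.na(lab)] <- genericSubLabel(parent)
    a$subcluster[inParent] <- lab
  }
  a$final <- ifelse(is.na(a$subcluster), a$metacluster, a$subcluster)
  new("PhenotypeAssignment", assignment = a)
}

#' One-call gating: metaclusters then subclusters
#'
#' @inheritParams assignSubclusters
#' @return a \linkS4class{PhenotypeAssignment}.
#' @export
assignPhenotypes <- function(table, rules) {
  assignSubclusters(table, assignMetaclusters(table, rules), rules)
}

## ---- proportions ----------------------------------------------------------

#' Per-patient cell-type proportions
#'
#' Pools each patient's cells across that patient's ROIs and computes label
#' proportions, either over the patient's total cell count
#' (\code{denominator = "all_cells"}, used for metacluster and final-label
#' proportions) or over the parent metacluster's cell count
#' (\code{denominator = "parent_metacluster"}, used for subcluster
#' fractions such as percent of the CD8 T-cell population). Patients with
#' zero cells in a parent metacluster yield \code{NA} (missing, not zero).
#'
#' @param assignment a \linkS4class{PhenotypeAssignment}.
#' @param table the matching \linkS4class{CellTable}.
#' @param level which labels to tabulate: \code{"metacluster"},
#'   \code{"final"} or \code{"subcluster"}.
#' @param denominator \code{"all_cells"} or \code{"parent_metacluster"}.
#' @return a data.frame with columns \code{patient}, \code{group},
#'   \code{label}, \code{proportion} and \code{denominator}; proportions
#'   over a shared denominator sum to 1 per patient.
#' @export
computeProportions <- function(assignment, table,
                               level = c("metacluster", "final",
                                         "subcluster"),
                               denominator = c("all_cells",
                                               "parent_metacluster")) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  a <- assignment@assignment
  cd <- cellData(table)
  stopIfNot(nrow(a) == nrow(cd), "assignment does not cover all cells")
  lab <- switch(level, metacluster = a$metacluster, final = a$final,
                subcluster = a$subcluster)
  pg <- unique(data.frame(patient = cd$patient, group = cd$group,
                          stringsAsFactors = FALSE))
  labs <- sort(unique(lab[!is.na(lab)]))
  out <- vector("list", nrow(pg))
  for (i in seq_len(nrow(pg))) {
    sel <- cd$patient == pg$patient[i]
    li <- lab[sel]
    if (denominator == "all_cells") {
      counts <- base::table(factor(li, levels = labs))
      keep <- !is.na(li)
      prop <- as.numeric(counts) / sum(keep)
    } else {
      parent <- a$metacluster[sel]
      prop <- vapply(labs, function(l) {
        p <- unique(a$metacluster[!is.na(lab) & lab == l])
        if (length(p) != 1L) return(NA_real_)
        den <- sum(parent == p)
        if (den == 0L) return(NA_real_)
        sum(li == l, na.rm = TRUE) / den
      }, numeric(1))
    }
    out[[i]] <- data.frame(patient = pg$patient[i], group = pg$group[i],
                           label = labs, proportion = prop,
                           denominator = denominator,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## ---- rule file round-trip -------------------------------------------------

GATING_SCHEMA <- "imcNiche/gating_rules/v1"

#' Read and write gating-rule files
#'
#' Delimited text, one rule per line (\code{level}, \code{parent},
#' \code{target}, semicolon-joined predicate terms), with the fallback and
#' immune metaclusters declared in header comment lines. Round-trippable:
#' \code{readGatingRules(writeGatingRules(x, f))} reproduces \code{x}.
#'
#' @param rules a \linkS4class{GatingRuleSet}.
#' @param path file path.
#' @return \code{readGatingRules} returns a \linkS4class{GatingRuleSet};
#'   \code{writeGatingRules} returns \code{path} invisibly.
#' @export
writeGatingRules <- function(rules, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# schema=", GATING_SCHEMA),
               paste0("# fallback=", rules@fallback),
               paste0("# immune=", paste(rules@immune, collapse = ";"))),
             con)
  r <- rules@rules
  r$parent[is.na(r$parent)] <- ""
  r$predicate[is.na(r$predicate)] <- ""
  write.csv(r, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeGatingRules
#' @export
readGatingRules <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  schema <- sub("^# schema=", "", grep("^# schema=", hdr, value = TRUE))
  if (length(schema) != 1L || schema != GATING_SCHEMA)
    stop("unsupported gating rule file schema: ",
         if (length(schema)) schema else "(none)", call. = FALSE)
  fallback <- sub("^# fallback=", "", grep("^# fallback=", hdr, value = TRUE))
  immune <- sub("^# immune=", "", grep("^# immune=", hdr, value = TRUE))
  immune <- if (nzchar(immune)) strsplit(immune, ";", fixed = TRUE)[[1L]]
            else character()
  body <- lines[!grepl("^#", lines)]
  r <- read.csv(text = paste(body, collapse = "\n"),
                stringsAsFactors = FALSE,
                colClasses = c(level = "character", parent = "character",
                               target = "character",
                               predicate = "character"))
  r$parent[r$parent == ""] <- NA_character_
  r$predicate[is.na(r$predicate)] <- ""
  GatingRuleSet(r, fallback = fallback, immune = immune)
}
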