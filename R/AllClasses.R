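#' @include AllGenerics.R utils.R symbols.R
NULL

#' Reference interactome
#'
#' An undirected, simple edge universe over gene symbols: no self-loops, no
#' duplicate unordered pairs. Interaction-type labels (e.g. SIF relations)
#' are preserved for display only; every topology computation treats the
#' graph as undirected and unlabelled.
#'
#' @slot edges `data.frame` with columns `from`, `to` (lexicographically
#'   ordered within each row) and `type`.
#' @param edges `data.frame` with at least two character columns (endpoints);
#'   an optional third column is kept as the interaction-type label.
#' @return `Interactome()` returns an `Interactome` object;
#'   `interactomeGenes()` the sorted node symbols; `interactomeEdges()` the
#'   edge `data.frame`.
#' @examples
#' ia <- Interactome(data.frame(from = c("a", "B"), to = c("B", "C")))
#' interactomeGenes(ia)
#' @aliases interactomeGenes interactomeEdges
#' @export Interactome
#' @exportClass Interactome
Interactome <- setClass("Interactome", representation(edges = "data.frame"))

setValidity("Interactome", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "type") %in% names(e)))
    return("edges must have columns from, to, type")
  if (any(e$from == e$to)) return("self-loops are not allowed")
  if (any(e$from > e$to)) return("edge endpoints must be row-wise sorted")
  if (anyDuplicated(paste(e$from, e$to))) return("duplicate unordered pairs")
  TRUE
})

#' @rdname Interactome-class
setMethod("initialize", "Interactome", function(.Object, edges = NULL, ...) {
  if (is.null(edges)) edges <- data.frame(from = character(0), to = character(0),
                                          type = character(0))
  if (ncol(edges) < 2) stopf("edge table needs at least two columns")
  from <- normalizeGeneSymbols(as.character(edges[[1]]))
  to <- normalizeGeneSymbols(as.character(edges[[2]]))
  type <- if (ncol(edges) >= 3 && !identical(names(edges)[3], "")) {
    as.character(edges[[3]])
  } else rep(NA_character_, length(from))
  loop <- from == to
  if (any(loop)) {
    msgf("dropped %d self-loop(s)", sum(loop))
    from <- from[!loop]; to <- to[!loop]; type <- type[!loop]
  }
  p <- sortedPairs(from, to)
  key <- paste(p$a, p$b)
  keep <- !duplicated(key)
  nd <- sum(!keep)
  if (nd > 0) msgf("collapsed %d duplicate unordered pair(s)", nd)
  e <- data.frame(from = p$a[keep], to = p$b[keep], type = type[keep],
                  stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  .Object@edges <- e
  validObject(.Object)
  .Object
})

setMethod("interactomeGenes", "Interactome", function(x)
  sort(unique(c(x@edges$from, x@edges$to))))

setMethod("interactomeEdges", "Interactome", function(x) x@edges)

setMethod("show", "Interactome", function(object) {
  cat(sprintf("Interactome: %d genes, %d edges\n",
              length(interactomeGenes(object)), nrow(object@edges)))
})

#' Disease gene network
#'
#' The combined disease network: seed genes (roles `DEG`, `QTL`) plus linker
#' genes (role `LINKER`), with the interactome edges induced on that node
#' set. Seed genes without any interactome edge are retained as degree-0
#' nodes; linkers by construction always have degree > 0.
#'
#' @slot nodes `data.frame` with columns `gene`, `role`.
#' @slot edges `data.frame` with columns `from`, `to`, `type`.
#' @param nodes,edges See slots.
#' @return `networkGenes()`: sorted node symbols; `nodeRoles()`: named
#'   character vector of roles; `networkEdges()`: the edge table;
#'   `isolatedSeeds()`: degree-0 seed genes, sorted.
#' @seealso [assembleNetwork]
#' @aliases networkGenes networkEdges nodeRoles isolatedSeeds
#' @export GeneNetwork
#' @exportClass GeneNetwork
GeneNetwork <- setClass("GeneNetwork",
                        representation(nodes = "data.frame", edges = "data.frame"))

setValidity("GeneNetwork", function(object) {
  n <- object@nodes; e <- object@edges
  if (!all(c("gene", "role") %in% names(n))) return("nodes need gene, role")
  if (!all(n$role %in% c("DEG", "QTL", "LINKER"))) return("unknown role")
  if (anyDuplicated(n$gene)) return("duplicate node gene")
  ends <- c(e$from, e$to)
  if (!all(ends %in% n$gene)) return("edge endpoint not in node set")
  if (any(e$from == e$to)) return("self-loops are not allowed")
  if (anyDuplicated(paste(e$from, e$to))) return("duplicate edges")
  deg <- table(factor(ends, levels = n$gene))
  if (any(n$role == "LINKER" & deg == 0))
    return("linker gene with degree 0")
  TRUE
})

setMethod("networkGenes", "GeneNetwork", function(x) sort(x@nodes$gene))

setMethod("nodeRoles", "GeneNetwork", function(x)
  setNames(x@nodes$role, x@nodes$gene))

setMethod("networkEdges", "GeneNetwork", function(x) x@edges)

setMethod("isolatedSeeds", "GeneNetwork", function(x) {
  deg <- table(factor(c(x@edges$from, x@edges$to), levels = x@nodes$gene))
  sort(x@nodes$gene[deg == 0 & x@nodes$role %in% c("DEG", "QTL")])
})

setMethod("show", "GeneNetwork", function(object) {
  r <- table(object@nodes$role)
  cat(sprintf("GeneNetwork: %d genes (%s), %d edges, %d isolated seed(s)\n",
              nrow(object@nodes),
              paste(sprintf("%s=%d", names(r), as.integer(r)), collapse = ", "),
              nrow(object@edges), length(isolatedSeeds(object))))
})

#' Annotation gene-set collection
#'
#' Named gene sets grouped under one functional category (e.g. one pathway
#' database), the substrate for over-representation analysis. Set names are
#' unique within the category and every set is non-empty.
#'
#' @slot category Single character label.
#' @slot sets Named list of character vectors (member gene symbols).
#' @param category,sets See slots.
#' @aliases annotationCategory geneSets
#' @export AnnotationCollection
#' @exportClass AnnotationCollection
AnnotationCollection <- setClass("AnnotationCollection",
                                 representation(category = "character", sets = "list"))

setValidity("AnnotationCollection", function(object) {
  if (length(object@category) != 1 || is.na(object@category))
    return("category must be a single label")
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || any(names(s) == "")) return("sets must be named")
    if (anyDuplicated(names(s))) return("duplicate set names within category")
    if (any(!lengths(s))) return("empty gene set")
  }
  TRUE
})

setMethod("initialize", "AnnotationCollection",
          function(.Object, category = "collection", sets = list(), ...) {
  .Object@category <- as.character(category)
  .Object@sets <- lapply(sets, function(g) sort(unique(normalizeGeneSymbols(g))))
  validObject(.Object)
  .Object
})

setMethod("annotationCategory", "AnnotationCollection", function(x) x@category)
setMethod("geneSets", "AnnotationCollection", function(x) x@sets)

setMethod("show", "AnnotationCollection", function(object) {
  cat(sprintf("AnnotationCollection '%s': %d sets (sizes %s)\n",
              object@category, length(object@sets),
              if (length(object@sets))
                paste(range(lengths(object@sets)), collapse = "-") else "-"))
})

#' Drug-gene effect table
#'
#' Rows of (drug, gene, kind, direction) where `kind` is `TARGET` (physical
#' drug target) or `EXPRESSION_EFFECT` (pharmaco-transcriptomic effect) and
#' `direction` is `INCREASE`, `DECREASE` or `UNKNOWN`. The (drug, gene, kind)
#' triple is unique; conflicting expression directions for the same triple
#' are collapsed to `UNKNOWN` (logged), since an unclear direction must never
#' count as a reversal.
#'
#' @slot rows `data.frame` with columns `drug`, `gene`, `kind`, `direction`.
#' @param rows See slot; free-text direction vocabulary is normalized via an
#'   internal dictionary (e.g. "up-regulates" -> `INCREASE`).
#' @aliases drugEffects
#' @export DrugEffectTable
#' @exportClass DrugEffectTable
DrugEffectTable <- setClass("DrugEffectTable", representation(rows = "data.frame"))

.directionDictionary <- c(
  increase = "INCREASE", increases = "INCREASE", increased = "INCREASE",
  up = "INCREASE", upregulate = "INCREASE", upregulates = "INCREASE",
  upregulated = "INCREASE", "up-regulates" = "INCREASE", induce = "INCREASE",
  induces = "INCREASE", activates = "INCREASE",
  decrease = "DECREASE", decreases = "DECREASE", decreased = "DECREASE",
  down = "DECREASE", downregulate = "DECREASE", downregulates = "DECREASE",
  downregulated = "DECREASE", "down-regulates" = "DECREASE",
  represses = "DECREASE", inhibits = "DECREASE",
  unknown = "UNKNOWN", unclear = "UNKNOWN", na = "UNKNOWN")

normalizeEffectDirection <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "unknown"
  out <- .directionDictionary[x]
  if (anyNA(out)) {
    stopf("unknown effect direction token(s): %s",
          paste(unique(x[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

setValidity("DrugEffectTable", function(object) {
  r <- object@rows
  if (!all(c("drug", "gene", "kind", "direction") %in% names(r)))
    return("rows need drug, gene, kind, direction")
  if (!all(r$kind %in% c("TARGET", "EXPRESSION_EFFECT"))) return("unknown kind")
  if (!all(r$direction %in% c("INCREASE", "DECREASE", "UNKNOWN")))
    return("unknown direction")
  if (anyDuplicated(paste(r$drug, r$gene, r$kind)))
    return("(drug, gene, kind) must be unique")
  TRUE
})

setMethod("initialize", "DrugEffectTable", function(.Object, rows = NULL, ...) {
  if (is.null(rows))
    rows <- data.frame(drug = character(0), gene = character(0),
                       kind = character(0), direction = character(0))
  kind <- toupper(trimws(as.character(rows$kind)))
  kind[kind %in% c("EXPRESSION", "EFFECT")] <- "EXPRESSION_EFFECT"
  r <- data.frame(drug = trimws(as.character(rows$drug)),
                  gene = normalizeGeneSymbols(as.character(rows$gene)),
                  kind = kind,
                  direction = normalizeEffectDirection(rows$direction),
                  stringsAsFactors = FALSE)
  key <- paste(r$drug, r$gene, r$kind)
  if (anyDuplicated(key)) {
    conflict <- tapply(r$direction, key, function(d) length(unique(d)) > 1)
    ncf <- sum(conflict)
    if (ncf > 0)
      msgf("%d (drug, gene, kind) conflict(s) collapsed to UNKNOWN", ncf)
    first <- !duplicated(key)
    dir <- r$direction[first]
    dir[conflict[key[first]]] <- "UNKNOWN"
    r <- r[first, , drop = FALSE]
    r$direction <- dir
  }
  r <- r[order(r$drug, r$gene, r$kind), , drop = FALSE]
  rownames(r) <- NULL
  .Object@rows <- r
  validObject(.Object)
  .Object
})

setMethod("drugEffects", "DrugEffectTable", function(x) x@rows)

setMethod("show", "DrugEffectTable", function(object) {
  r <- object@rows
  cat(sprintf("DrugEffectTable: %d rows, %d drugs (%d TARGET, %d EXPRESSION_EFFECT)\n",
              nrow(r), length(unique(r$drug)), sum(r$kind == "TARGET"),
              sum(r$kind == "EXPRESSION_EFFECT")))
})

#' Linker search result
#'
#' Output of [findLinkers]: the chosen linker genes, the number of seed
#' components before/after linking, and the seeds absent from the
#' interactome altogether.
#'
#' @slot linkers Character vector of linker genes (disjoint from seeds).
#' @slot componentsBefore,componentsAfter Seed-component counts.
#' @slot isolatedSeeds Seeds with no interactome edges at all.
#' @export
#' @exportClass LinkerSearchResult
LinkerSearchResult <- setClass("LinkerSearchResult",
  representation(linkers = "character", componentsBefore = "integer",
                 componentsAfter = "integer", isolatedSeeds = "character"))

setMethod("show", "LinkerSearchResult", function(object) {
  cat(sprintf("LinkerSearchResult: %d linker(s), seed components %d -> %d, %d isolated seed(s)\n",
              length(object@linkers), object@componentsBefore,
              object@componentsAfter, length(object@isolatedSeeds)))
})

#' Centrality report
#'
#' Exact degree and unnormalized shortest-path betweenness for every node,
#' and betweenness for every edge, of a disease network. Values are raw
#' pair counts on the undirected simple graph; disconnected components are
#' handled independently and isolated nodes get betweenness 0.
#'
#' @slot nodes `data.frame`: `gene`, `role`, `degree`, `betweenness`.
#' @slot edges `data.frame`: `from`, `to`, `betweenness`.
#' @seealso [computeCentralities], [flagHubs]
#' @export
#' @exportClass CentralityReport
CentralityReport <- setClass("CentralityReport",
  representation(nodes = "data.frame", edges = "data.frame"))

setMethod("show", "CentralityReport", function(object) {
  cat(sprintf("CentralityReport: %d nodes, %d edges; max degree %d, max node betweenness %.4g\n",
              nrow(object@nodes), nrow(object@edges),
              max(object@nodes$degree), max(object@nodes$betweenness)))
})

#' Module assignment
#'
#' A partition of the network into functional modules with its Newman
#' modularity Q. Module ids are contiguous 0-based integers; isolated nodes
#' share one dedicated module.
#'
#' @slot assignment Named integer vector, gene -> module id.
#' @slot modularityQ Newman modularity of the partition.
#' @slot nModules Number of distinct modules.
#' @aliases moduleMembership
#' @seealso [spectralPartition], [modularityQ]
#' @export
#' @exportClass ModuleAssignment
ModuleAssignment <- setClass("ModuleAssignment",
  representation(assignment = "integer", modularityQ = "numeric",
                 nModules = "integer"))

setValidity("ModuleAssignment", function(object) {
  a <- object@assignment
  if (is.null(names(a))) return("assignment must be named by gene")
  ids <- sort(unique(a))
  if (length(ids) && !identical(ids, seq_along(ids) - 1L))
    return("module ids must be contiguous from 0")
  if (object@nModules != length(ids)) return("nModules inconsistent")
  TRUE
})

setMethod("moduleMembership", "ModuleAssignment", function(x) x@assignment)

setMethod("show", "ModuleAssignment", function(object) {
  sz <- sort(table(object@assignment), decreasing = TRUE)
  cat(sprintf("ModuleAssignment: %d modules (sizes %s), Q = %.4f\n",
              object@nModules, paste(as.integer(sz), collapse = ", "),
              object@modularityQ))
})

#' Drug ranking rubric configuration
#'
#' The bonus/penalty point values of the ranking rubric, the pricing switch,
#' and the annual-cost band boundaries (EUR/year). All criterion points live
#' here so the rubric is data, not code; the defaults reproduce the published
#' rubric exactly (see [rubricConfig]).
#'
#' @slot points Named integer-valued vector of criterion points.
#' @slot pricingEnabled Logical; `FALSE` zeroes every pricing criterion.
#' @slot bands Named numeric: `veryLowMax`, `lowMax`, `veryHighMin`.
#' @export
#' @exportClass RubricConfig
RubricConfig <- setClass("RubricConfig",
  representation(points = "numeric", pricingEnabled = "logical",
                 bands = "numeric"))

setValidity("RubricConfig", function(object) {
  need <- c("immunomod_general", "immunomod_skin", "network_targets",
            "topical", "who_essential", "price_low", "price_very_low",
            "no_atc", "not_orderable", "unclear_direction", "grade3to5_ae",
            "practical_issue", "severe_practical_issue", "price_penalty")
  if (!all(need %in% names(object@points))) return("missing criterion points")
  if (any(object@points != round(object@points)))
    return("criterion points must be integers")
  b <- object@bands
  if (!all(c("veryLowMax", "lowMax", "veryHighMin") %in% names(b)))
    return("bands need veryLowMax, lowMax, veryHighMin")
  if (!(b["veryLowMax"] < b["lowMax"] && b["lowMax"] < b["veryHighMin"]))
    return("price bands must be ordered")
  TRUE
})

setMethod("show", "RubricConfig", function(object) {
  cat(sprintf("RubricConfig: %d criteria, pricing %s\n",
              length(object@points),
              if (object@pricingEnabled) "enabled" else "disabled"))
})

#' Per-drug score breakdown
#'
#' The applied rubric criteria with their points, and the resulting total,
#' for one drug. The total always equals the sum of the applied points.
#'
#' @slot drug Drug label.
#' @slot applied `data.frame` with columns `criterion`, `points`.
#' @slot total Integer-valued total score.
#' @aliases scoreTotal scoreApplied
#' @seealso [scoreDrug]
#' @export
#' @exportClass ScoreBreakdown
ScoreBreakdown <- setClass("ScoreBreakdown",
  representation(drug = "character", applied = "data.frame", total = "numeric"))

setValidity("ScoreBreakdown", function(object) {
  if (!isTRUE(all.equal(object@total, sum(object@applied$points))))
    return("total must equal the sum of applied points")
  TRUE
})

setMethod("scoreTotal", "ScoreBreakdown", function(x) x@total)
setMethod("scoreApplied", "ScoreBreakdown", function(x) x@applied)

setMethod("show", "ScoreBreakdown", function(object) {
  cat(sprintf("ScoreBreakdown for '%s': total %+d\n", object@drug,
              as.integer(object@total)))
  if (nrow(object@applied)) {
    for (i in seq_len(nrow(object@applied)))
      cat(sprintf("  %+d  %s\n", as.integer(object@applied$points[i]),
                  object@applied$criterion[i]))
  } else cat("  (no criteria applied)\n")
})

#' Ranked candidate list
#'
#' Drugs ordered by total rubric score (descending, ties by name), the
#' per-drug breakdowns, and the shortlist of drugs with a strictly positive
#' total.
#'
#' @slot breakdowns Named list of [ScoreBreakdown-class] objects.
#' @slot table `data.frame` with columns `drug`, `total`, ordered.
#' @slot shortlist Character vector of drugs with `total > 0`.
#' @seealso [rankDrugs]
#' @export
#' @exportClass RankedList
RankedList <- setClass("RankedList",
  representation(breakdowns = "list", table = "data.frame",
                 shortlist = "character"))

setMethod("show", "RankedList", function(object) {
  cat(sprintf("RankedList: %d drugs ranked, %d on shortlist (score > 0)\n",
              nrow(object@table), length(object@shortlist)))
  print(utils::head(object@table, 10), row.names = FALSE)
})

# igraph view of an Interactome or GeneNetwork (undirected, simple); for a
# GeneNetwork, isolated nodes are included as degree-0 vertices.
asIgraph <- function(x) {
  if (is(x, "Interactome")) {
    igraph::graph_from_data_frame(x@edges[, c("from", "to")], directed = FALSE)
  } else if (is(x, "GeneNetwork")) {
    igraph::graph_from_data_frame(x@edges[, c("from", "to")], directed = FALSE,
                                  vertices = data.frame(name = x@nodes$gene))
  } else stopf("cannot convert %s to igraph", class(x)[1])
}
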