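#' Seeds with no interactome coverage
#'
#' Returns the seed genes absent from the interactome node set (no functional
#' interaction data at all), sorted lexicographically. These are retained in
#' the assembled network as degree-0 nodes but excluded from connectivity
#' targets.
#'
#' @param seeds Seed table from [makeSeeds] or a character vector of symbols.
#' @param interactome An [Interactome-class].
#' @return Sorted character vector.
#' @export
identifyIsolatedSeeds <- function(seeds, interactome) {
  genes <- if (is.data.frame(seeds)) seeds$gene else normalizeGeneSymbols(seeds)
  if (!length(genes)) stopf("seeds must be non-empty")
  sort(setdiff(genes, interactomeGenes(interactome)))
}

# Components of the subgraph induced on seeds+linkers. `membership` covers
# all subgraph vertices; `n` counts only components containing >= 1 seed,
# and `seedComps` is the id set of those components.
.seedComponents <- function(g, seedsIn, linkers) {
  sub <- igraph::induced_subgraph(g, c(seedsIn, linkers))
  memb <- igraph::components(sub)$membership
  seedComps <- unique(memb[seedsIn])
  list(n = length(seedComps), membership = memb, seedComps = seedComps)
}

#' Find a minimal set of linker genes connecting the seeds
#'
#' Greedy Steiner-tree-style approximation: repeatedly add the non-seed
#' interactome gene that joins the largest number of currently distinct seed
#' components (ties: smaller interactome degree first, then lexicographic).
#' When no single gene joins two components but the interactome still
#' connects them, the lexicographically smallest shortest interactome path
#' between the two closest seed components is added instead. Finally,
#' linkers whose removal leaves connectivity unchanged are pruned, so the
#' chosen set is setwise-minimal under the greedy order.
#'
#' @param seeds Seed table from [makeSeeds] or character vector.
#' @param interactome An [Interactome-class] with at least one edge.
#' @param maxPathLen Candidate linkers are restricted to genes within this
#'   interactome distance of at least two seeds (default 3), for
#'   tractability.
#' @return A [LinkerSearchResult-class].
#' @export
findLinkers <- function(seeds, interactome, maxPathLen = 3) {
  genes <- if (is.data.frame(seeds)) seeds$gene else normalizeGeneSymbols(seeds)
  genes <- unique(genes)
  if (!length(genes)) stopf("seeds must be non-empty")
  if (!nrow(interactomeEdges(interactome))) stopf("interactome is empty")
  g <- asIgraph(interactome)
  nodes <- igraph::V(g)$name
  isolated <- sort(setdiff(genes, nodes))
  seedsIn <- sort(intersect(genes, nodes))

  emptyRes <- function(before, after, linkers = character(0))
    LinkerSearchResult(linkers = linkers,
                       componentsBefore = as.integer(before),
                       componentsAfter = as.integer(after),
                       isolatedSeeds = isolated)
  if (length(seedsIn) <= 1)
    return(emptyRes(length(seedsIn), length(seedsIn)))

  before <- .seedComponents(g, seedsIn, character(0))$n
  # seeds may span several components of the full interactome; that many
  # components is the best achievable
  fullMemb <- igraph::components(g)$membership[seedsIn]
  target <- length(unique(fullMemb))

  cand <- setdiff(nodes, genes)
  if (length(cand)) {
    d <- igraph::distances(g, v = cand, to = seedsIn)
    cand <- cand[rowSums(d <= maxPathLen) >= 2]
  }
  candDegree <- igraph::degree(g, v = cand)

  chosen <- character(0)
  state <- .seedComponents(g, seedsIn, chosen)
  while (state$n > target) {
    avail <- setdiff(cand, chosen)
    joins <- vapply(avail, function(cc) {
      nb <- igraph::neighbors(g, cc)$name
      touched <- unique(state$membership[intersect(nb, c(seedsIn, chosen))])
      touched <- intersect(touched, state$seedComps)
      max(0L, length(touched) - 1L)
    }, integer(1))
    if (!length(joins)) joins <- integer(0)
    if (length(avail) && max(joins) > 0) {
      best <- avail[joins == max(joins)]
      best <- best[order(candDegree[best], best)][1]
      chosen <- c(chosen, best)
    } else {
      # no single candidate joins two components; bridge the closest pair of
      # seed components through a shortest interactome path
      memb <- state$membership
      comps <- split(names(memb), memb)
      comps <- comps[as.character(state$seedComps)]
      if (length(comps) < 2) break
      reps <- vapply(comps, function(x) sort(x)[1], character(1))
      dd <- igraph::distances(g, v = reps, to = reps)
      diag(dd) <- Inf
      dd[!is.finite(dd)] <- Inf
      if (!any(is.finite(dd))) break
      idx <- which(dd == min(dd), arr.ind = TRUE)
      ord <- order(rownames(dd)[idx[, 1]], colnames(dd)[idx[, 2]])
      i <- idx[ord[1], 1]; j <- idx[ord[1], 2]
      paths <- igraph::all_shortest_paths(g, from = reps[i], to = reps[j])$res
      mids <- lapply(paths, function(p) setdiff(igraph::as_ids(p), genes))
      keys <- vapply(mids, function(m) paste(sort(m), collapse = "|"), character(1))
      add <- mids[[order(keys)[1]]]
      if (!length(add)) break
      chosen <- c(chosen, setdiff(add, chosen))
    }
    state <- .seedComponents(g, seedsIn, chosen)
  }

  # prune: drop any linker whose removal leaves the seed-component count
  # unchanged and strands no other linker
  final <- state$n
  repeat {
    dropped <- FALSE
    for (l in rev(chosen)) {
      keep <- setdiff(chosen, l)
      st <- .seedComponents(g, seedsIn, keep)
      if (st$n != final) next
      if (length(keep)) {
        sub <- igraph::induced_subgraph(g, c(seedsIn, keep))
        if (any(igraph::degree(sub, v = keep) == 0)) next
      }
      chosen <- keep
      dropped <- TRUE
      break
    }
    if (!dropped) break
  }

  emptyRes(before, .seedComponents(g, seedsIn, chosen)$n, sort(chosen))
}

#' Assemble the combined disease network
#'
#' Node set = seeds plus linkers (disjoint); edge set = the interactome edges
#' induced on that node set. Seeds absent from the interactome are retained
#' as degree-0 nodes with their seed role.
#'
#' @param seeds Seed table from [makeSeeds] (columns `gene`, `origin`).
#' @param linkers Character vector of linker genes, disjoint from seeds.
#' @param interactome An [Interactome-class].
#' @return A [GeneNetwork-class] with roles `DEG`/`QTL`/`LINKER`.
#' @examples
#' ia <- Interactome(data.frame(from = c("A", "L", "A"),
#'                              to = c("L", "B", "B")))
#' assembleNetwork(makeSeeds(c("A", "B")), "L", ia)
#' @export
assembleNetwork <- function(seeds, linkers, interactome) {
  if (!is.data.frame(seeds) || !all(c("gene", "origin") %in% names(seeds)))
    seeds <- makeSeeds(seeds)
  linkers <- if (length(linkers)) unique(normalizeGeneSymbols(linkers)) else character(0)
  clash <- intersect(linkers, seeds$gene)
  if (length(clash))
    stopf("role conflict: gene(s) both seed and linker: %s",
          paste(clash, collapse = ", "))
  nodes <- data.frame(
    gene = c(seeds$gene, linkers),
    role = c(ifelse(seeds$origin == "QTL", "QTL", "DEG"),
             rep("LINKER", length(linkers))),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  e <- interactomeEdges(interactome)
  keep <- e$from %in% nodes$gene & e$to %in% nodes$gene
  edges <- e[keep, , drop = FALSE]
  rownames(edges) <- NULL
  GeneNetwork(nodes = nodes, edges = edges)
}
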