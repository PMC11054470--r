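# Independent brute-force oracles and toy-graph builders. These
# deliberately avoid the code paths they check: betweenness by explicit
# path enumeration, modularity maxima by set-partition enumeration,
# hypergeometric tails by draw enumeration, coverage and linker optima by
# subset enumeration.

pk <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# synthesis spec scaled down for tiny-interactome tests
smallSpec <- function(seed, n, m = 2, ...) {
  args <- list(seed = seed, interactomeN = n, attachmentM = m, nDegs = 5,
               nQtls = 1, isolatedFraction = 0, plantedLinkers = 2,
               nDrugs = 4, plantedReversal = c(P = 2), decoyReversalMax = 1,
               nTargetDrugs = 1, annotationNSets = 3, plantedSetSize = 4,
               plantedOverlap = 2)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthesisSpec, args)
}

toyEdges <- function(from, to) {
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

# GeneNetwork over arbitrary toy edges; extra genes become isolated nodes
toyNetwork <- function(edges, extraNodes = character(0)) {
  ia <- suppressMessages(Interactome(edges))
  genes <- unique(c(interactomeGenes(ia), extraNodes))
  suppressMessages(assembleNetwork(makeSeeds(genes), character(0), ia))
}

randomEdges <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p
  if (!any(keep)) keep[1] <- TRUE
  toyEdges(nodes[idx[keep, 1]], nodes[idx[keep, 2]])
}

# --- betweenness oracle: enumerate every simple path per pair, keep the
# shortest, split credit equally across co-shortest paths ---
bruteBetweenness <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  adj <- lapply(setNames(nodes, nodes), function(v)
    sort(unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))))
  nb <- setNames(numeric(length(nodes)), nodes)
  ekey <- pk(edges$from, edges$to)
  eb <- setNames(numeric(length(ekey)), ekey)
  pairs <- combn(nodes, 2)
  for (c in seq_len(ncol(pairs))) {
    s <- pairs[1, c]; t <- pairs[2, c]
    env <- new.env()
    env$best <- Inf
    env$paths <- list()
    dfs <- function(v, trail) {
      if (length(trail) - 1 > env$best) return()
      if (v == t) {
        len <- length(trail) - 1
        if (len < env$best) { env$best <- len; env$paths <- list() }
        if (len == env$best) env$paths[[length(env$paths) + 1]] <- trail
        return()
      }
      for (w in adj[[v]]) if (!(w %in% trail)) dfs(w, c(trail, w))
    }
    dfs(s, s)
    np <- length(env$paths)
    if (np == 0) next
    for (pth in env$paths) {
      if (length(pth) > 2) {
        mid <- pth[-c(1, length(pth))]
        nb[mid] <- nb[mid] + 1 / np
      }
      ek <- pk(pth[-length(pth)], pth[-1])
      eb[ek] <- eb[ek] + 1 / np
    }
  }
  list(node = nb, edge = eb)
}

# --- all set partitions of n items as restricted growth strings ---
partitionsOf <- function(n) {
  res <- vector("list", 120000)
  cnt <- 0L
  rec <- function(prefix, maxUsed) {
    if (length(prefix) == n) {
      cnt <<- cnt + 1L
      res[[cnt]] <<- prefix
      return(invisible(NULL))
    }
    for (k in seq_len(maxUsed + 1L))
      rec(c(prefix, k), max(maxUsed, k))
  }
  rec(integer(0), 0L)
  res[seq_len(cnt)]
}

# --- modularity of a partition straight from the definition, and the
# exhaustive maximum over all partitions ---
modularityFromDef <- function(edges, assignment) {
  m <- nrow(edges)
  mods <- unique(assignment)
  q <- 0
  degAll <- table(factor(c(edges$from, edges$to), levels = names(assignment)))
  for (c in mods) {
    members <- names(assignment)[assignment == c]
    ec <- sum(edges$from %in% members & edges$to %in% members)
    dc <- sum(degAll[members])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

bruteMaxQ <- function(edges, nodes) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[cbind(edges$from, edges$to)] <- 1
  A[cbind(edges$to, edges$from)] <- 1
  k <- rowSums(A)
  m <- sum(A) / 2
  B <- A - outer(k, k) / (2 * m)
  best <- -Inf
  for (p in partitionsOf(n)) {
    q <- sum(B[outer(p, p, "==")]) / (2 * m)
    if (q > best) best <- q
  }
  best
}

# --- hypergeometric upper tail by enumerating all C(N, n) draws ---
hypergeomEnum <- function(k, K, n, N) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# --- minimum linker-set size by exhaustive subset search ---
bruteMinLinkers <- function(edges, seeds, maxSize = 4) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  nodes <- igraph::V(g)$name
  seedsIn <- intersect(seeds, nodes)
  cand <- setdiff(nodes, seeds)
  nComp <- function(extra) {
    sub <- igraph::induced_subgraph(g, c(seedsIn, extra))
    memb <- igraph::components(sub)$membership
    length(unique(memb[seedsIn]))
  }
  for (size in 0:maxSize) {
    if (size == 0) {
      if (nComp(character(0)) == 1) return(0L)
      next
    }
    if (length(cand) < size) break
    sets <- combn(cand, size)
    for (j in seq_len(ncol(sets)))
      if (nComp(sets[, j]) == 1) return(size)
  }
  Inf
}

# --- optimal k-drug coverage by subset enumeration ---
bruteMaxCoverage <- function(map, k) {
  drugs <- names(map)
  k <- min(k, length(drugs))
  best <- 0
  sets <- combn(drugs, k)
  for (j in seq_len(ncol(sets)))
    best <- max(best, length(unique(unlist(map[sets[, j]]))))
  best
}
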