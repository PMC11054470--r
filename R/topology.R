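#' Compute exact node and edge centralities
#'
#' Degree is exact; node and edge betweenness are exact all-pairs
#' shortest-path counts on the undirected simple graph, unnormalized (each
#' unordered pair counted once, fractional credit across equally short
#' paths). Connected components are handled independently and isolated nodes
#' get betweenness 0.
#'
#' @param network A [GeneNetwork-class] with at least one edge.
#' @return A [CentralityReport-class]; node rows sorted by gene, edge rows by
#'   endpoints.
#' @examples
#' ia <- Interactome(data.frame(from = c("A", "B"), to = c("B", "C")))
#' net <- assembleNetwork(makeSeeds(c("A", "B", "C")), character(0), ia)
#' computeCentralities(net)
#' @export
computeCentralities <- function(network) {
  if (!nrow(networkEdges(network))) stopf("network has no edges")
  g <- asIgraph(network)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  ebtw <- igraph::edge_betweenness(g, directed = FALSE, weights = NA)
  ends <- igraph::ends(g, igraph::E(g))
  p <- sortedPairs(ends[, 1], ends[, 2])
  roles <- nodeRoles(network)
  nodes <- data.frame(gene = names(deg), role = unname(roles[names(deg)]),
                      degree = as.integer(deg), betweenness = unname(btw),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- data.frame(from = p$a, to = p$b, betweenness = ebtw,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  CentralityReport(nodes = nodes, edges = edges)
}

#' Flag hub nodes and hub edges at a top-fraction rule
#'
#' Hub nodes are the top `floor(fraction * n_nodes)` genes by degree (at
#' least 1); hub edges the top `floor(fraction * n_edges)` edges by edge
#' betweenness. Ties at the cutoff are resolved lexicographically after the
#' score, so the result is scale-invariant and deterministic. With the
#' default 10% rule a 78-gene network yields 7 hub genes.
#'
#' @param report A [CentralityReport-class].
#' @param fraction Top fraction in (0, 1]; default 0.10.
#' @return List with `hubNodes` (gene symbols, descending degree) and
#'   `hubEdges` (`"A|B"` keys, descending edge betweenness).
#' @export
flagHubs <- function(report, fraction = 0.10) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stopf("fraction must lie in (0, 1]")
  n <- report@nodes
  e <- report@edges
  nHub <- max(1L, floor(fraction * nrow(n)))
  ordN <- order(-n$degree, n$gene)
  hubNodes <- n$gene[ordN][seq_len(min(nHub, nrow(n)))]
  nEdge <- floor(fraction * nrow(e))
  ordE <- order(-e$betweenness, e$from, e$to)
  hubEdges <- if (nEdge > 0)
    pairKey(e$from, e$to)[ordE][seq_len(min(nEdge, nrow(e)))]
  else character(0)
  list(hubNodes = hubNodes, hubEdges = hubEdges)
}

#' Power-law diagnostic for the degree distribution
#'
#' Least-squares line on log(count) versus log(degree) over the empirical
#' degree histogram (degree-0 nodes and zero-count degrees skipped). A
#' degree distribution compatible with a power law (high r-squared, exponent
#' typically 1.5-3.5) is the hallmark of scale-free biological networks as
#' opposed to random graphs. This is a simple diagnostic, not a
#' maximum-likelihood tail fit.
#'
#' @param x A [CentralityReport-class] or a numeric vector of node degrees.
#' @return List with `exponent` (= minus the fitted slope), `rSquared` and
#'   `nDegreeBins`.
#' @export
fitPowerLaw <- function(x) {
  deg <- if (is(x, "CentralityReport")) x@nodes$degree else as.numeric(x)
  deg <- deg[deg > 0]
  tab <- table(deg)
  k <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  if (length(k) < 3) stopf("degree distribution too degenerate")
  fit <- lm(log(cnt) ~ log(k))
  # a perfect fit triggers an informational warning from summary.lm; an
  # exactly power-law histogram is a legitimate input here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(exponent = -unname(coef(fit)[2]),
       rSquared = r2,
       nDegreeBins = length(k))
}
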