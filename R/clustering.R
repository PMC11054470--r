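#' Newman modularity of a partition
#'
#' Q = sum over modules c of (e_c/m - (d_c/2m)^2), with m the number of
#' edges, e_c the intra-module edge count and d_c the total degree inside
#' module c. The trivial one-module partition always gives Q = 0.
#'
#' @param network A [GeneNetwork-class].
#' @param assignment Named vector (gene -> module id) covering every node.
#' @return Modularity Q.
#' @examples
#' ia <- Interactome(data.frame(from = c("A", "B", "C", "D", "E", "F"),
#'                              to   = c("B", "C", "A", "E", "F", "D")))
#' net <- assembleNetwork(makeSeeds(LETTERS[1:6]), character(0), ia)
#' modularityQ(net, setNames(c(0, 0, 0, 1, 1, 1), LETTERS[1:6]))  # 0.5
#' @export
modularityQ <- function(network, assignment) {
  genes <- networkGenes(network)
  miss <- setdiff(genes, names(assignment))
  if (length(miss))
    stopf("assignment does not cover node(s): %s",
          paste(utils::head(miss, 5), collapse = ", "))
  g <- asIgraph(network)
  memb <- as.integer(factor(assignment[igraph::V(g)$name]))
  igraph::modularity(g, memb)
}

# Recursive leading-eigenvector bisection over the (generalized) modularity
# matrix. `idx` indexes nodes in lexicographic order, so the sign convention
# -- first (lexicographically smallest) non-zero entry made non-negative --
# is permutation-invariant. When the leading eigenvalue is degenerate
# (symmetric graphs), every eigenvector of the near-degenerate leading
# space is tried and the split with the largest modularity gain is kept,
# which removes the dependence on LAPACK's arbitrary basis choice.
.bisect <- function(B, m, idx, tol = 1e-10, refine = FALSE) {
  if (length(idx) <= 1) return(list(idx))
  Bg <- B[idx, idx, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg)
  e <- eigen(Bg, symmetric = TRUE)
  lambda <- e$values[1]
  if (lambda <= tol) return(list(idx))
  cand <- which(e$values > lambda - 1e-8)
  bestS <- NULL
  bestDQ <- -Inf
  for (j in cand) {
    v <- e$vectors[, j]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1]] < 0) v <- -v
    s <- v >= 0
    if (all(s) || !any(s)) next
    sv <- ifelse(s, 1, -1)
    dQ <- as.numeric(t(sv) %*% Bg %*% sv) / (4 * m)
    if (dQ > bestDQ + 1e-12) {
      bestDQ <- dQ
      bestS <- s
    }
  }
  if (is.null(bestS)) return(list(idx))
  if (refine) {
    sv <- ifelse(bestS, 1, -1)
    gain <- as.numeric(t(sv) %*% Bg %*% sv)
    repeat {
      improved <- FALSE
      for (i in seq_along(sv)) {
        s2 <- sv
        s2[i] <- -s2[i]
        g2 <- as.numeric(t(s2) %*% Bg %*% s2)
        if (g2 > gain + 1e-12) {
          sv <- s2
          gain <- g2
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    bestS <- sv > 0
    if (all(bestS) || !any(bestS)) return(list(idx))
    bestDQ <- gain / (4 * m)
  }
  if (bestDQ <= tol) return(list(idx))
  c(.bisect(B, m, idx[bestS], tol, refine),
    .bisect(B, m, idx[!bestS], tol, refine))
}

#' Spectral modularity partition of the network
#'
#' Newman's leading-eigenvector method: recursive bisection along the
#' leading eigenvector of the modularity matrix, keeping a split only when
#' it increases Q by more than `tol`. Deterministic: nodes are processed in
#' lexicographic order and the eigenvector sign is fixed by making the entry
#' of the smallest node non-negative; degenerate leading eigenspaces are
#' resolved by taking the basis vector whose split gains the most
#' modularity. Isolated nodes carry no modularity signal and are grouped
#' into one dedicated module. Kernighan-Lin-style single-vertex refinement
#' is available behind `refine` but off by default.
#'
#' @param network A [GeneNetwork-class] with at least one edge.
#' @param tol Minimum Q improvement to accept a split (default 1e-10).
#' @param refine Apply a greedy single-vertex sweep after each bisection.
#' @return A [ModuleAssignment-class] (0-based contiguous module ids,
#'   modules ordered by their lexicographically smallest member).
#' @export
spectralPartition <- function(network, tol = 1e-10, refine = FALSE) {
  if (!nrow(networkEdges(network))) stopf("network has no edges")
  genes <- networkGenes(network)
  g <- asIgraph(network)
  deg <- igraph::degree(g)[genes]
  con <- genes[deg > 0]
  iso <- genes[deg == 0]
  A <- matrix(0, length(con), length(con), dimnames = list(con, con))
  e <- networkEdges(network)
  A[cbind(e$from, e$to)] <- 1
  A[cbind(e$to, e$from)] <- 1
  k <- rowSums(A)
  m <- nrow(e)
  B <- A - outer(k, k) / (2 * m)
  groups <- .bisect(B, m, seq_along(con), tol, refine)
  members <- lapply(groups, function(i) con[i])
  if (length(iso)) members <- c(members, list(iso))
  members <- members[order(vapply(members, function(x) sort(x)[1], character(1)))]
  assignment <- integer(length(genes))
  names(assignment) <- genes
  for (i in seq_along(members)) assignment[members[[i]]] <- i - 1L
  ModuleAssignment(assignment = assignment,
                   modularityQ = modularityQ(network, assignment),
                   nModules = length(members))
}
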