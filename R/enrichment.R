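#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeom(N, K, n): the probability of drawing at least
#' `k` annotated genes when `n` query genes are drawn from a universe of `N`
#' genes of which `K` carry the annotation (one-sided Fisher test).
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Annotation-set size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @examples
#' hypergeomP(3, 4, 3, 10)  # 4/120
#' @export
hypergeomP <- function(k, K, n, N) {
  ok <- is.numeric(k) && is.numeric(K) && is.numeric(n) && is.numeric(N)
  if (!ok) stopf("hypergeomP arguments must be numeric")
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stopf("hypergeomP bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis with BH FDR
#'
#' Tests every set of a collection against the query with the one-sided
#' hypergeometric test. BH q-values are computed per category over all
#' tested sets (sets with zero overlap enter the correction with p = 1);
#' rows with overlap >= 1 are returned, sorted by q, then p, then set name.
#' Query genes outside the universe are dropped with a logged count, and
#' set members are intersected with the universe.
#'
#' @param query Character vector of query gene symbols.
#' @param collection An [AnnotationCollection-class].
#' @param universe Background gene symbols; default: all genes appearing in
#'   the collection. The background choice changes p-values materially and
#'   is deliberately surfaced.
#' @param alpha FDR threshold; `significant` marks `q < alpha` (strict).
#' @return `data.frame` with columns `category`, `set_name`, `overlap_k`,
#'   `set_size_K`, `query_size_n`, `universe_N`, `p_value`, `q_value`,
#'   `significant`, `overlap_genes` (`;`-joined).
#' @export
enrich <- function(query, collection, universe = NULL, alpha = 0.05) {
  sets <- geneSets(collection)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(normalizeGeneSymbols(universe))
  N <- length(universe)
  if (!N) stopf("empty universe")
  query <- unique(normalizeGeneSymbols(query))
  outside <- setdiff(query, universe)
  if (length(outside))
    msgf("dropped %d query gene(s) outside the universe", length(outside))
  query <- intersect(query, universe)
  n <- length(query)
  nm <- names(sets)
  res <- lapply(nm, function(s) {
    members <- intersect(sets[[s]], universe)
    ov <- intersect(query, members)
    k <- length(ov)
    K <- length(members)
    p <- if (K == 0) 1 else hypergeomP(k, K, n, N)
    list(set_name = s, overlap_k = k, set_size_K = K, p_value = p,
         overlap_genes = paste(sort(ov), collapse = ";"))
  })
  tab <- data.frame(
    category = annotationCategory(collection),
    set_name = vapply(res, `[[`, character(1), "set_name"),
    overlap_k = vapply(res, `[[`, numeric(1), "overlap_k"),
    set_size_K = vapply(res, `[[`, numeric(1), "set_size_K"),
    query_size_n = n, universe_N = N,
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  tab$q_value <- p.adjust(tab$p_value, method = "BH")
  tab$significant <- tab$q_value < alpha
  tab$overlap_genes <- vapply(res, `[[`, character(1), "overlap_genes")
  tab <- tab[tab$overlap_k >= 1, , drop = FALSE]
  tab <- tab[order(tab$q_value, tab$p_value, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Filter network genes by tissue expression score
#'
#' Keeps genes whose expression score is strictly greater than the
#' threshold (default 2.5, the STRING skin-score cut for
#' higher-than-average skin expression). Genes without a score are treated
#' as below threshold with a logged count.
#'
#' @param genes Character vector of gene symbols.
#' @param scores Named numeric vector (gene -> score).
#' @param threshold Strict lower bound; default 2.5.
#' @return The genes passing the filter, in input order.
#' @export
sensitivityFilter <- function(genes, scores, threshold = 2.5) {
  genes <- normalizeGeneSymbols(genes)
  miss <- setdiff(genes, names(scores))
  if (length(miss))
    msgf("%d gene(s) without expression score treated as below threshold",
         length(miss))
  sc <- scores[genes]
  genes[!is.na(sc) & sc > threshold]
}

#' Compare full and filtered enrichment results
#'
#' Quantifies how much of the full-network enrichment signal survives a
#' sensitivity re-analysis: repeated terms are the significant
#' (category, set) pairs present in both result lists, and per-category
#' preservation of the top term (smallest q, then p, then name) is
#' reported.
#'
#' @param full,filtered Result `data.frame`s from [enrich] (possibly
#'   row-bound across categories), computed with the same collection.
#' @param alpha Significance threshold on q (strict).
#' @return List with `nSignificantFull`, `nSignificantFiltered`,
#'   `nRepeated`, `fractionRepeated` and `topTermPreserved` (named logical
#'   per category).
#' @export
compareEnrichments <- function(full, filtered, alpha = 0.05) {
  sigKey <- function(x) {
    s <- x[x$q_value < alpha, , drop = FALSE]
    paste(s$category, s$set_name, sep = "\r")
  }
  fullSig <- sigKey(full)
  filtSig <- sigKey(filtered)
  rep <- intersect(fullSig, filtSig)
  top <- vapply(split(full, full$category), function(x) {
    x <- x[order(x$q_value, x$p_value, x$set_name), , drop = FALSE]
    paste(x$category[1], x$set_name[1], sep = "\r")
  }, character(1))
  list(nSignificantFull = length(fullSig),
       nSignificantFiltered = length(filtSig),
       nRepeated = length(rep),
       fractionRepeated = if (length(fullSig)) length(rep) / length(fullSig) else 0,
       topTermPreserved = vapply(top, `%in%`, logical(1), filtSig))
}
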