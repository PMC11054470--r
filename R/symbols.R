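#' Normalize gene symbols
#'
#' Gene identity throughout the package is the bare HGNC-style symbol string,
#' upper-cased; comparison is therefore case-insensitive. No alias resolution
#' is attempted.
#'
#' @param x Character vector of gene symbols.
#' @return Upper-cased, whitespace-trimmed character vector.
#' @examples
#' normalizeGeneSymbols(c("s100a8", " Stat3 "))
#' @export
normalizeGeneSymbols <- function(x) {
  if (!is.character(x)) stopf("gene symbols must be character, got %s", class(x)[1])
  x <- trimws(x)
  bad <- is.na(x) | x == "" | grepl("[[:space:]]", x)
  if (any(bad)) {
    stopf("invalid gene symbol(s): %s",
          paste(utils::head(sprintf("'%s'", x[bad]), 5), collapse = ", "))
  }
  toupper(x)
}

#' Combine DEG and QTL gene lists into a seed table
#'
#' A gene appearing in both lists keeps origin `DEG` and is counted once.
#'
#' @param degs Either a DEG table (`data.frame` with columns `gene`,
#'   `direction`) or a character vector of DEG symbols.
#' @param qtls Character vector of QTL gene symbols.
#' @return `data.frame` with columns `gene`, `origin` (`"DEG"` or `"QTL"`).
#' @examples
#' makeSeeds(c("S100A8", "LCE3A"), qtls = c("GMEB2", "S100A8"))
#' @export
makeSeeds <- function(degs, qtls = character(0)) {
  dg <- if (is.data.frame(degs)) degs$gene else degs
  dg <- unique(normalizeGeneSymbols(dg))
  qt <- if (length(qtls)) unique(normalizeGeneSymbols(qtls)) else character(0)
  dup <- intersect(qt, dg)
  if (length(dup)) {
    msgf("%d gene(s) in both DEG and QTL lists kept with origin DEG: %s",
         length(dup), paste(dup, collapse = ", "))
    qt <- setdiff(qt, dg)
  }
  data.frame(gene = c(dg, qt),
             origin = c(rep("DEG", length(dg)), rep("QTL", length(qt))),
             stringsAsFactors = FALSE)
}
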