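#' Read an interactome edge list
#'
#' Supports SIF (`nodeA relation nodeB [nodeB2 ...]`, whitespace-separated,
#' no header) and 2-column TSV (`from<TAB>to[<TAB>type]`, header row, the
#' canonical dialect). Unordered pairs are de-duplicated and self-loops
#' dropped with a logged count.
#'
#' @param path File path.
#' @param format `"SIF"` or `"TSV2"`.
#' @return An [Interactome-class] object.
#' @examples
#' f <- tempfile(fileext = ".sif")
#' writeLines(c("A fi B", "B fi A", "B fi C"), f)
#' readEdgeList(f, format = "SIF")
#' @export
readEdgeList <- function(path, format = c("TSV2", "SIF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty edge-list file: %s", path)
  if (format == "SIF") {
    from <- character(0); to <- character(0); type <- character(0)
    for (i in seq_along(lines)) {
      tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(tok) < 3)
        stopf("malformed SIF row at line %d: need 'nodeA relation nodeB'", i)
      tgt <- tok[-(1:2)]
      from <- c(from, rep(tok[1], length(tgt)))
      to <- c(to, tgt)
      type <- c(type, rep(tok[2], length(tgt)))
    }
    Interactome(data.frame(from = from, to = to, type = type,
                           stringsAsFactors = FALSE))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (ncol(tab) < 2) stopf("TSV2 edge list needs at least 2 columns")
    bad <- which(is.na(tab[[1]]) | is.na(tab[[2]]) |
                   trimws(as.character(tab[[1]])) == "" |
                   trimws(as.character(tab[[2]])) == "")
    if (length(bad))
      stopf("malformed TSV2 row at line %d (missing endpoint)", bad[1] + 1L)
    Interactome(tab)
  }
}

#' Write an interactome edge list
#'
#' @param x An [Interactome-class].
#' @param path Output path.
#' @param format `"TSV2"` (header row) or `"SIF"` (relation defaults to
#'   `"interacts"` where no type label is stored).
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(x, path, format = c("TSV2", "SIF")) {
  format <- match.arg(format)
  e <- interactomeEdges(x)
  if (format == "SIF") {
    rel <- ifelse(is.na(e$type), "interacts", e$type)
    writeLines(paste(e$from, rel, e$to, sep = "\t"), path)
  } else {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated GMT dialect: `set_name<TAB>description<TAB>member...`.
#' Members are case-normalized and de-duplicated within a set.
#'
#' @param path File path.
#' @param category Category label for the collection; defaults to the file
#'   name without extension.
#' @return An [AnnotationCollection-class].
#' @export
readGmt <- function(path, category = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(category)) category <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  sets <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(tok) < 3)
      stopf("malformed GMT row at line %d: fewer than 3 columns", i)
    nm <- trimws(tok[1])
    if (nm %in% names(sets)) stopf("duplicate set name '%s' at line %d", nm, i)
    sets[[nm]] <- tok[-(1:2)]
  }
  AnnotationCollection(category = category, sets = sets)
}

#' Write a GMT gene-set collection
#'
#' @param x An [AnnotationCollection-class].
#' @param path Output path.
#' @param description Description column value (recycled).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(x, path, description = NA) {
  s <- geneSets(x)
  desc <- if (is.na(description)) annotationCategory(x) else description
  writeLines(vapply(names(s), function(nm)
    paste(c(nm, desc, s[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Read a DEG table
#'
#' TSV with header columns `gene` and `direction`; directions are parsed to
#' `UP`/`DOWN` (reversal matching is undefined without a direction, so
#' anything else is an error). Duplicate genes are rejected.
#'
#' @param path File path.
#' @return `data.frame` with columns `gene`, `direction`.
#' @export
readDegTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(tab)))
    stopf("DEG table needs columns 'gene' and 'direction'")
  degTable(tab$gene, tab$direction)
}

#' Construct a validated DEG table
#'
#' @param gene Character vector of gene symbols.
#' @param direction Character vector; parsed case-insensitively to
#'   `UP`/`DOWN`.
#' @return `data.frame` with columns `gene`, `direction`.
#' @examples
#' degTable(c("S100A8", "LCE3A"), c("up", "down"))
#' @export
degTable <- function(gene, direction) {
  gene <- normalizeGeneSymbols(as.character(gene))
  dir <- toupper(trimws(as.character(direction)))
  bad <- !(dir %in% c("UP", "DOWN"))
  if (any(bad))
    stopf("unknown DEG direction for gene(s): %s",
          paste(sprintf("%s ('%s')", gene[bad], direction[bad]), collapse = ", "))
  if (anyDuplicated(gene))
    stopf("duplicate DEG gene(s): %s",
          paste(unique(gene[duplicated(gene)]), collapse = ", "))
  data.frame(gene = gene, direction = dir, stringsAsFactors = FALSE)
}

#' Write a DEG table
#'
#' @param x DEG `data.frame` (columns `gene`, `direction`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDegTable <- function(x, path) {
  utils::write.table(x[, c("gene", "direction")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain gene list
#'
#' One symbol per line; normalized and de-duplicated.
#'
#' @param path File path.
#' @return Character vector of symbols.
#' @export
readGeneList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  unique(normalizeGeneSymbols(lines[nzchar(lines)]))
}

#' Read a tissue expression-score table
#'
#' TSV with header columns `gene`, `score`; scores must be finite. The
#' scores are on the scale of the STRING per-tissue expression score, where
#' values above 2.5 mark higher-than-average skin expression.
#'
#' @param path File path.
#' @return Named numeric vector (gene -> score).
#' @export
readExpressionScores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "score") %in% names(tab)))
    stopf("expression-score table needs columns 'gene' and 'score'")
  sc <- as.numeric(tab$score)
  if (any(!is.finite(sc))) stopf("non-finite expression score(s)")
  setNames(sc, normalizeGeneSymbols(tab$gene))
}

#' Read a drug-gene effect table
#'
#' TSV with header columns `drug`, `gene`, `kind`, `direction` (DrugBank-like
#' schema). Kinds normalize to `TARGET`/`EXPRESSION_EFFECT`; free-text
#' directions are mapped through a packaged dictionary with conflicting
#' duplicates collapsed to `UNKNOWN`.
#'
#' @param path File path.
#' @return A [DrugEffectTable-class].
#' @export
readDrugEffectTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug", "gene", "kind", "direction")
  if (!all(need %in% names(tab)))
    stopf("drug effect table needs columns %s", paste(need, collapse = ", "))
  DrugEffectTable(rows = tab)
}

#' Write a drug-gene effect table
#'
#' @param x A [DrugEffectTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDrugEffectTable <- function(x, path) {
  utils::write.table(drugEffects(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a SNP association table
#'
#' TSV with header columns `variant`, `p`; p-values must lie in (0, 1].
#'
#' @param path File path.
#' @return `data.frame` with columns `variant`, `p`.
#' @export
readSnpTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant", "p") %in% names(tab)))
    stopf("SNP table needs columns 'variant' and 'p'")
  p <- as.numeric(tab$p)
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stopf("SNP p-values must lie in (0, 1]")
  data.frame(variant = as.character(tab$variant), p = p,
             stringsAsFactors = FALSE)
}

.annotationCols <- c("drug", "immunomodGeneral", "immunomodSkin",
                     "nNetworkTargets", "topicalPossible", "whoEssential",
                     "priceBand", "hasAtc", "orderable", "directionClear",
                     "grade3to5Risk", "practicalIssue")

#' Read per-drug criterion annotations for ranking
#'
#' TSV with one column per rubric criterion field (see [drugAnnotation] for
#' the schema). Logical columns accept TRUE/FALSE; `priceBand` must be one of
#' `VERY_LOW`, `LOW`, `MID`, `VERY_HIGH`, `UNAVAILABLE`; `practicalIssue`
#' one of `NONE`, `ISSUE`, `SEVERE`.
#'
#' @param path File path.
#' @return `data.frame`, one row per drug.
#' @export
readDrugAnnotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.annotationCols, names(tab))
  if (length(miss))
    stopf("annotation table missing column(s): %s", paste(miss, collapse = ", "))
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    do.call(drugAnnotation, as.list(tab[i, .annotationCols]))))
}

#' Write a gene network to JSON
#'
#' Serializes nodes (with roles), edges and isolated seeds; [readNetwork]
#' restores an equal object.
#'
#' @param x A [GeneNetwork-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(x, path) {
  obj <- list(nodes = x@nodes, edges = x@edges,
              isolated_seeds = isolatedSeeds(x))
  jsonlite::write_json(obj, path, dataframe = "columns", na = "null",
                       auto_unbox = FALSE)
  invisible(path)
}

#' Read a gene network from JSON
#'
#' @param path Path written by [writeNetwork].
#' @return A [GeneNetwork-class].
#' @export
readNetwork <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  edges <- if (length(obj$edges$from)) {
    data.frame(from = obj$edges$from, to = obj$edges$to,
               type = if (!is.null(obj$edges$type)) as.character(obj$edges$type)
                      else NA_character_,
               stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0),
                    type = character(0))
  GeneNetwork(nodes = nodes, edges = edges)
}
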