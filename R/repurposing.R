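#' Map drugs to their physical targets within the network
#'
#' Keeps `TARGET` rows whose gene lies in the network; drugs with at least
#' one network target are retained. The summary partitions hit genes into
#' main genes (roles `DEG`/`QTL`) and linkers.
#'
#' @param network A [GeneNetwork-class].
#' @param drugTable A [DrugEffectTable-class].
#' @return List with `map` (named list drug -> sorted gene vector) and
#'   `summary` (`nDrugs`, `nMainGenesHit`, `nLinkerGenesHit`).
#' @export
mapTargets <- function(network, drugTable) {
  r <- drugEffects(drugTable)
  r <- r[r$kind == "TARGET" & r$gene %in% networkGenes(network), , drop = FALSE]
  map <- lapply(split(r$gene, r$drug), function(g) sort(unique(g)))
  map <- map[order(names(map))]
  roles <- nodeRoles(network)
  hit <- unique(unlist(map, use.names = FALSE))
  list(map = map,
       summary = list(nDrugs = length(map),
                      nMainGenesHit = sum(roles[hit] %in% c("DEG", "QTL")),
                      nLinkerGenesHit = sum(roles[hit] == "LINKER")))
}

#' Transcriptomic reversal profiles
#'
#' A gene belongs to a drug's reversal set iff the drug's expression effect
#' opposes the disease direction: `UP` DEGs paired with `DECREASE` effects,
#' `DOWN` DEGs with `INCREASE`. `UNKNOWN` effect directions never count, and
#' same-direction (aggravating) pairs are excluded. Drugs with an empty
#' reversal set are dropped.
#'
#' @param degs DEG table (columns `gene`, `direction` in `UP`/`DOWN`).
#' @param drugTable A [DrugEffectTable-class]; only `EXPRESSION_EFFECT` rows
#'   are considered.
#' @return List with `map` (named list drug -> sorted reversed DEGs) and
#'   `justification` (`data.frame`: drug, gene, degDirection,
#'   effectDirection, reverses).
#' @export
reversalProfile <- function(degs, drugTable) {
  r <- drugEffects(drugTable)
  r <- r[r$kind == "EXPRESSION_EFFECT", , drop = FALSE]
  degDir <- setNames(degs$direction, degs$gene)
  r <- r[r$gene %in% names(degDir), , drop = FALSE]
  dd <- unname(degDir[r$gene])
  reverses <- (dd == "UP" & r$direction == "DECREASE") |
              (dd == "DOWN" & r$direction == "INCREASE")
  just <- data.frame(drug = r$drug, gene = r$gene, degDirection = dd,
                     effectDirection = r$direction, reverses = reverses,
                     stringsAsFactors = FALSE)
  rev <- r[reverses, , drop = FALSE]
  map <- lapply(split(rev$gene, rev$drug), function(g) sort(unique(g)))
  map <- map[lengths(map) > 0]
  map <- map[order(names(map))]
  list(map = map, justification = just)
}

.profileMap <- function(profile) {
  if (is.list(profile) && !is.null(profile$map)) profile$map else profile
}

#' Combined reversal coverage of a drug set
#'
#' Union of the listed drugs' reversal sets.
#'
#' @param profile Result of [reversalProfile] (or a bare named list of gene
#'   sets).
#' @param drugs Character vector of drug labels present in the profile.
#' @return List with `genes` (sorted union) and `size`.
#' @export
combinationCoverage <- function(profile, drugs) {
  map <- .profileMap(profile)
  unknown <- setdiff(drugs, names(map))
  if (length(unknown))
    stopf("drug(s) not in reversal profile: %s", paste(unknown, collapse = ", "))
  genes <- sort(unique(unlist(map[drugs], use.names = FALSE)))
  list(genes = genes, size = length(genes))
}

#' Greedy maximum-coverage drug selection
#'
#' Standard greedy set cover: repeatedly pick the drug with the largest
#' marginal coverage; ties go to the larger total reversal set, then
#' lexicographic order. Generalizes the fixed pick-the-top-k-by-size recipe
#' to a principled selector with the usual (1 - 1/e) guarantee.
#'
#' @param profile Result of [reversalProfile] (or a bare named list).
#' @param k Number of drugs to select (`k >= 1`); if `k` exceeds the number
#'   of profiled drugs, all drugs are returned.
#' @return Ordered character vector of selected drugs.
#' @export
greedyMaxCoverage <- function(profile, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) stopf("k must be >= 1")
  map <- .profileMap(profile)
  k <- min(k, length(map))
  chosen <- character(0)
  covered <- character(0)
  total <- lengths(map)
  for (i in seq_len(k)) {
    avail <- setdiff(names(map), chosen)
    marg <- vapply(avail, function(d) length(setdiff(map[[d]], covered)),
                   integer(1))
    best <- avail[order(-marg, -total[avail], avail)][1]
    chosen <- c(chosen, best)
    covered <- union(covered, map[[best]])
  }
  chosen
}

#' Merge target-based and reversal-based candidates
#'
#' Union of the two candidate sources with provenance tags `TARGET`,
#' `REVERSAL` or `BOTH`; deterministic ordering by provenance
#' (alphabetical: BOTH, REVERSAL, TARGET) then drug name.
#'
#' @param targetMap Result of [mapTargets].
#' @param profile Result of [reversalProfile].
#' @return `data.frame` with columns `drug`, `provenance`.
#' @export
mergeCandidates <- function(targetMap, profile) {
  t <- names(if (is.list(targetMap) && !is.null(targetMap$map)) targetMap$map
             else targetMap)
  r <- names(.profileMap(profile))
  drugs <- union(t, r)
  prov <- ifelse(drugs %in% t & drugs %in% r, "BOTH",
                 ifelse(drugs %in% t, "TARGET", "REVERSAL"))
  out <- data.frame(drug = drugs, provenance = prov, stringsAsFactors = FALSE)
  out <- out[order(out$provenance, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pharmaco-genomic SNP lookup
#'
#' Joins genome-wide significant SNPs (p strictly below the threshold,
#' default 5e-8) against a pharmaco-genomics table and returns the unique
#' associated drugs.
#'
#' @param snps `data.frame` with columns `variant`, `p`.
#' @param pharmacogenomicTable `data.frame` with columns `variant`, `drug`.
#' @param threshold Genome-wide significance threshold (strict `<`).
#' @return Sorted character vector of drugs (possibly empty).
#' @export
snpLookup <- function(snps, pharmacogenomicTable, threshold = 5e-8) {
  sig <- snps$variant[snps$p < threshold]
  if (!nrow(pharmacogenomicTable)) return(character(0))
  sort(unique(pharmacogenomicTable$drug[
    pharmacogenomicTable$variant %in% sig]))
}

#' Reversal matrix in tabular form
#'
#' Drugs-by-DEGs matrix with cells `reverses`, `aggravates` or `none`,
#' mirroring a pharmaco-transcriptomics heat-map layout.
#'
#' @param degs DEG table.
#' @param drugTable A [DrugEffectTable-class].
#' @return `data.frame`, one row per profiled drug, one column per DEG.
#' @export
reversalMatrix <- function(degs, drugTable) {
  prof <- reversalProfile(degs, drugTable)
  just <- prof$justification
  drugs <- sort(unique(just$drug))
  m <- matrix("none", length(drugs), nrow(degs),
              dimnames = list(drugs, degs$gene))
  if (nrow(just)) {
    state <- ifelse(just$reverses, "reverses",
                    ifelse(just$effectDirection == "UNKNOWN", "none",
                           "aggravates"))
    m[cbind(just$drug, just$gene)] <- state
  }
  data.frame(drug = drugs, m, check.names = FALSE, stringsAsFactors = FALSE,
             row.names = NULL)
}
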