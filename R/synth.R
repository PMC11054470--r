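#' Synthetic study specification
#'
#' Bundles every knob of the seeded generators. The defaults mirror the
#' shape of the motivating study: 52 DEGs + 3 QTL seeds of which 9 have no
#' interactome coverage, 23 planted linker genes (so the assembled network
#' has 78 nodes), three planted reversal drugs covering 11 DEGs each with a
#' 23-gene union, a 47/78 fraction of network genes above the 2.5
#' skin-expression threshold, and one annotation set enriched in the DEGs
#' at overlap 15/20.
#'
#' @param seed Integer master seed; every generator is a pure function of
#'   (spec, seed).
#' @param interactomeN Number of interactome genes.
#' @param attachmentM Preferential-attachment edges per new node.
#' @param nDegs,nQtls Seed-gene counts.
#' @param isolatedFraction Fraction of seeds sampled from outside the
#'   interactome (no interaction coverage).
#' @param plantedLinkers Number of forced linker genes in the planted
#'   interactome used by [genSyntheticStudy].
#' @param nDrugs Total drugs in the effect table.
#' @param plantedReversal Named integer vector: planted drug -> number of
#'   DEGs its expression effects reverse. The default three-drug layout has
#'   pairwise overlaps (5, 1, 4) giving a 23-gene union.
#' @param decoyReversalMax Maximum reversal-set size of decoy drugs (kept
#'   strictly below the planted quotas for recovery tests).
#' @param nTargetDrugs Drugs receiving physical `TARGET` rows.
#' @param scoreFractionAbove Fraction of genes given an expression score
#'   above 2.5.
#' @param annotationNSets Random annotation sets per collection.
#' @param plantedSetSize,plantedOverlap Size of the planted enriched set and
#'   its overlap with the DEGs.
#' @return List of class `vheSynthesisSpec`.
#' @export
synthesisSpec <- function(seed = 1L, interactomeN = 600L, attachmentM = 2L,
                          nDegs = 52L, nQtls = 3L,
                          isolatedFraction = 9 / 55, plantedLinkers = 23L,
                          nDrugs = 40L,
                          plantedReversal = c(DRUG_A = 11L, DRUG_B = 11L,
                                              DRUG_C = 11L),
                          decoyReversalMax = 3L, nTargetDrugs = 12L,
                          scoreFractionAbove = 47 / 78,
                          annotationNSets = 30L, plantedSetSize = 20L,
                          plantedOverlap = 15L) {
  spec <- list(seed = as.integer(seed), interactomeN = as.integer(interactomeN),
               attachmentM = as.integer(attachmentM), nDegs = as.integer(nDegs),
               nQtls = as.integer(nQtls), isolatedFraction = isolatedFraction,
               plantedLinkers = as.integer(plantedLinkers),
               nDrugs = as.integer(nDrugs), plantedReversal = plantedReversal,
               decoyReversalMax = as.integer(decoyReversalMax),
               nTargetDrugs = as.integer(nTargetDrugs),
               scoreFractionAbove = scoreFractionAbove,
               annotationNSets = as.integer(annotationNSets),
               plantedSetSize = as.integer(plantedSetSize),
               plantedOverlap = as.integer(plantedOverlap))
  if (spec$nDegs + spec$nQtls > spec$interactomeN)
    stopf("seed counts exceed interactome size")
  if (spec$plantedOverlap > min(spec$plantedSetSize, spec$nDegs))
    stopf("planted overlap infeasible")
  if (sum(spec$plantedReversal) > 3 * spec$nDegs)
    stopf("planted reversal quotas infeasible")
  class(spec) <- "vheSynthesisSpec"
  spec
}

.synGene <- function(i) sprintf("G%04d", i)

#' Generate a scale-free synthetic interactome
#'
#' Preferential attachment over the synthetic gene namespace `G0001...`:
#' starts from `attachmentM` unconnected genes, then each new gene attaches
#' to `attachmentM` distinct existing genes with probability proportional
#' to degree + 1, giving exactly `attachmentM * (interactomeN -
#' attachmentM)` edges. Deterministic per seed; the synthetic namespace is
#' disjoint from real symbols so fixtures cannot be confused with real
#' data.
#'
#' @param spec A [synthesisSpec()].
#' @return An [Interactome-class].
#' @export
genInteractome <- function(spec) {
  n <- spec$interactomeN
  m <- spec$attachmentM
  if (n < m + 1) stopf("interactomeN must exceed attachmentM")
  withSeed(spec$seed, {
    deg <- integer(n)
    from <- character(0); to <- character(0)
    for (i in (m + 1):n) {
      existing <- seq_len(i - 1)
      pick <- sample(existing, min(m, length(existing)),
                     prob = deg[existing] + 1)
      deg[pick] <- deg[pick] + 1L
      deg[i] <- deg[i] + length(pick)
      from <- c(from, rep(.synGene(i), length(pick)))
      to <- c(to, .synGene(pick))
    }
    Interactome(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  })
}

#' Generate expression scores with a fixed fraction above threshold
#'
#' Exactly `round(fractionAbove * length(genes))` genes receive a score
#' strictly above 2.5 (uniform on (2.5, 5]); the rest fall in [0, 2.5).
#'
#' @param genes Character vector of genes to score.
#' @param fractionAbove Target fraction above the 2.5 threshold.
#' @param seed Integer seed.
#' @return Named numeric vector.
#' @export
genExpressionScores <- function(genes, fractionAbove = 47 / 78, seed = 1L) {
  withSeed(seed, {
    nAbove <- round(fractionAbove * length(genes))
    hi <- sample(seq_along(genes), nAbove)
    sc <- runif(length(genes), 0, 2.49)
    sc[hi] <- runif(nAbove, 2.51, 5)
    setNames(sc, genes)
  })
}

#' Generate disease seed inputs
#'
#' Samples DEG and QTL seeds from the interactome, replaces a configurable
#' fraction of the DEGs with genes outside the interactome (namespace
#' `X###`) to emulate seeds without interaction coverage, draws DEG
#' directions 50/50 up/down, and scores all genes for the skin-expression
#' sensitivity filter.
#'
#' @param spec A [synthesisSpec()].
#' @param interactome An [Interactome-class].
#' @return List with `degs` (DEG table), `qtls` (character) and `scores`
#'   (named numeric over interactome genes plus isolated seeds).
#' @export
genDiseaseInputs <- function(spec, interactome) {
  genes <- interactomeGenes(interactome)
  nSeeds <- spec$nDegs + spec$nQtls
  nIso <- round(spec$isolatedFraction * nSeeds)
  if (nIso > spec$nDegs) stopf("isolatedFraction infeasible")
  if (nSeeds - nIso > length(genes)) stopf("not enough interactome genes")
  withSeed(spec$seed + 1L, {
    inside <- sample(genes, nSeeds - nIso)
    iso <- if (nIso > 0) sprintf("X%03d", seq_len(nIso)) else character(0)
    qtls <- if (spec$nQtls > 0) inside[seq_len(spec$nQtls)] else character(0)
    degIn <- setdiff(inside, qtls)
    degGenes <- c(degIn, iso)
    dirs <- ifelse(rbinom(length(degGenes), 1, 0.5) == 1, "UP", "DOWN")
    scores <- genExpressionScores(c(genes, iso), spec$scoreFractionAbove,
                                  seed = spec$seed + 2L)
    list(degs = degTable(degGenes, dirs), qtls = qtls, scores = scores)
  })
}

# planted index layout reproducing the published overlap structure:
# |A|=|B|=|C|=11, A^B=5, A^C=1, B^C=4, triple empty, union 23
.plantedLayout11 <- list(A = 1:11, B = c(7:11, 12:17), C = c(1, 14:17, 18:23))

#' Generate a drug-effect table with planted reversal structure
#'
#' Every planted drug receives expression-effect rows exactly opposing its
#' chosen DEGs' directions, plus decoy same-direction rows and off-DEG
#' rows; decoy drugs get small reversal sets (at most `decoyReversalMax`)
#' so planted drugs are recoverable as the top reversal candidates. A
#' disjoint drug subset receives physical `TARGET` rows against interactome
#' genes. With the default three-drug/11-gene layout the planted union is
#' 23 genes.
#'
#' @param spec A [synthesisSpec()].
#' @param degs DEG table from [genDiseaseInputs].
#' @param interactome Optional [Interactome-class] supplying target genes.
#' @return A [DrugEffectTable-class].
#' @export
genDrugTables <- function(spec, degs, interactome = NULL) {
  planted <- spec$plantedReversal
  if (any(planted > spec$nDegs)) stopf("planted count exceeds nDegs")
  opp <- function(d) ifelse(d == "UP", "DECREASE", "INCREASE")
  same <- function(d) ifelse(d == "UP", "INCREASE", "DECREASE")
  withSeed(spec$seed + 3L, {
    rows <- list()
    addRow <- function(drug, gene, kind, direction)
      rows[[length(rows) + 1L]] <<- data.frame(drug = drug, gene = gene,
                                               kind = kind,
                                               direction = direction,
                                               stringsAsFactors = FALSE)
    # planted reversal sets
    if (length(planted) == 3 && all(planted == 11) && spec$nDegs >= 23) {
      sets <- lapply(.plantedLayout11, function(i) degs$gene[i])
      names(sets) <- names(planted)
    } else {
      if (sum(planted) > spec$nDegs)
        stopf("disjoint planted quotas exceed nDegs")
      off <- 0L
      sets <- lapply(planted, function(q) {
        s <- degs$gene[(off + 1):(off + q)]
        off <<- off + q
        s
      })
    }
    for (d in names(sets)) {
      g <- sets[[d]]
      dir <- degs$direction[match(g, degs$gene)]
      addRow(d, g, "EXPRESSION_EFFECT", opp(dir))
      rest <- setdiff(degs$gene, g)
      decoy <- sample(rest, min(3, length(rest)))
      addRow(d, decoy, "EXPRESSION_EFFECT",
             same(degs$direction[match(decoy, degs$gene)]))
    }
    # decoy drugs: small reversal sets plus aggravating rows
    nDecoy <- max(0L, spec$nDrugs - length(planted) - spec$nTargetDrugs)
    for (i in seq_len(nDecoy)) {
      d <- sprintf("DECOY_%03d", i)
      nRev <- if (spec$decoyReversalMax > 0)
        sample(0:spec$decoyReversalMax, 1) else 0L
      g <- sample(degs$gene, nRev + 2)
      dir <- degs$direction[match(g, degs$gene)]
      if (nRev > 0)
        addRow(d, g[seq_len(nRev)], "EXPRESSION_EFFECT",
               opp(dir[seq_len(nRev)]))
      addRow(d, g[(nRev + 1):length(g)], "EXPRESSION_EFFECT",
             same(dir[(nRev + 1):length(g)]))
    }
    # target drugs against interactome genes (mix of seeds and non-seeds)
    tgtPool <- if (!is.null(interactome)) {
      c(degs$gene[degs$gene %in% interactomeGenes(interactome)],
        sample(interactomeGenes(interactome), min(50, spec$interactomeN)))
    } else degs$gene
    for (i in seq_len(spec$nTargetDrugs)) {
      d <- sprintf("TDRUG_%03d", i)
      g <- unique(sample(tgtPool, sample(1:6, 1)))
      addRow(d, g, "TARGET", "UNKNOWN")
    }
    DrugEffectTable(rows = do.call(rbind, rows))
  })
}

#' Generate an annotation collection with one planted enriched set
#'
#' `annotationNSets` random sets drawn from the universe, plus one planted
#' set of size `plantedSetSize` containing `plantedOverlap` genes from the
#' query (the DEGs); with the default 15/20 overlap against a universe of
#' hundreds of genes the planted set attains the minimum q-value in
#' [enrich].
#'
#' @param spec A [synthesisSpec()].
#' @param universe Character vector of background genes.
#' @param query Genes the planted set should be enriched in (default none:
#'   purely random collection).
#' @param category Collection label.
#' @return An [AnnotationCollection-class]; the planted set is named
#'   `"SET_PLANTED"`.
#' @export
genAnnotationCollection <- function(spec, universe, query = NULL,
                                    category = "synthetic") {
  withSeed(spec$seed + 4L, {
    sets <- list()
    for (i in seq_len(spec$annotationNSets)) {
      sz <- sample(10:50, 1)
      sets[[sprintf("SET%04d", i)]] <- sample(universe, min(sz, length(universe)))
    }
    if (!is.null(query) && spec$plantedOverlap > 0) {
      query <- intersect(query, universe)
      inQ <- sample(query, min(spec$plantedOverlap, length(query)))
      outQ <- sample(setdiff(universe, query),
                     spec$plantedSetSize - length(inQ))
      sets[["SET_PLANTED"]] <- c(inQ, outQ)
    }
    AnnotationCollection(category = category, sets = sets)
  })
}

#' Generate per-drug rubric annotations
#'
#' Seeded random criterion flags for a drug list, for exercising the
#' ranking stage end-to-end.
#'
#' @param spec A [synthesisSpec()].
#' @param drugs Character vector of drug labels.
#' @param targetCounts Optional named numeric of network-target counts.
#' @return Annotation `data.frame`.
#' @export
genDrugAnnotations <- function(spec, drugs, targetCounts = NULL) {
  withSeed(spec$seed + 5L, {
    do.call(rbind, lapply(drugs, function(d) {
      drugAnnotation(
        d,
        immunomodGeneral = runif(1) < 0.3, immunomodSkin = runif(1) < 0.2,
        nNetworkTargets = if (!is.null(targetCounts) && d %in% names(targetCounts))
          targetCounts[[d]] else sample(0:6, 1),
        topicalPossible = runif(1) < 0.4, whoEssential = runif(1) < 0.3,
        priceBand = sample(c("VERY_LOW", "LOW", "MID", "VERY_HIGH",
                             "UNAVAILABLE"), 1,
                           prob = c(0.2, 0.3, 0.3, 0.1, 0.1)),
        hasAtc = runif(1) < 0.9, orderable = runif(1) < 0.9,
        directionClear = runif(1) < 0.8, grade3to5Risk = runif(1) < 0.2,
        practicalIssue = sample(c("NONE", "ISSUE", "SEVERE"), 1,
                                prob = c(0.7, 0.2, 0.1)))
    }))
  })
}

#' Generate a complete synthetic study
#'
#' Produces every pipeline input with planted structure: an interactome in
#' which exactly `plantedLinkers` designated genes are required to join the
#' seed components into one network (a chain of seed groups bridged by the
#' planted linkers, embedded alongside a preferential-attachment
#' background), seed tables with the configured number of
#' uncovered/isolated genes, drug tables with the planted reversal layout,
#' expression scores, an annotation collection enriched in the DEGs, rubric
#' annotations, and SNP/pharmaco-genomics tables (the latter empty by
#' default, matching a lookup that highlights no drugs).
#'
#' @param spec A [synthesisSpec()].
#' @return List: `interactome`, `degs`, `qtls`, `scores`, `drugTable`,
#'   `collection`, `annotations`, `snps`, `pgx`, `spec`.
#' @export
genSyntheticStudy <- function(spec = synthesisSpec()) {
  nL <- spec$plantedLinkers
  nSeeds <- spec$nDegs + spec$nQtls
  nIso <- round(spec$isolatedFraction * nSeeds)
  nCon <- nSeeds - nIso
  if (nCon < nL + 1) stopf("need at least plantedLinkers + 1 connected seeds")
  withSeed(spec$seed + 6L, {
    seedGenes <- .synGene(seq_len(nCon))
    linkGenes <- sprintf("L%03d", seq_len(nL))
    isoGenes <- if (nIso > 0) sprintf("X%03d", seq_len(nIso)) else character(0)
    # split connected seeds into nL + 1 groups chained by the linkers
    groupOf <- sort(rep_len(seq_len(nL + 1), nCon))
    groups <- split(seedGenes, groupOf)
    from <- character(0); to <- character(0)
    for (g in groups) if (length(g) > 1) {
      from <- c(from, g[-length(g)]); to <- c(to, g[-1])
    }
    for (i in seq_len(nL)) {
      from <- c(from, linkGenes[i], linkGenes[i])
      to <- c(to, groups[[i]][1], groups[[i + 1]][1])
    }
    # preferential-attachment background glued to the linkers only, so no
    # background gene can replace a planted linker
    nBg <- max(0L, spec$interactomeN - nCon - nL)
    if (nBg > 0) {
      bg <- sprintf("B%04d", seq_len(nBg))
      bgDeg <- integer(nBg)
      for (i in seq_len(nBg)) {
        if (i == 1) {
          anchor <- sample(linkGenes, 1)
          from <- c(from, bg[i]); to <- c(to, anchor)
        } else {
          existing <- seq_len(i - 1)
          pick <- sample(existing, min(spec$attachmentM, length(existing)),
                         prob = bgDeg[existing] + 1)
          bgDeg[pick] <- bgDeg[pick] + 1L
          bgDeg[i] <- bgDeg[i] + length(pick)
          from <- c(from, rep(bg[i], length(pick))); to <- c(to, bg[pick])
        }
      }
    }
    interactome <- Interactome(data.frame(from = from, to = to,
                                          stringsAsFactors = FALSE))
    qtls <- seedGenes[seq_len(spec$nQtls)]
    degGenes <- c(setdiff(seedGenes, qtls), isoGenes)
    dirs <- ifelse(rbinom(length(degGenes), 1, 0.5) == 1, "UP", "DOWN")
    degs <- degTable(degGenes, dirs)
    scores <- genExpressionScores(
      unique(c(interactomeGenes(interactome), isoGenes)),
      spec$scoreFractionAbove, seed = spec$seed + 2L)
    drugTable <- genDrugTables(spec, degs, interactome)
    collection <- genAnnotationCollection(
      spec, universe = unique(c(interactomeGenes(interactome), isoGenes)),
      query = degs$gene)
    annotations <- genDrugAnnotations(
      spec, sort(unique(drugEffects(drugTable)$drug)))
    snps <- data.frame(
      variant = c("rsSYN0001", "rsSYN0002", "rsSYN0003"),
      p = c(1e-9, 5e-8, 0.02), stringsAsFactors = FALSE)
    pgx <- data.frame(variant = character(0), drug = character(0),
                      stringsAsFactors = FALSE)
    list(interactome = interactome, degs = degs, qtls = qtls,
         scores = scores, drugTable = drugTable, collection = collection,
         annotations = annotations, snps = snps, pgx = pgx, spec = spec)
  })
}
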