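#' Pipeline configuration
#'
#' Holds the thresholds the workflow runs at -- hub fraction 0.10,
#' enrichment FDR 0.05, skin-expression cut 2.5, genome-wide significance
#' 5e-8 -- together with either a set of input paths or a synthetic study
#' spec, the rubric, and the output directory.
#'
#' @param outDir Output directory (created if missing).
#' @param inputs Named list of input file paths: `interactome` (TSV2 or
#'   SIF by extension), `degs`, `qtls`, `scores`, `drugs`, `gmt`,
#'   `annotations`, `snps`, `pgx`. Ignored when `synthSpec` is given.
#' @param synthSpec A [synthesisSpec()]; when supplied the pipeline
#'   generates its own inputs (written under `outDir/inputs/`).
#' @param hubFraction Top fraction for hub flagging.
#' @param alpha Enrichment FDR threshold.
#' @param skinThreshold Sensitivity-filter expression cut.
#' @param gwasThreshold SNP significance cut.
#' @param rubric A [RubricConfig-class].
#' @param maxPathLen Linker-candidate distance bound.
#' @param tiers Enrichment tiers to run, a subset of
#'   `c("degs", "qtls", "network", "modules")`.
#' @return List of class `vhePipelineConfig`.
#' @export
pipelineConfig <- function(outDir, inputs = NULL, synthSpec = NULL,
                           hubFraction = 0.10, alpha = 0.05,
                           skinThreshold = 2.5, gwasThreshold = 5e-8,
                           rubric = rubricConfig(), maxPathLen = 3,
                           tiers = c("degs", "qtls", "network", "modules")) {
  stopifnot(hubFraction > 0, hubFraction <= 1, alpha > 0, alpha <= 1,
            gwasThreshold > 0, gwasThreshold < 1)
  cfg <- list(outDir = outDir, inputs = inputs, synthSpec = synthSpec,
              hubFraction = hubFraction, alpha = alpha,
              skinThreshold = skinThreshold, gwasThreshold = gwasThreshold,
              rubric = rubric, maxPathLen = maxPathLen,
              tiers = match.arg(tiers, several.ok = TRUE))
  class(cfg) <- "vhePipelineConfig"
  cfg
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full repurposing pipeline
#'
#' Executes assemble -> topology -> cluster -> enrich (four tiers: DEGs,
#' QTL genes, whole network, per-module, plus the skin-expression
#' sensitivity re-analysis) -> repurpose -> rank (primary and no-pricing
#' secondary), writing every intermediate artifact as TSV/JSON under the
#' configured output directory plus a JSON run manifest with per-stage
#' counts and a config fingerprint. Any stage error aborts with the stage
#' name and cause; artifacts of completed stages are retained. Re-running
#' with the same config and inputs reproduces every TSV/JSON output
#' byte-identically (the timestamp is confined to the manifest).
#'
#' @param config A [pipelineConfig()].
#' @return The manifest, invisibly (list).
#' @export
runPipeline <- function(config) {
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "vheRx",
                   version = as.character(packageVersion("vheRx")),
                   config = list(hubFraction = config$hubFraction,
                                 alpha = config$alpha,
                                 skinThreshold = config$skinThreshold,
                                 gwasThreshold = config$gwasThreshold,
                                 maxPathLen = config$maxPathLen,
                                 tiers = config$tiers,
                                 pricingEnabled = config$rubric@pricingEnabled,
                                 synthetic = !is.null(config$synthSpec),
                                 seed = if (!is.null(config$synthSpec))
                                   config$synthSpec$seed else NA),
                   counts = list())
  manifest$configHash <- configHash(jsonlite::toJSON(manifest$config,
                                                    auto_unbox = TRUE))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # ---- inputs ----
  dat <- stage("inputs", {
    if (!is.null(config$synthSpec)) {
      study <- genSyntheticStudy(config$synthSpec)
      idir <- file.path(out, "inputs")
      dir.create(idir, showWarnings = FALSE)
      writeEdgeList(study$interactome, file.path(idir, "interactome.tsv"))
      writeDegTable(study$degs, file.path(idir, "degs.tsv"))
      writeLines(study$qtls, file.path(idir, "qtls.txt"))
      .writeTsv(data.frame(gene = names(study$scores),
                           score = study$scores),
                file.path(idir, "scores.tsv"))
      writeDrugEffectTable(study$drugTable, file.path(idir, "drugs.tsv"))
      writeGmt(study$collection, file.path(idir, "annotation_sets.gmt"))
      .writeTsv(study$annotations, file.path(idir, "annotations.tsv"))
      .writeTsv(study$snps, file.path(idir, "snps.tsv"))
      .writeTsv(study$pgx, file.path(idir, "pgx.tsv"))
      study
    } else {
      ip <- config$inputs
      need <- c("interactome", "degs", "qtls", "scores", "gmt")
      miss <- setdiff(need, names(ip))
      if (length(miss))
        stopf("missing input path(s): %s", paste(miss, collapse = ", "))
      fmt <- if (grepl("\\.sif$", ip$interactome, ignore.case = TRUE))
        "SIF" else "TSV2"
      # the drug table and rubric annotations are read lazily by their own
      # stages, so earlier stages complete even if those files are missing
      list(interactome = readEdgeList(ip$interactome, fmt),
           degs = readDegTable(ip$degs),
           qtls = readGeneList(ip$qtls),
           scores = readExpressionScores(ip$scores),
           drugTable = NULL, drugsPath = ip$drugs,
           collection = readGmt(ip$gmt),
           annotations = NULL, annotationsPath = ip$annotations,
           snps = if (!is.null(ip$snps)) readSnpTable(ip$snps) else
             data.frame(variant = character(0), p = numeric(0)),
           pgx = if (!is.null(ip$pgx))
             utils::read.delim(ip$pgx, stringsAsFactors = FALSE) else
             data.frame(variant = character(0), drug = character(0)))
    }
  })

  # ---- assemble ----
  net <- stage("assemble", {
    seeds <- makeSeeds(dat$degs, dat$qtls)
    ls <- findLinkers(seeds, dat$interactome, maxPathLen = config$maxPathLen)
    network <- assembleNetwork(seeds, ls@linkers, dat$interactome)
    writeNetwork(network, file.path(out, "network.json"))
    deg <- table(factor(c(networkEdges(network)$from,
                          networkEdges(network)$to),
                        levels = networkGenes(network)))
    .writeTsv(data.frame(gene = networkGenes(network),
                         role = unname(nodeRoles(network)[networkGenes(network)]),
                         degree = as.integer(deg)),
              file.path(out, "network_nodes.tsv"))
    e <- networkEdges(network)
    writeLines(paste(e$from, ifelse(is.na(e$type), "interacts", e$type),
                     e$to, sep = "\t"),
               file.path(out, "network_edges.sif"))
    manifest$counts$assemble <- list(
      seeds = nrow(seeds), linkers = length(ls@linkers),
      networkNodes = length(networkGenes(network)),
      networkEdges = nrow(e), isolatedSeeds = length(ls@isolatedSeeds))
    network
  })

  # ---- topology ----
  report <- stage("topology", {
    rep <- computeCentralities(net)
    hubs <- flagHubs(rep, config$hubFraction)
    tab <- rep@nodes
    tab$is_hub <- tab$gene %in% hubs$hubNodes
    .writeTsv(tab, file.path(out, "topology_nodes.tsv"))
    etab <- rep@edges
    etab$is_hub <- pairKey(etab$from, etab$to) %in% hubs$hubEdges
    .writeTsv(etab, file.path(out, "topology_edges.tsv"))
    pl <- tryCatch(fitPowerLaw(rep),
                   error = function(e) list(exponent = NA, rSquared = NA,
                                            nDegreeBins = NA))
    manifest$counts$topology <- list(
      hubNodes = length(hubs$hubNodes), hubEdges = length(hubs$hubEdges),
      powerLawExponent = pl$exponent, powerLawR2 = pl$rSquared)
    rep
  })

  # ---- cluster ----
  modules <- stage("cluster", {
    ma <- spectralPartition(net)
    .writeTsv(data.frame(gene = names(moduleMembership(ma)),
                         module_id = unname(moduleMembership(ma))),
              file.path(out, "modules.tsv"))
    jsonlite::write_json(list(q = ma@modularityQ, nModules = ma@nModules,
                              sizes = as.integer(table(moduleMembership(ma)))),
                         file.path(out, "clustering.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$counts$cluster <- list(nModules = ma@nModules,
                                     modularityQ = ma@modularityQ)
    ma
  })

  # ---- enrich ----
  stage("enrich", {
    universe <- NULL  # default: collection genes
    queries <- list()
    if ("degs" %in% config$tiers) queries$degs <- dat$degs$gene
    if ("qtls" %in% config$tiers) queries$qtls <- dat$qtls
    if ("network" %in% config$tiers) queries$network <- networkGenes(net)
    if ("modules" %in% config$tiers) {
      mm <- moduleMembership(modules)
      for (id in sort(unique(mm)))
        queries[[sprintf("module_%02d", id)]] <- names(mm)[mm == id]
    }
    nSig <- list()
    for (tier in names(queries)) {
      res <- suppressMessages(enrich(queries[[tier]], dat$collection,
                                     universe, config$alpha))
      .writeTsv(res, file.path(out, sprintf("enrichment_%s.tsv", tier)))
      nSig[[tier]] <- sum(res$significant)
    }
    fullRes <- suppressMessages(enrich(networkGenes(net), dat$collection,
                                       universe, config$alpha))
    filtGenes <- suppressMessages(
      sensitivityFilter(networkGenes(net), dat$scores, config$skinThreshold))
    filtRes <- suppressMessages(enrich(filtGenes, dat$collection, universe,
                                       config$alpha))
    comp <- compareEnrichments(fullRes, filtRes, config$alpha)
    jsonlite::write_json(
      list(nGenesAboveThreshold = length(filtGenes),
           nSignificantFull = comp$nSignificantFull,
           nSignificantFiltered = comp$nSignificantFiltered,
           nRepeated = comp$nRepeated,
           fractionRepeated = comp$fractionRepeated),
      file.path(out, "sensitivity.json"), auto_unbox = TRUE, digits = NA)
    manifest$counts$enrich <- c(nSig,
                                 list(sensitivityFraction = comp$fractionRepeated))
    NULL
  })

  # ---- repurpose ----
  cand <- stage("repurpose", {
    if (is.null(dat$drugTable)) {
      if (is.null(dat$drugsPath))
        stopf("no drug-effect table configured")
      dat$drugTable <- readDrugEffectTable(dat$drugsPath)
    }
    tm <- mapTargets(net, dat$drugTable)
    prof <- reversalProfile(dat$degs, dat$drugTable)
    merged <- mergeCandidates(tm, prof)
    .writeTsv(merged, file.path(out, "candidates.tsv"))
    .writeTsv(reversalMatrix(dat$degs, dat$drugTable),
              file.path(out, "reversal_matrix.tsv"))
    sz <- lengths(prof$map)
    top3 <- names(sz)[order(-sz, names(sz))][seq_len(min(3, length(sz)))]
    cov <- if (length(top3)) combinationCoverage(prof, top3) else
      list(genes = character(0), size = 0)
    greedy <- if (length(prof$map)) greedyMaxCoverage(prof, 3) else character(0)
    pgxDrugs <- snpLookup(dat$snps, dat$pgx, config$gwasThreshold)
    jsonlite::write_json(
      list(topBySize = top3, topBySizeCoverage = cov$size,
           coveredGenes = cov$genes, greedyTop3 = greedy,
           pgxDrugs = pgxDrugs),
      file.path(out, "coverage.json"), digits = NA)
    manifest$counts$repurpose <- list(
      targetDrugs = tm$summary$nDrugs,
      mainGenesHit = tm$summary$nMainGenesHit,
      linkerGenesHit = tm$summary$nLinkerGenesHit,
      reversalDrugs = length(prof$map),
      uniqueCandidates = nrow(merged),
      top3Coverage = cov$size, pgxDrugs = length(pgxDrugs))
    merged
  })

  # ---- rank ----
  stage("rank", {
    if (is.null(dat$annotations)) {
      if (is.null(dat$annotationsPath))
        stopf("no drug-annotation table configured")
      dat$annotations <- readDrugAnnotations(dat$annotationsPath)
    }
    ann <- dat$annotations
    sec <- secondaryAnalysis(ann, config$rubric)
    .writeTsv(sec$primary@table, file.path(out, "ranked.tsv"))
    .writeTsv(sec$table, file.path(out, "ranking_secondary.tsv"))
    audit <- lapply(sec$primary@breakdowns, function(b)
      list(total = scoreTotal(b),
           applied = setNames(as.list(scoreApplied(b)$points),
                              scoreApplied(b)$criterion)))
    jsonlite::write_json(audit, file.path(out, "ranking_audit.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$counts$rank <- list(
      ranked = nrow(sec$primary@table),
      shortlist = length(sec$primary@shortlist),
      droppedWithoutPricing = length(sec$droppedFromShortlist))
    NULL
  })

  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
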