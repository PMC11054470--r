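targetTable <- function(drug, genes) {
  DrugEffectTable(rows = data.frame(drug = drug, gene = genes,
                                    kind = "TARGET", direction = "UNKNOWN"))
}

effectTable <- function(drug, gene, direction) {
  DrugEffectTable(rows = data.frame(drug = drug, gene = gene,
                                    kind = "EXPRESSION_EFFECT",
                                    direction = direction))
}

test_that("target mapping keeps only network genes", {
  net <- toyNetwork(toyEdges(c("X", "Y"), c("Y", "Z")))
  tm <- mapTargets(net, targetTable("D", c("X", "OUT")))
  expect_equal(tm$map$D, "X")
  expect_equal(tm$summary$nDrugs, 1)

  tm0 <- mapTargets(net, targetTable("D", "OUT"))
  expect_length(tm0$map, 0)
})

test_that("the published calcitriol target set maps intact", {
  genes <- promisingCandidates()$genes[[
    match("Calcitriol", promisingCandidates()$drug)]]
  chain <- c(genes, "STAT3")
  ia <- suppressMessages(Interactome(toyEdges(chain[-length(chain)],
                                              chain[-1])))
  net <- assembleNetwork(makeSeeds(genes), "STAT3", ia)
  tm <- mapTargets(net, targetTable("Calcitriol", c(genes, "ZZZOUT")))
  expect_equal(tm$map$Calcitriol,
               sort(c("BIRC3", "C1S", "S100A8", "SERPINB3", "SNTB1", "TNC")))
  expect_equal(length(tm$map$Calcitriol), 6)
})

test_that("reversal requires strictly opposing directions", {
  degs <- degTable(c("G1", "G2", "G3"), c("UP", "UP", "DOWN"))
  det <- effectTable("D", c("G1", "G2", "G3"),
                     c("DECREASE", "INCREASE", "UNKNOWN"))
  prof <- reversalProfile(degs, det)
  expect_equal(prof$map$D, "G1")

  # a drug with only aggravating rows is dropped entirely
  agg <- effectTable("D", "G1", "INCREASE")
  expect_length(reversalProfile(degs, agg)$map, 0)
})

test_that("the reversal rule is antisymmetric under global direction flips", {
  set.seed(17)
  genes <- sprintf("G%02d", 1:20)
  degs <- degTable(genes, sample(c("UP", "DOWN"), 20, TRUE))
  det <- effectTable(sample(c("D1", "D2", "D3"), 20, TRUE), genes,
                     sample(c("INCREASE", "DECREASE", "UNKNOWN"), 20, TRUE))
  flip <- function(x, a, b) ifelse(x == a, b, ifelse(x == b, a, x))
  degsF <- degTable(genes, flip(degs$direction, "UP", "DOWN"))
  rowsF <- drugEffects(det)
  rowsF$direction <- flip(rowsF$direction, "INCREASE", "DECREASE")
  expect_equal(reversalProfile(degs, det)$map,
               reversalProfile(degsF, DrugEffectTable(rows = rowsF))$map)
})

test_that("combination coverage reproduces the published three-drug union", {
  rs <- reversalGeneSets()
  expect_equal(unname(lengths(rs)), c(11, 11, 11))
  cov <- combinationCoverage(rs, names(rs))
  expect_equal(cov$size, 23)

  pair <- combinationCoverage(rs, c("Tretinoin", "Cyclosporine"))
  expect_equal(pair$size, 17)
  expect_equal(intersect(rs$Tretinoin, rs$Cyclosporine),
               c("LAPTM5", "LYZ", "S100A8", "S100A9", "TNC"))

  expect_equal(combinationCoverage(rs, "Tretinoin")$genes,
               sort(rs$Tretinoin))
  expect_error(combinationCoverage(rs, "Nonexistent"), "Nonexistent")
  # union dominance
  expect_gte(cov$size, max(lengths(rs)))
})

test_that("greedy coverage picks complementary drugs with guarantees", {
  map <- list(D1 = c("a", "b"), D2 = c("b", "c"), D3 = "c")
  expect_equal(greedyMaxCoverage(map, 2), c("D1", "D2"))
  expect_equal(greedyMaxCoverage(map, 1), "D1")
  expect_equal(greedyMaxCoverage(map, 10), c("D1", "D2", "D3"))
  expect_error(greedyMaxCoverage(map, 0), ">= 1")

  set.seed(23)
  for (rep in 1:5) {
    map <- lapply(setNames(1:8, sprintf("D%d", 1:8)), function(i)
      sample(letters, sample(2:8, 1)))
    for (k in 2:3) {
      got <- length(unique(unlist(map[greedyMaxCoverage(map, k)])))
      opt <- bruteMaxCoverage(map, k)
      expect_gte(got, ceiling((1 - 1 / exp(1)) * opt) - 1e-9)
    }
  }
})

test_that("candidate merging tracks provenance and exact cardinality", {
  tm <- list(map = list(D1 = "A"))
  prof <- list(map = list(D2 = "B"))
  merged <- mergeCandidates(tm, prof)
  expect_equal(merged$provenance[match(c("D1", "D2"), merged$drug)],
               c("TARGET", "REVERSAL"))

  both <- mergeCandidates(list(map = list(D1 = "A")),
                          list(map = list(D1 = "B")))
  expect_equal(both$provenance, "BOTH")
  expect_equal(nrow(both), 1)

  # 67 target drugs and 60 reversal drugs sharing 4 -> 123 unique
  tmap <- setNames(replicate(67, "A", simplify = FALSE),
                   sprintf("T%03d", 1:67))
  rmap <- setNames(replicate(60, "B", simplify = FALSE),
                   c(sprintf("T%03d", 1:4), sprintf("R%03d", 1:56)))
  m <- mergeCandidates(list(map = tmap), list(map = rmap))
  expect_equal(nrow(m), 123)
  expect_equal(sum(m$provenance == "BOTH"), 4)
})

test_that("SNP lookup applies the genome-wide threshold strictly", {
  pgx <- data.frame(variant = c("rs1", "rs2"), drug = c("D1", "D2"),
                    stringsAsFactors = FALSE)
  snps <- data.frame(variant = c("rs1", "rs2"), p = c(1e-9, 5e-8))
  expect_equal(snpLookup(snps, pgx), "D1")  # 5e-8 itself excluded
  empty <- data.frame(variant = character(0), drug = character(0))
  expect_equal(snpLookup(snps, empty), character(0))
})

test_that("planted reversal structure is recovered exactly", {
  for (m in c(1, 5, 11)) {
    spec <- synthesisSpec(seed = 40 + m, nDrugs = 12,
                          plantedReversal = c(PLANTED = m),
                          decoyReversalMax = max(0, min(m - 1, 3)))
    st <- genSyntheticStudy(spec)
    prof <- reversalProfile(st$degs, st$drugTable)
    expect_equal(length(prof$map$PLANTED), m)
    expect_equal(prof$map$PLANTED, sort(st$degs$gene[seq_len(m)]))
  }
})

test_that("the reversal matrix mirrors the profile", {
  degs <- degTable(c("G1", "G2"), c("UP", "DOWN"))
  det <- effectTable(c("D", "D"), c("G1", "G2"), c("DECREASE", "DECREASE"))
  rm <- reversalMatrix(degs, det)
  expect_equal(rm$G1, "reverses")
  expect_equal(rm$G2, "aggravates")
})
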