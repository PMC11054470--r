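test_that("betweenness matches closed forms on canonical graphs", {
  # 5-node star: the centre lies on all C(4,2) = 6 leaf pairs
  star <- toyNetwork(toyEdges(rep("X", 4), c("A", "B", "C", "D")))
  rep <- computeCentralities(star)
  btw <- setNames(rep@nodes$betweenness, rep@nodes$gene)
  expect_equal(unname(btw["X"]), 6)
  expect_equal(unname(btw[c("A", "B", "C", "D")]), rep(0, 4))

  # path A-B-C
  path <- toyNetwork(toyEdges(c("A", "B"), c("B", "C")))
  rep2 <- computeCentralities(path)
  expect_equal(rep2@nodes$betweenness[rep2@nodes$gene == "B"], 1)
  eb <- setNames(rep2@edges$betweenness, pk(rep2@edges$from, rep2@edges$to))
  expect_equal(unname(eb["A|B"]), 2)

  # two disconnected edges: no node lies between any pair
  two <- toyNetwork(toyEdges(c("A", "C"), c("B", "D")))
  expect_equal(computeCentralities(two)@nodes$betweenness, rep(0, 4))

  # isolated nodes get betweenness 0 rather than an error
  iso <- toyNetwork(toyEdges("A", "B"), extraNodes = "C")
  repIso <- computeCentralities(iso)
  expect_equal(repIso@nodes$betweenness[repIso@nodes$gene == "C"], 0)
})

test_that("betweenness equals the path-enumeration oracle on small graphs", {
  cases <- list(randomEdges(6, 0.4, 101), randomEdges(7, 0.3, 102),
                randomEdges(8, 0.3, 103), randomEdges(9, 0.25, 104),
                toyEdges(c("A", "B", "C", "A"), c("B", "C", "D", "D")))
  for (e in cases) {
    net <- toyNetwork(e)
    rep <- computeCentralities(net)
    oracle <- bruteBetweenness(networkEdges(net))
    got <- setNames(rep@nodes$betweenness, rep@nodes$gene)
    expect_equal(got[names(oracle$node)], oracle$node, tolerance = 1e-9)
    gotE <- setNames(rep@edges$betweenness, pk(rep@edges$from, rep@edges$to))
    expect_equal(gotE[names(oracle$edge)], oracle$edge, tolerance = 1e-9)
  }
})

test_that("degree sums are even and match twice the edge count", {
  net <- toyNetwork(randomEdges(9, 0.3, 7))
  rep <- computeCentralities(net)
  expect_equal(sum(rep@nodes$degree), 2 * nrow(networkEdges(net)))
})

test_that("hub flagging uses the floor rule with lexicographic tie-breaks", {
  mkReport <- function(deg) {
    CentralityReport(
      nodes = data.frame(gene = names(deg), role = "DEG",
                         degree = as.integer(deg),
                         betweenness = 0, stringsAsFactors = FALSE),
      edges = data.frame(from = character(0), to = character(0),
                         betweenness = numeric(0)))
  }
  # 78 nodes at 10% -> 7 hubs
  deg <- setNames(78:1, sprintf("G%02d", 1:78))
  expect_length(flagHubs(mkReport(deg), 0.10)$hubNodes, 7)
  # all-equal degrees -> the single lexicographically first node
  eq <- setNames(rep(3, 10), sprintf("N%02d", 10:1))
  expect_equal(flagHubs(mkReport(eq), 0.10)$hubNodes, "N01")
  # fraction 1.0 returns everything in score order
  expect_length(flagHubs(mkReport(deg), 1.0)$hubNodes, 78)
  expect_error(flagHubs(mkReport(deg), 0), "\\(0, 1\\]")
})

test_that("hub flagging is scale-invariant in the scores", {
  net <- toyNetwork(randomEdges(9, 0.35, 42))
  rep <- computeCentralities(net)
  scaled <- CentralityReport(
    nodes = transform(rep@nodes, degree = degree * 3L),
    edges = transform(rep@edges, betweenness = betweenness * 10))
  h1 <- flagHubs(rep, 0.25)
  h2 <- flagHubs(scaled, 0.25)
  expect_equal(h1$hubNodes, h2$hubNodes)
  expect_equal(h1$hubEdges, h2$hubEdges)
})

test_that("power-law fitting recovers an exact generating law", {
  # counts 4096 * k^-2 for k in {1, 2, 4, 8} lie exactly on a log-log line
  deg <- rep(c(1, 2, 4, 8), c(4096, 1024, 256, 64))
  fit <- fitPowerLaw(deg)
  expect_equal(fit$exponent, 2, tolerance = 1e-9)
  expect_equal(fit$rSquared, 1, tolerance = 1e-9)
  expect_equal(fit$nDegreeBins, 4)
})

test_that("degenerate degree distributions are rejected", {
  expect_error(fitPowerLaw(rep(4, 100)), "degenerate")
  ring <- toyNetwork(toyEdges(c("A", "B", "C"), c("B", "C", "A")))
  expect_error(fitPowerLaw(computeCentralities(ring)), "degenerate")
})

test_that("preferential-attachment graphs look scale-free to the diagnostic", {
  ia <- genInteractome(synthesisSpec(seed = 9, interactomeN = 500,
                                     attachmentM = 2))
  net <- assembleNetwork(makeSeeds(interactomeGenes(ia)), character(0), ia)
  fit <- fitPowerLaw(computeCentralities(net))
  expect_gte(fit$exponent, 1.5)
  expect_lte(fit$exponent, 3.5)
  expect_gt(fit$rSquared, 0.7)
})
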