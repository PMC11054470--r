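test_that("modularity matches closed forms and the textbook definition", {
  tri2 <- toyNetwork(toyEdges(c("A", "B", "C", "D", "E", "F"),
                              c("B", "C", "A", "E", "F", "D")))
  one <- setNames(rep(0L, 6), networkGenes(tri2))
  expect_equal(modularityQ(tri2, one), 0)
  split <- setNames(c(0, 0, 0, 1, 1, 1), c("A", "B", "C", "D", "E", "F"))
  expect_equal(modularityQ(tri2, split), 0.5)
  expect_error(modularityQ(tri2, split[-1]), "cover")

  for (seed in c(31, 32)) {
    net <- toyNetwork(randomEdges(8, 0.35, seed))
    set.seed(seed)
    assign <- setNames(sample(0:2, length(networkGenes(net)), TRUE),
                       networkGenes(net))
    expect_equal(modularityQ(net, assign),
                 modularityFromDef(networkEdges(net), assign),
                 tolerance = 1e-12)
  }
})

clique <- function(nodes) {
  p <- t(combn(nodes, 2))
  toyEdges(p[, 1], p[, 2])
}

test_that("spectral partition separates two bridged cliques", {
  e <- rbind(clique(c("A1", "A2", "A3", "A4")),
             clique(c("B1", "B2", "B3", "B4")),
             toyEdges("A1", "B1"))
  net <- toyNetwork(e)
  ma <- spectralPartition(net)
  expect_equal(ma@nModules, 2L)
  mm <- moduleMembership(ma)
  expect_length(unique(mm[c("A1", "A2", "A3", "A4")]), 1)
  expect_length(unique(mm[c("B1", "B2", "B3", "B4")]), 1)
  expect_gt(ma@modularityQ, 0.3)
})

test_that("a ring of three cliques yields the clique partition", {
  cl <- list(sprintf("A%d", 1:5), sprintf("B%d", 1:5), sprintf("C%d", 1:5))
  e <- rbind(clique(cl[[1]]), clique(cl[[2]]), clique(cl[[3]]),
             toyEdges(c("A1", "B1", "C1"), c("B2", "C2", "A2")))
  net <- toyNetwork(e)
  ma <- spectralPartition(net)
  expect_equal(ma@nModules, 3L)
  mm <- moduleMembership(ma)
  for (g in cl) expect_length(unique(mm[g]), 1)
  # agrees with direct evaluation of the clique partition, and beats merges
  expect_equal(ma@modularityQ, modularityQ(net, mm), tolerance = 1e-12)
  merged <- mm; merged[cl[[2]]] <- merged[cl[[1]]][1]
  expect_gt(ma@modularityQ, modularityQ(net, merged))
})

test_that("spectral Q is non-negative and near the exhaustive optimum on small graphs", {
  for (seed in c(51, 52, 53)) {
    net <- toyNetwork(randomEdges(8, 0.35, seed))
    ma <- spectralPartition(net)
    expect_gte(ma@modularityQ, 0)
    opt <- bruteMaxQ(networkEdges(net), networkGenes(net))
    expect_lte(ma@modularityQ, opt + 1e-9)
    expect_gte(ma@modularityQ, opt - 0.05)
  }
})

test_that("partitioning is invariant to node input order", {
  e <- randomEdges(9, 0.3, 61)
  net1 <- toyNetwork(e)
  net2 <- toyNetwork(e[sample(nrow(e)), ])
  m1 <- moduleMembership(spectralPartition(net1))
  m2 <- moduleMembership(spectralPartition(net2))
  expect_equal(m1, m2[names(m1)])
})

test_that("random assignments never beat the spectral partition", {
  net <- toyNetwork(randomEdges(10, 0.3, 71))
  q <- spectralPartition(net)@modularityQ
  set.seed(71)
  for (i in 1:25) {
    ra <- setNames(sample(0:3, length(networkGenes(net)), TRUE),
                   networkGenes(net))
    expect_lte(modularityQ(net, ra), q + 1e-9)
  }
})

test_that("isolated nodes share one dedicated module", {
  net <- toyNetwork(toyEdges(c("A", "B"), c("B", "C")),
                    extraNodes = c("X", "Y"))
  ma <- spectralPartition(net)
  mm <- moduleMembership(ma)
  expect_equal(mm[["X"]], mm[["Y"]])
  expect_false(mm[["X"]] %in% mm[c("A", "B", "C")])
})

test_that("the leading-eigenvector implementation agrees with an independent one", {
  e <- rbind(clique(sprintf("A%d", 1:5)), clique(sprintf("B%d", 1:5)),
             clique(sprintf("C%d", 1:4)),
             toyEdges(c("A1", "B1"), c("B2", "C1")))
  net <- toyNetwork(e)
  ours <- spectralPartition(net)
  g <- igraph::graph_from_data_frame(networkEdges(net)[, 1:2],
                                     directed = FALSE)
  ref <- igraph::cluster_leading_eigen(g)
  expect_equal(ours@modularityQ,
               igraph::modularity(g, igraph::membership(ref)),
               tolerance = 0.05)
})
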