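test_that("hypergeometric tail matches hand calculations and degenerate cases", {
  expect_equal(hypergeomP(0, 4, 3, 10), 1.0)
  expect_equal(hypergeomP(3, 4, 3, 10), 4 / 120, tolerance = 1e-12)
  expect_equal(hypergeomP(5, 5, 5, 5), 1.0)
  expect_error(hypergeomP(4, 3, 4, 10), "bounds")
  expect_error(hypergeomP(1, 11, 2, 10), "bounds")
})

test_that("hypergeometric tail equals draw enumeration for small universes", {
  for (N in c(8, 10, 12)) {
    for (K in c(2, 4, N %/% 2)) {
      for (n in c(3, 5)) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeomP(k, K, n, N), hypergeomEnum(k, K, n, N),
                       tolerance = 1e-12,
                       label = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
})

plantedCollection <- function(universe, query, overlap = 15, size = 20,
                              nRandom = 25, seed = 5) {
  set.seed(seed)
  sets <- lapply(seq_len(nRandom), function(i) sample(universe, 30))
  names(sets) <- sprintf("R%02d", seq_len(nRandom))
  sets$PLANTED <- c(sample(query, overlap),
                    sample(setdiff(universe, query), size - overlap))
  AnnotationCollection(category = "toy", sets = sets)
}

test_that("a strongly planted set attains the minimum q-value", {
  universe <- sprintf("U%04d", 1:1000)
  query <- universe[1:20]
  col <- plantedCollection(universe, query)
  res <- enrich(query, col, universe)
  expect_equal(res$set_name[1], "PLANTED")
  expect_lt(res$q_value[1], 0.05)
  expect_equal(res$overlap_k[1], 15)
  direct <- hypergeomP(15, 20, 20, 1000)
  expect_equal(res$p_value[1], direct, tolerance = 1e-12)
})

test_that("disjoint queries and permissive alpha behave at the boundaries", {
  universe <- sprintf("U%04d", 1:200)
  col <- AnnotationCollection(category = "c",
                              sets = list(S1 = universe[1:10],
                                          S2 = universe[11:30]))
  res <- enrich(universe[150:160], col, universe)
  expect_equal(nrow(res), 0)

  res2 <- enrich(universe[1:12], col, universe, alpha = 1.0)
  expect_true(all(res2$significant))
})

test_that("q-values respect BH monotonicity and set-order invariance", {
  universe <- sprintf("U%04d", 1:500)
  query <- universe[1:25]
  col <- plantedCollection(universe, query, seed = 6)
  res <- enrich(query, col, universe)
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  sets <- geneSets(col)
  colRev <- AnnotationCollection(category = "toy", sets = rev(sets))
  res2 <- enrich(query, colRev, universe)
  expect_equal(res[order(res$set_name), ]$q_value,
               res2[order(res2$set_name), ]$q_value)
})

test_that("genes outside the universe are dropped with a message", {
  universe <- sprintf("U%04d", 1:100)
  col <- AnnotationCollection(category = "c", sets = list(S = universe[1:10]))
  expect_message(enrich(c(universe[1:5], "ZZZZ"), col, universe), "outside")
  expect_error(enrich("A", col, character(0)), "empty universe")
})

test_that("the expression filter is strict at the threshold", {
  sc <- c(A = 3.0, B = 2.5, C = 1.0)
  expect_equal(sensitivityFilter(c("A", "B", "C"), sc), "A")
  expect_equal(sensitivityFilter(c("A", "B", "C"), sc + 10),
               c("A", "B", "C"))
  expect_message(out <- sensitivityFilter(c("A", "D"), sc), "without")
  expect_equal(out, "A")
})

test_that("sensitivity comparison reports repeated-term fractions", {
  mkRes <- function(names, q) {
    n <- length(names)
    data.frame(category = rep("c", n), set_name = names,
               overlap_k = rep(1, n), set_size_K = rep(10, n),
               query_size_n = rep(5, n), universe_N = rep(100, n),
               p_value = q, q_value = q, significant = q < 0.05,
               overlap_genes = rep("", n), stringsAsFactors = FALSE)
  }
  full <- mkRes(sprintf("S%02d", 1:50), rep(0.01, 50))
  expect_equal(compareEnrichments(full, full)$fractionRepeated, 1.0)
  empty <- mkRes(character(0), numeric(0))
  expect_equal(compareEnrichments(full, empty)$fractionRepeated, 0.0)
  # 42 of 50 significant terms recur: fraction 0.84
  filtered <- mkRes(sprintf("S%02d", 1:42), rep(0.01, 42))
  cmp <- compareEnrichments(full, filtered)
  expect_equal(cmp$nRepeated, 42)
  expect_equal(cmp$fractionRepeated, 0.84)
  expect_true(cmp$topTermPreserved[["c"]])
})

test_that("BH keeps the false discovery rate near nominal under the null", {
  # small simulation here; the full 1000-replicate check runs with the
  # acceptance suite
  universe <- sprintf("U%03d", 1:300)
  set.seed(99)
  fdp <- replicate(200, {
    sets <- lapply(1:15, function(i) sample(universe, 25))
    names(sets) <- sprintf("S%02d", 1:15)
    col <- AnnotationCollection(category = "null", sets = sets)
    res <- enrich(sample(universe, 20), col, universe, alpha = 0.05)
    r <- sum(res$significant)
    if (r == 0) 0 else 1
  })
  expect_lte(mean(fdp), 0.12)
})
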