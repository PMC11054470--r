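neutral <- function(drug = "x", ...) drugAnnotation(drug, ...)

test_that("each rubric criterion contributes its published points in isolation", {
  cases <- list(
    list(neutral(immunomodGeneral = TRUE), 1),
    list(neutral(immunomodSkin = TRUE), 2),
    list(neutral(nNetworkTargets = 5), 1),
    list(neutral(nNetworkTargets = 3), 0),   # strictly more than 3
    list(neutral(topicalPossible = TRUE), 1),
    list(neutral(whoEssential = TRUE), 1),
    list(neutral(priceBand = "LOW"), 1),
    list(neutral(priceBand = "VERY_LOW"), 2),
    list(neutral(priceBand = "VERY_HIGH"), -1),
    list(neutral(priceBand = "UNAVAILABLE"), -1),
    list(neutral(hasAtc = FALSE), -2),
    list(neutral(orderable = FALSE), -1),
    list(neutral(directionClear = FALSE), -1),
    list(neutral(grade3to5Risk = TRUE), -1),
    list(neutral(practicalIssue = "ISSUE"), -1),
    list(neutral(practicalIssue = "SEVERE"), -2),
    list(neutral(), 0))
  for (cs in cases)
    expect_equal(scoreTotal(scoreDrug(cs[[1]])), cs[[2]],
                 label = paste(unlist(cs[[1]]), collapse = "/"))
})

test_that("skin immunomodulation dominates the general criterion", {
  b <- scoreDrug(neutral(immunomodGeneral = TRUE, immunomodSkin = TRUE))
  expect_equal(scoreTotal(b), 2)
  expect_equal(scoreApplied(b)$criterion, "immunomod_skin")
})

test_that("totals decompose into applied criteria and respect exhaustive bounds", {
  combos <- expand.grid(
    immunomodGeneral = c(TRUE, FALSE), immunomodSkin = c(TRUE, FALSE),
    nNetworkTargets = c(0, 5), topicalPossible = c(TRUE, FALSE),
    whoEssential = c(TRUE, FALSE),
    priceBand = c("VERY_LOW", "LOW", "MID", "VERY_HIGH", "UNAVAILABLE"),
    hasAtc = c(TRUE, FALSE), orderable = c(TRUE, FALSE),
    directionClear = c(TRUE, FALSE), grade3to5Risk = c(TRUE, FALSE),
    practicalIssue = c("NONE", "ISSUE", "SEVERE"),
    stringsAsFactors = FALSE)
  cfgOn <- rubricConfig()
  cfgOff <- rubricConfig(pricingEnabled = FALSE)
  totOn <- totOff <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ann <- do.call(drugAnnotation, c(list(drug = "x"), as.list(combos[i, ])))
    bOn <- scoreDrug(ann, cfgOn)
    expect_equal(scoreTotal(bOn), sum(scoreApplied(bOn)$points))
    totOn[i] <- scoreTotal(bOn)
    totOff[i] <- scoreTotal(scoreDrug(ann, cfgOff))
  }
  expect_equal(range(totOn), c(-8, 7))
  expect_equal(range(totOff), c(-7, 5))
})

test_that("bonuses never decrease and penalties never increase a total", {
  set.seed(77)
  for (i in 1:20) {
    ann <- neutral(
      immunomodGeneral = runif(1) < 0.5, nNetworkTargets = sample(0:6, 1),
      topicalPossible = runif(1) < 0.5, whoEssential = runif(1) < 0.5,
      priceBand = sample(c("VERY_LOW", "LOW", "MID", "VERY_HIGH"), 1),
      hasAtc = runif(1) < 0.5, orderable = runif(1) < 0.5,
      grade3to5Risk = runif(1) < 0.5)
    base <- scoreTotal(scoreDrug(ann))
    up <- ann; up$whoEssential <- TRUE
    expect_gte(scoreTotal(scoreDrug(up)), base)
    down <- ann; down$grade3to5Risk <- TRUE
    expect_lte(scoreTotal(scoreDrug(down)), base)
  }
})

test_that("price bands follow the published boundaries", {
  expect_equal(priceBand(c(10, 50, 500, 501, 20000, 20001, NA)),
               c("VERY_LOW", "LOW", "LOW", "MID", "MID", "VERY_HIGH",
                 "UNAVAILABLE"))
})

test_that("incomplete annotations are rejected by name", {
  ann <- neutral()
  ann$orderable <- NA
  expect_error(scoreDrug(ann), "orderable")
})

test_that("ranking sorts by total and shortlists strictly positive scores", {
  anns <- rbind(neutral("good", immunomodSkin = TRUE, topicalPossible = TRUE),
                neutral("zero"),
                neutral("bad", hasAtc = FALSE))
  rl <- rankDrugs(anns)
  expect_equal(rl@table$drug, c("good", "zero", "bad"))
  expect_equal(rl@shortlist, "good")  # a total of exactly 0 is excluded
  expect_error(rankDrugs(rbind(neutral("a"), neutral("a"))), "duplicate")
})

test_that("disabling pricing equals zeroing the pricing points", {
  zeroed <- rubricConfig(points = c(price_low = 0, price_very_low = 0,
                                    price_penalty = 0))
  set.seed(78)
  for (i in 1:20) {
    ann <- neutral(priceBand = sample(c("VERY_LOW", "LOW", "MID",
                                        "VERY_HIGH", "UNAVAILABLE"), 1),
                   whoEssential = runif(1) < 0.5,
                   grade3to5Risk = runif(1) < 0.5)
    expect_equal(
      scoreTotal(scoreDrug(ann, rubricConfig(pricingEnabled = FALSE))),
      scoreTotal(scoreDrug(ann, zeroed)))
  }
})

test_that("the no-pricing secondary analysis drops pricing-carried drugs", {
  irb <- neutral("Irbesartan", priceBand = "VERY_LOW")
  expect_equal(scoreTotal(scoreDrug(irb)), 2)
  sec <- secondaryAnalysis(rbind(irb, neutral("other", immunomodSkin = TRUE)))
  expect_equal(sec$droppedFromShortlist, "Irbesartan")
  expect_equal(sec$table$totalNoPricing[sec$table$drug == "Irbesartan"], 0)
  expect_equal(sec$table$delta[sec$table$drug == "other"], 0)

  # a pricing-penalty-only drug rises to 0 but still misses the shortlist
  pen <- neutral("pen", priceBand = "VERY_HIGH")
  sec2 <- secondaryAnalysis(rbind(pen, neutral("filler", topicalPossible = TRUE)))
  expect_equal(sec2$table$totalNoPricing[sec2$table$drug == "pen"], 0)
  expect_false("pen" %in% sec2$noPricing@shortlist)
})

test_that("reconstructed annotations reproduce the published ranking", {
  pc <- promisingCandidates()
  expect_equal(nrow(pc), 46)
  ann <- reconstructRankingAnnotations(pc)
  rl <- rankDrugs(ann)
  expect_equal(setNames(rl@table$total, rl@table$drug)[pc$drug],
               setNames(pc$score, pc$drug))
  # every published drug scores > 0, i.e. the whole table is the shortlist
  expect_setequal(rl@shortlist, pc$drug)
  sec <- secondaryAnalysis(ann)
  expect_setequal(sec$droppedFromShortlist,
                  c("Irbesartan", "Rosuvastatin", "Saxagliptin",
                    "Silicon dioxide"))
})
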