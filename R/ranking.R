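#' Default drug-ranking rubric
#'
#' Bonus criteria: immunomodulating efficacy in inflammatory/auto-immune
#' diseases (+1) or specifically in such skin diseases (+2; the two are
#' mutually exclusive with the skin criterion dominating), more than three
#' network target genes (+1), topical application possible (+1), WHO
#' essential-medicines listing (+1), low annual price 50-500 EUR (+1) or
#' very low < 50 EUR (+2; bands disjoint). Penalty criteria: no ATC code
#' (-2), not orderable (-1), unclear direction of effect (-1), 0.1-1% risk
#' of grade 3-5 adverse events (-1), practical issues (-1) or severe
#' practical issues (-2; worst applies), price unavailable or very
#' expensive > 20000 EUR/year (-1). With all criteria active the total lies
#' between -8 and +7; with pricing disabled between -7 and +5.
#'
#' Band-edge convention: 50 and 500 EUR/year belong to the LOW band, 20000
#' to MID.
#'
#' @param pricingEnabled If `FALSE`, every pricing criterion contributes 0
#'   (the secondary-analysis mode).
#' @param points Optional named replacement of individual criterion points.
#' @return A [RubricConfig-class].
#' @examples
#' rubricConfig()
#' rubricConfig(pricingEnabled = FALSE)
#' @export
rubricConfig <- function(pricingEnabled = TRUE, points = NULL) {
  p <- c(immunomod_general = 1, immunomod_skin = 2, network_targets = 1,
         topical = 1, who_essential = 1, price_low = 1, price_very_low = 2,
         no_atc = -2, not_orderable = -1, unclear_direction = -1,
         grade3to5_ae = -1, practical_issue = -1, severe_practical_issue = -2,
         price_penalty = -1)
  if (!is.null(points)) {
    bad <- setdiff(names(points), names(p))
    if (length(bad)) stopf("unknown criterion: %s", paste(bad, collapse = ", "))
    p[names(points)] <- points
  }
  RubricConfig(points = p, pricingEnabled = isTRUE(pricingEnabled),
               bands = c(veryLowMax = 50, lowMax = 500, veryHighMin = 20000))
}

#' Price band from annual cost
#'
#' `< 50` EUR/year is `VERY_LOW`; `[50, 500]` is `LOW`; `(500, 20000]` is
#' `MID` (no points); `> 20000` is `VERY_HIGH`. An unknown cost is
#' `UNAVAILABLE`.
#'
#' @param annualCostEur Numeric annual cost in EUR, or `NA`.
#' @param config A [RubricConfig-class] carrying the band boundaries.
#' @return One of `"VERY_LOW"`, `"LOW"`, `"MID"`, `"VERY_HIGH"`,
#'   `"UNAVAILABLE"`.
#' @export
priceBand <- function(annualCostEur, config = rubricConfig()) {
  b <- config@bands
  vapply(annualCostEur, function(x) {
    if (is.na(x)) "UNAVAILABLE"
    else if (x < b[["veryLowMax"]]) "VERY_LOW"
    else if (x <= b[["lowMax"]]) "LOW"
    else if (x <= b[["veryHighMin"]]) "MID"
    else "VERY_HIGH"
  }, character(1))
}

#' Construct a per-drug criterion annotation
#'
#' One record of the evidence needed to score a drug: the literature-curated
#' criterion flags. Every field must be set; scoring refuses incomplete
#' annotations.
#'
#' @param drug Drug label.
#' @param immunomodGeneral Immunomodulating efficacy in inflammatory or
#'   auto-immune disease (completed phase 2 plus ongoing phase 3).
#' @param immunomodSkin As above but in skin disease (dominates the general
#'   flag).
#' @param nNetworkTargets Number of network genes the drug physically
#'   targets.
#' @param topicalPossible Topical application or compounding possible.
#' @param whoEssential On the WHO essential-medicines list.
#' @param priceBand One of `VERY_LOW`, `LOW`, `MID`, `VERY_HIGH`,
#'   `UNAVAILABLE`.
#' @param hasAtc Has an ATC code.
#' @param orderable Available for order.
#' @param directionClear Direction of effect on genes is clear.
#' @param grade3to5Risk 0.1-1% chance of grade 3-5 adverse events.
#' @param practicalIssue One of `NONE`, `ISSUE`, `SEVERE`.
#' @return One-row `data.frame`.
#' @examples
#' drugAnnotation("irbesartan", priceBand = "VERY_LOW")
#' @export
drugAnnotation <- function(drug,
                           immunomodGeneral = FALSE, immunomodSkin = FALSE,
                           nNetworkTargets = 0, topicalPossible = FALSE,
                           whoEssential = FALSE, priceBand = "MID",
                           hasAtc = TRUE, orderable = TRUE,
                           directionClear = TRUE, grade3to5Risk = FALSE,
                           practicalIssue = "NONE") {
  priceBand <- toupper(as.character(priceBand))
  practicalIssue <- toupper(as.character(practicalIssue))
  if (!priceBand %in% c("VERY_LOW", "LOW", "MID", "VERY_HIGH", "UNAVAILABLE"))
    stopf("invalid priceBand '%s'", priceBand)
  if (!practicalIssue %in% c("NONE", "ISSUE", "SEVERE"))
    stopf("invalid practicalIssue '%s'", practicalIssue)
  data.frame(drug = as.character(drug),
             immunomodGeneral = as.logical(immunomodGeneral),
             immunomodSkin = as.logical(immunomodSkin),
             nNetworkTargets = as.numeric(nNetworkTargets),
             topicalPossible = as.logical(topicalPossible),
             whoEssential = as.logical(whoEssential),
             priceBand = priceBand, hasAtc = as.logical(hasAtc),
             orderable = as.logical(orderable),
             directionClear = as.logical(directionClear),
             grade3to5Risk = as.logical(grade3to5Risk),
             practicalIssue = practicalIssue, stringsAsFactors = FALSE)
}

#' Score one drug against the rubric
#'
#' Applies every active criterion to the annotation and returns the applied
#' points with their total. Exclusivity rules: skin immunomodulation
#' dominates the general criterion (they never stack); the price bands are
#' disjoint; `SEVERE` practical issues replace plain issues. The
#' unavailable-price penalty is independent of the separate not-orderable
#' penalty. With pricing disabled, price criteria are skipped entirely.
#'
#' @param annotation A one-row `data.frame` or named list from
#'   [drugAnnotation]; every field must be present and non-missing.
#' @param config A [RubricConfig-class].
#' @return A [ScoreBreakdown-class].
#' @examples
#' scoreTotal(scoreDrug(drugAnnotation("x", immunomodSkin = TRUE)))      # 2
#' scoreTotal(scoreDrug(drugAnnotation("x", nNetworkTargets = 5)))       # 1
#' scoreTotal(scoreDrug(drugAnnotation("x", hasAtc = FALSE)))            # -2
#' @export
scoreDrug <- function(annotation, config = rubricConfig()) {
  a <- as.list(annotation)
  for (f in .annotationCols) {
    if (is.null(a[[f]]) || is.na(a[[f]]))
      stopf("annotation field missing or NA: %s", f)
  }
  pts <- config@points
  applied <- list()
  add <- function(criterion) {
    applied[[length(applied) + 1L]] <<- list(criterion = criterion,
                                             points = unname(pts[criterion]))
  }
  if (isTRUE(a$immunomodSkin)) add("immunomod_skin")
  else if (isTRUE(a$immunomodGeneral)) add("immunomod_general")
  if (a$nNetworkTargets > 3) add("network_targets")
  if (isTRUE(a$topicalPossible)) add("topical")
  if (isTRUE(a$whoEssential)) add("who_essential")
  if (config@pricingEnabled) {
    if (a$priceBand == "VERY_LOW") add("price_very_low")
    else if (a$priceBand == "LOW") add("price_low")
    else if (a$priceBand %in% c("VERY_HIGH", "UNAVAILABLE")) add("price_penalty")
  }
  if (!isTRUE(a$hasAtc)) add("no_atc")
  if (!isTRUE(a$orderable)) add("not_orderable")
  if (!isTRUE(a$directionClear)) add("unclear_direction")
  if (isTRUE(a$grade3to5Risk)) add("grade3to5_ae")
  if (a$practicalIssue == "SEVERE") add("severe_practical_issue")
  else if (a$practicalIssue == "ISSUE") add("practical_issue")
  df <- if (length(applied)) {
    data.frame(criterion = vapply(applied, `[[`, character(1), "criterion"),
               points = vapply(applied, `[[`, numeric(1), "points"),
               stringsAsFactors = FALSE)
  } else data.frame(criterion = character(0), points = numeric(0))
  ScoreBreakdown(drug = a$drug, applied = df, total = sum(df$points))
}

#' Rank annotated drugs by rubric score
#'
#' Scores every drug, orders by total (descending, ties by name) and
#' extracts the shortlist of drugs with a strictly positive total.
#'
#' @param annotations `data.frame` of annotations (one row per drug, unique
#'   drugs).
#' @param config A [RubricConfig-class].
#' @return A [RankedList-class].
#' @export
rankDrugs <- function(annotations, config = rubricConfig()) {
  if (!nrow(annotations)) stopf("annotations must be non-empty")
  if (anyDuplicated(annotations$drug))
    stopf("duplicate drug(s): %s",
          paste(unique(annotations$drug[duplicated(annotations$drug)]),
                collapse = ", "))
  br <- lapply(seq_len(nrow(annotations)), function(i)
    scoreDrug(annotations[i, , drop = FALSE], config))
  names(br) <- annotations$drug
  tab <- data.frame(drug = annotations$drug,
                    total = vapply(br, scoreTotal, numeric(1)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$total, tab$drug), , drop = FALSE]
  rownames(tab) <- NULL
  RankedList(breakdowns = br[tab$drug], table = tab,
             shortlist = tab$drug[tab$total > 0])
}

#' Secondary analysis: ranking without pricing criteria
#'
#' Re-runs the ranking with every pricing criterion disabled and reports
#' per-drug score deltas and the drugs that drop off the score > 0
#' shortlist once cost considerations are removed.
#'
#' @param annotations `data.frame` of annotations.
#' @param config Primary-mode [RubricConfig-class] (pricing enabled).
#' @return List with `table` (`data.frame`: drug, totalPrimary,
#'   totalNoPricing, delta, dropped), `droppedFromShortlist`, and the two
#'   [RankedList-class] objects (`primary`, `noPricing`).
#' @export
secondaryAnalysis <- function(annotations, config = rubricConfig()) {
  noPriceCfg <- RubricConfig(points = config@points, pricingEnabled = FALSE,
                             bands = config@bands)
  primary <- rankDrugs(annotations, config)
  secondary <- rankDrugs(annotations, noPriceCfg)
  t1 <- setNames(primary@table$total, primary@table$drug)
  t2 <- setNames(secondary@table$total, secondary@table$drug)
  drugs <- sort(names(t1))
  dropped <- drugs[t1[drugs] > 0 & t2[drugs] <= 0]
  tab <- data.frame(drug = drugs, totalPrimary = unname(t1[drugs]),
                    totalNoPricing = unname(t2[drugs]),
                    delta = unname(t2[drugs] - t1[drugs]),
                    dropped = drugs %in% dropped, stringsAsFactors = FALSE)
  list(table = tab, droppedFromShortlist = dropped,
       primary = primary, noPricing = secondary)
}
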