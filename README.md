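# vheRx

Network-guided drug repurposing for vesicular hand eczema (VHE).

Severe chronic hand eczema has a single approved systemic therapy in the EU
(alitretinoin), and the vesicular subtype responds to it poorly. `vheRx`
implements, as a tested and reusable R pipeline, a transcriptomics- and
genomics-guided strategy for finding repurposing candidates: disease seed
genes are joined into a functional network, the network's biology is
characterised, drugs are matched against it two ways (physical targets and
expression-signature reversal), and the resulting candidates are ranked with
a transparent multi-criteria rubric. It is aimed at computational
dermatology / systems-biology groups who want to re-run, stress-test or
adapt this class of repurposing analysis with their own gene lists,
interactomes and drug tables.

## The method

**Network assembly.** Seeds are differentially expressed genes (DEGs, each
with an up/down direction) plus QTL genes from a GWAS locus. Over a
reference interactome G, a minimal set of *linker* genes L is added so that
all covered seeds fall in one connected component — a greedy Steiner-style
search that repeatedly adds the non-seed gene joining the most seed
components (ties: lower degree, then lexicographic), bridges stalled
configurations along shortest interactome paths, and prunes redundant
linkers. Seeds with no interactome coverage are kept as isolated nodes.

**Topology and modules.** Node degree k(v) and unnormalized shortest-path
betweenness g(v) = Σ_{s≠v≠t} σ_st(v)/σ_st flag hub genes and hub
interactions at a top-10% rule (floor, minimum 1, lexicographic
tie-breaks); a log–log least-squares fit of the degree histogram checks the
scale-free shape expected of real biological networks. Functional modules
come from Newman's leading-eigenvector spectral partition of the modularity
matrix B = A − kkᵀ/2m, accepting each bisection only when
ΔQ = sᵀB_g s / 4m > 0, with deterministic sign and degeneracy conventions.

**Enrichment.** Gene lists (DEGs, QTL genes, whole network, each module)
are tested against GMT annotation collections with the one-sided
hypergeometric tail P(X ≥ k), X ~ Hypergeom(N, K, n), and per-category
Benjamini–Hochberg q-values (significant: q < 0.05). A sensitivity
re-analysis repeats enrichment on the genes with skin-expression score
> 2.5 and reports the fraction of significant terms that recur.

**Drug matching.** A drug *reverses* a DEG when its expression effect
opposes the disease direction (UP↔DECREASE, DOWN↔INCREASE; UNKNOWN never
counts). Per-drug reversal sets support combination coverage (set union)
and a greedy maximum-coverage selector with the usual (1 − 1/e) guarantee.
Physical-target matches against network genes and reversal matches merge
into one provenance-tagged candidate list; a pharmaco-genomics lookup joins
genome-wide-significant SNPs (p < 5×10⁻⁸) to drug interactions.

**Ranking.** Each candidate is scored by a bonus/penalty rubric
(immunomodulation in skin disease +2 or general +1, >3 network targets +1,
topical use +1, WHO essential medicine +1, price very low +2 / low +1; no
ATC code −2, not orderable −1, unclear effect direction −1, grade 3–5
adverse-event risk −1, practical issues −1/−2, price unavailable or very
high −1). The shortlist is every drug with total > 0; a secondary analysis
re-ranks with all pricing criteria disabled.

## Worked example

The synthetic-study generator emulates the full study shape (52 DEGs + 3
QTL genes, 9 without interactome coverage, 23 planted linkers, three
planted reversal drugs):

```r
library(vheRx)
study <- genSyntheticStudy(synthesisSpec(seed = 42))
seeds <- makeSeeds(study$degs, study$qtls)
(linkers <- findLinkers(seeds, study$interactome))
#> LinkerSearchResult: 23 linker(s), seed components 24 -> 1, 9 isolated seed(s)
(net <- assembleNetwork(seeds, linkers@linkers, study$interactome))
#> GeneNetwork: 78 genes (DEG=52, LINKER=23, QTL=3), 68 edges, 9 isolated seed(s)
spectralPartition(net)
#> ModuleAssignment: 9 modules (sizes 12, 10, 9, 9, 9, 8, 8, 7, 6), Q = 0.7678
prof <- reversalProfile(study$degs, study$drugTable)
combinationCoverage(prof, greedyMaxCoverage(prof, 3))$size
#> [1] 24
```

The linker search reports 23 linkers joining 24 seed components into one;
the assembled network holds all 78 genes (isolated seeds retained at degree
0); spectral clustering finds 9 modules at modularity Q = 0.77; and the
best 3-drug combination reverses 24 of the 52 DEGs. On the published gene
lists the three strongest reversal drugs cover 11 DEGs each and 23 jointly:

```r
rs <- reversalGeneSets()
lengths(rs)
#>       Tretinoin    Cyclosporine Silicon dioxide
#>              11              11              11
combinationCoverage(rs, names(rs))$size
#> [1] 23
```

Scoring a drug shows the full audit trail:

```r
irbesartan <- drugAnnotation("Irbesartan", priceBand = "VERY_LOW")
scoreDrug(irbesartan)
#> ScoreBreakdown for 'Irbesartan': total +2
#>   +2  price_very_low
scoreTotal(scoreDrug(irbesartan, rubricConfig(pricingEnabled = FALSE)))
#> [1] 0
```

A drug carried only by its very-low-price bonus scores 2 with pricing
enabled and 0 without — exactly the behaviour of the published secondary
analysis. `runPipeline(pipelineConfig(outDir, synthSpec = synthesisSpec()))`
executes every stage end-to-end and writes TSV/JSON artifacts plus a run
manifest.

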