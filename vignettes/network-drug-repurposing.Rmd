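---
title: "Methods: network-guided drug repurposing for vesicular hand eczema"
author: "vheRx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-guided drug repurposing for vesicular hand eczema}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vheRx)
```

# Overview

`vheRx` chains six analysis stages into one workflow for hypothesis-level
drug repurposing in vesicular hand eczema (VHE): disease-network assembly,
topology analysis, spectral module detection, functional enrichment,
drug--gene matching, and rubric-based candidate ranking. This vignette
documents the modelling choices, the parameters that matter, the numerical
conventions, and what the bundled synthetic data can and cannot show.

The pipeline operates at the level of HGNC-style gene symbols, upper-cased,
with no alias resolution. That is a deliberate simplification: the
upstream resources it emulates (interactome exports, DEG tables, drug--gene
tables) already speak symbols, and an ID-mapping service would add a heavy
dependency for little analytical gain. The cost is that symbol drift
between resources silently reduces overlap; users mixing annotation
vintages should harmonise symbols beforehand.

# Network assembly

Seeds are of two kinds: differentially expressed genes (DEGs), each
carrying a mandatory `UP`/`DOWN` direction, and QTL genes from a
disease-associated locus. A gene in both lists keeps the DEG origin and is
counted once. Seeds are projected onto a reference interactome, treated as
an undirected simple graph even where the source annotates direction --
topology measures on a mixed directed/undirected graph would otherwise
depend on annotation coverage rather than biology. Direction labels are
retained for display.

## Linker search

The interactome rarely connects all seeds directly, so `findLinkers()`
adds *linker* genes: non-seed genes recruited purely to join seed
components. The search is a greedy Steiner-tree approximation:

1. Candidates are non-seed genes within `maxPathLen` (default 3) of at
   least two seeds. The bound keeps the candidate set small on large
   interactomes; 3 is generous, as useful single linkers sit at distance 1
   from two seeds.
2. Repeatedly add the candidate joining the largest number of currently
   distinct seed components. Ties break toward the smaller interactome
   degree (preferring specific bridges over promiscuous hubs), then
   lexicographically.
3. If no single candidate joins two components but the interactome still
   connects them, the two closest seed components are bridged along a
   shortest interactome path (the lexicographically smallest such path).
   This fallback was added because a strict one-gene-at-a-time greedy
   stalls whenever the only bridges are two or more genes long, and the
   assembly contract is a single connected component whenever the
   interactome permits one.
4. Finally, any linker whose removal leaves the seed-component count
   unchanged (and strands no other linker) is pruned, so the returned set
   is setwise-minimal under the greedy order.

The procedure is deterministic and, on small instances, close to optimal:
the test suite compares it with exhaustive search over all linker subsets
up to size 4. It is a heuristic, though -- no claim of global minimality is
made, matching the "minimal required additional genes" intent rather than
an exact Steiner solution (NP-hard in general).

Seeds with no interactome edges at all are reported separately and kept in
the assembled network as degree-0 nodes with their seed role: they are part
of the disease gene set even when no interaction evidence exists. They are
excluded from connectivity targets, betweenness (trivially 0) and
modularity signal.

# Topology

Degree and betweenness are computed exactly on the undirected simple graph
(igraph's shortest-path counting), unnormalized -- raw pair counts make the
values directly comparable to the brute-force path-enumeration oracle used
in the tests, and normalization would not change hub ordering. Components
are handled independently.

Hub flagging uses a top-fraction rule, default 0.10: the top
`floor(0.10 * n)` nodes by degree (minimum 1) and the top
`floor(0.10 * m)` edges by edge betweenness. Floor is the only reading
consistent with a 78-gene network yielding exactly 7 hub genes. Ties at
the cutoff resolve lexicographically after the score, making the rule
deterministic and scale-invariant.

The power-law diagnostic fits a least-squares line to log(count) versus
log(degree) over the empirical degree histogram, skipping degree 0 and
empty bins, and refuses distributions with fewer than three distinct
degrees. A maximum-likelihood tail fit would be more rigorous
statistically, but the pipeline only makes a qualitative scale-free-or-not
assessment, so the simplest defensible diagnostic is used; the function is
a seam where a different estimator can be substituted.

# Spectral modules

`spectralPartition()` implements Newman's leading-eigenvector method:
recursive bisection along the leading eigenvector of the (generalized)
modularity matrix `B = A - k k' / 2m`, keeping a split only when it
increases Q by more than `tol = 1e-10`. Numerical conventions, all chosen
for determinism:

* Nodes enter the matrix in lexicographic order, so results are invariant
  to input order.
* The eigenvector sign is fixed by making its first non-zero entry (the
  lexicographically smallest node) non-negative.
* When the leading eigenvalue is degenerate -- symmetric graphs produce
  multi-dimensional leading eigenspaces whose LAPACK basis is arbitrary --
  every near-degenerate eigenvector (within 1e-8 of the maximum) is tried
  and the split with the largest ΔQ kept.
* Isolated nodes are placed in one dedicated module: they carry no
  modularity signal, and scattering them as singletons would inflate the
  module count.

A Kernighan--Lin-style single-vertex sweep is available via
`refine = TRUE` but is off by default: the emulated workflow gives no
indication of refinement, and the default should match the plain method.
Recursive bisection without refinement is a known heuristic; the test
suite bounds its gap against the exhaustive optimum (within 0.05 on
graphs of up to 10 nodes, where the full partition lattice is enumerable).

`modularityQ()` evaluates partitions with the standard
`Q = Σ_c (e_c/m - (d_c/2m)^2)`; the one-module partition is always 0.

# Enrichment

Over-representation uses the one-sided hypergeometric upper tail
`P(X >= k)` -- the documented default of the upstream enrichment plugins
the pipeline emulates. Three choices deserve scrutiny:

* **Universe.** Defaults to all genes in the annotation collection, but is
  a parameter because it changes p-values materially. Query genes outside
  the universe are dropped with a logged count.
* **FDR scope.** Benjamini--Hochberg within each category separately,
  mirroring per-database reporting in the emulated workflow; whether the
  original correction was per-category or global is not documented, so the
  choice is surfaced here. Sets with zero overlap enter the correction at
  p = 1 (omitting them would bias q-values downward); only sets with
  overlap >= 1 are returned.
* **Significance** is strict (`q < alpha`, default 0.05).

The sensitivity re-analysis filters network genes to those with tissue
expression score strictly greater than 2.5 (the higher-than-average skin
expression cut, strict per its "> 2.5" definition; genes without a score
count as below threshold, logged) and reports the fraction of significant
terms that recur plus per-category top-term preservation.

# Drug matching

The reversal rule is deliberately conservative: a drug counts for a DEG
only when its expression effect strictly opposes the disease direction.
`UNKNOWN` directions never count -- the ranking rubric penalises unclear
directions separately, so guessing here would double-count evidence. A
drug reported to both increase and decrease the same gene is collapsed to
`UNKNOWN` at table construction (logged). Free-text effect vocabularies
("up-regulates", "represses", ...) normalise through a packaged
dictionary.

Combination coverage is plain set union. Two selectors are exposed: the
fixed recipe (take the top-k drugs by individual reversal count, report
their union) and `greedyMaxCoverage()`, the standard greedy
maximum-coverage algorithm with its (1 - 1/e) approximation guarantee,
ties toward the larger total set then lexicographic. The SNP lookup joins
variants at strict `p < 5e-8` (the conventional genome-wide significance
threshold) to a pharmaco-genomics table.

# Ranking rubric

All criterion points live in `RubricConfig` as data, not code, so the
rubric is auditable and adjustable; the defaults reproduce the published
point table exactly. Decisions where the source rubric is silent:

* Skin (+2) and general (+1) immunomodulation are mutually exclusive with
  skin dominating. A skin trial implies the general case, and stacking to
  +3 is inconsistent with every observable score pattern.
* The price bonuses are mutually exclusive by band construction. Band
  edges: cost < 50 EUR/year is `VERY_LOW`, 50--500 inclusive is `LOW`,
  (500, 20000] is `MID` (0 points), above 20000 `VERY_HIGH`. The edges 50
  and 500 fall to `LOW` and 20000 to `MID` by convention (the printed
  ranges are inclusive, "50--500" and ">20,000").
* `ISSUE` (-1) and `SEVERE` (-2) practical issues are exclusive; the worst
  applies.
* The unavailable-price penalty (-1) is independent of the separate
  not-orderable penalty (-1): they are distinct rubric rows.

Under these rules the total is bounded in [-8, +7] with pricing enabled
and [-7, +5] without, verified by exhaustive enumeration of all annotation
combinations. The shortlist is strict (`total > 0`); the secondary
analysis re-ranks with every pricing criterion skipped, which is provably
identical to zeroing the three pricing point values.

`reconstructRankingAnnotations()` deserves an honesty note: the published
ranking reports only per-drug totals, not the underlying criterion flags.
The fixture reconstructs *a* flag assignment that reproduces every
published total, the published no-pricing behaviour (exactly irbesartan,
rosuvastatin, saxagliptin and silicon dioxide dropping to 0), and silicon
dioxide's missing ATC code. Individual flags for other drugs are synthetic
and must not be read as claims about the real curation.

# Synthetic data

Every pipeline input has a seeded generator; all are pure functions of
their spec (RNG state is saved and restored around each call). The default
`synthesisSpec()` mirrors the motivating study's shape: 52 DEGs + 3 QTL
genes, of which 9 lack interactome coverage; 23 planted linkers (so the
assembled network has 78 genes); three planted reversal drugs covering 11
DEGs each with pairwise overlaps (5, 1, 4) and hence a 23-gene union; a
47/78 fraction of genes above the 2.5 expression threshold; and one
annotation set containing 15 of the DEGs among 20 members.

Two generators exist for interactomes. `genInteractome()` produces a plain
preferential-attachment graph (each new gene attaches to `m` distinct
existing genes with probability proportional to degree + 1, giving exactly
`m(n - m)` edges) -- scale-free, for topology tests.
`genSyntheticStudy()` instead plants the linker structure explicitly:
connected seeds form a chain of groups bridged only by designated linker
genes, with a preferential-attachment background glued to the linkers, so
the greedy search provably must recover exactly the planted linkers. The
synthetic namespace (`G####`, `L###`, `X###`, `B####`) is disjoint from
real gene symbols to prevent fixture/real mixing; the only real-symbol
fixture is the published candidate table.

What the generators do *not* emulate: realistic expression magnitudes,
correlated directions, linkage structure among SNPs, or the topology of a
curated functional-interaction database. Passing tests therefore
demonstrate that the algorithms recover known combinatorial structure
under controlled conditions -- they say nothing about biological validity
on real data, which depends entirely on the quality of the user's inputs.

# Degenerate inputs and error policy

Readers reject malformed rows with line numbers; empty files, empty
universes, empty seed sets, networks without edges, and degree
distributions with fewer than three distinct values are errors, not
silently absorbed. Self-loops, duplicate edges, out-of-universe query
genes, unscored genes and direction conflicts are dropped or collapsed
*with logged counts* -- the emulated upstream tools absorb these silently,
which makes results irreproducible. The pipeline aborts on the first
failing stage, naming it, and keeps artifacts of completed stages.

# Problem sizes in the test suite

The suite checks exact oracles at the scales where enumeration is
feasible: all 63 labelled graphs on four nodes plus random sparse graphs
to nine nodes for betweenness; the full partition lattice to ten nodes
(Bell(10) = 115975) for modularity optima; all draws for hypergeometric
tails to N = 12; subsets to size 4 for linker optimality; 1000 null
replicates for FDR control; 100 seeds for planted-structure recovery; and
the full 7680-row annotation grid for rubric bounds. These sizes were
chosen so each oracle is exhaustive at its scale while the whole suite
stays comfortably fast.

# Known limitations

* Linker search and spectral bisection are heuristics with documented
  determinism conventions, not exact optimisers.
* The enrichment model assumes independent sets; overlapping pathway
  hierarchies violate this as they do for any hypergeometric ORA.
* Reversal matching is binary per gene; effect sizes, dose and tissue
  context are out of scope, as is any causal claim.
* The ranking rubric encodes expert judgement; the engine guarantees only
  transparency and reproducibility of the arithmetic, not the wisdom of
  the weights.
* Real interactome, drug-table and annotation contents are inputs, not
  package data: reproducing specific published counts that depend on 2023
  database snapshots is explicitly out of scope.
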