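Package: vheRx
Title: Network-Guided Drug Repurposing for Vesicular Hand Eczema
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles a disease gene network for vesicular hand eczema from
    differentially expressed genes and QTL genes over a reference interactome
    (adding a minimal set of linker genes), analyses its topology (degree and
    betweenness hubs, power-law degree diagnostics), partitions it into
    functional modules by leading-eigenvector spectral modularity clustering,
    runs hypergeometric over-representation analysis with Benjamini-Hochberg
    FDR control (including a skin-expression sensitivity re-analysis), matches
    drugs to the network by physical targets and by transcriptomic signature
    reversal (with combination coverage), and ranks candidates with a
    transparent multi-criteria bonus/penalty rubric, including a secondary
    no-pricing analysis. Seeded synthetic-data generators with planted
    structure emulate every pipeline input for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'symbols.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'assembly.R'
    'clustering.R'
    'enrichment.R'
    'fixtures.R'
    'io.R'
    'pipeline.R'
    'ranking.R'
    'repurposing.R'
    'synth.R'
    'topology.R'
    'vheRx-package.R'
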