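Package: hybridtrace
Title: Detecting Ancient Introgression from Divergent Gene Copies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether a divergent extra copy of a nuclear gene found
    inside a clade arose by introgressive hybridization rather than by gene
    duplication and loss or by incomplete lineage sorting.  Implements
    parsimony gene-tree/species-tree reconciliation with duplication and
    loss counting under least-common-ancestor mapping, relative node-age
    hypothesis tests on 95% highest-posterior-density age intervals,
    Jukes-Cantor distance concordance checks between co-occurring gene
    copies, diagnostic-SNP classification of sequences against two clade
    references, allele-specific primer-site discovery based on 3' terminal
    mismatches, and a multispecies-coalescent synthetic-data generator with
    introgression, duplication-loss and deep-coalescence scenarios.  Reads
    and writes rooted dated trees in Newick and annotated NEXUS (BEAST or
    FigTree dialect, including node-height HPD annotations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    knitr
Config/testthat/edition: 3
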