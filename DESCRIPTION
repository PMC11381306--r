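Package: riverassembly
Title: Community Assembly Processes and Co-Occurrence Networks for
    Seasonal Bacterioplankton
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the ecological processes structuring microbial
    communities sampled across environmental gradients. Fits the Sloan
    neutral community model to occurrence-frequency data, partitions
    pairwise community turnover into deterministic and stochastic
    assembly processes with beta nearest taxon index (betaNTI) and
    Bray-Curtis Raup-Crick (RC-bray) null models, builds signed
    Spearman co-occurrence networks with modularity and Zi-Pi keystone
    classification, and provides the supporting diversity, ordination
    and environment-association statistics (Chao1, Shannon,
    rarefaction, PCoA, ANOSIM, Kruskal-Wallis, Wilcoxon with FDR
    control, VIF screening, Mantel and partial Mantel tests, RDA with
    hierarchical variance partitioning). A synthetic-community
    generator with known assembly regimes supports end-to-end
    ground-truth recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
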