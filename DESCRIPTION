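Package: tjstorm
Title: Tight-Junction Nano-Architecture Analysis for Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("BBB", "Imaging Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification of blood-brain-barrier tight-junction
    nano-architecture from dSTORM localization data. Reads ThunderSTORM-style
    molecular lists, partitions localizations into clusters by a strict
    distance-threshold single-linkage rule (default 70 nm), computes
    per-cluster convex-hull areas and signal densities, per-capillary totals
    and diameter-normalized abundance, claudin-5/ZO1 cluster-coupling
    classification, and a reference-normalized tracer leakage index in a
    fixed abluminal band (default 100-300 nm). Includes nonparametric group
    comparisons (Mann-Whitney U, Kruskal-Wallis with Dunn post hoc) and a
    Neyman-Scott synthetic scene generator with ground truth so the full
    pipeline is testable without deposited imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
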