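Package: toplap
Title: Persistent Laplacian Featurization and Classification of Protein
    Solubility Changes upon Mutation
Version: 0.1.0
Authors@R: person("toplap", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Element-specific persistent combinatorial Laplacian and
    persistent homology featurization of wild-type/mutant protein structure
    pairs around a mutation site, with pluggable sequence-transformer and
    auxiliary embedding blocks, a gradient-boosted-tree classifier of
    solubility change (decrease, no change, increase), and normalized
    multiclass performance metrics (CPR, GC2). Includes a combinatorial
    Hodge Laplacian engine with an entrywise oracle, Vietoris-Rips and
    alpha/Cech filtrations with persistence barcodes, and deterministic
    synthetic fixtures so everything runs offline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
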