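Package: commassembly
Title: Phylogenetic Null Models and Co-Occurrence Networks for Microbial
    Community Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the ecological processes structuring microbial
    communities from OTU count tables and a phylogeny. Implements
    abundance-weighted alpha and beta mean pairwise phylogenetic distance
    (MPD) with phylogeny-pool null models and the nearest relative index
    (NRI and betaNRI), Mantel correlogram tests of phylogenetic signal in
    environmental optima, SparCC compositional correlation networks with
    permutation significance, checkerboard C-score non-randomness tests,
    co-occurrence network topology, and the supporting group statistics
    (Tukey compact letter displays, one-sample t-tests against the +/-2
    decision rule, Pearson correlation panels, quadratic yield fits).
    Ships a synthetic-study generator with known assembly ground truth
    (environmental filtering, competitive exclusion, neutral) so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    vegan,
    withr
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
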