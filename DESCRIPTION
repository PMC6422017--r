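Package: cladosig
Title: Topology-Only Phylogenetic Signal Analysis for Landmark Shape Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for phylogenetic signal in continuous traits using only the
    topology of a rooted cladogram, with no branch lengths: orthonormal
    decomposition of trait variance across tree nodes (the orthogram, with the
    R2Max, SkR2k, Dmax and SCE permutation statistics), and Abouheif's C-mean
    autocorrelation test built from a proximity matrix of inverse
    direct-descendant counts. Includes the upstream geometric-morphometric
    quantification (TPS input, centroid size, generalized Procrustes
    superimposition, shape PCA), squared-change parsimony reconstruction of
    ancestral landmark configurations, Fitch parsimony for binary characters,
    nonparametric group tests of skull proportion ratios, and a synthetic-data
    generator (Yule topologies, Brownian-motion and white-noise traits and
    landmark sets) providing ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
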