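Package: tcnets
Title: Tree-Child Phylogenetic Networks and Their Reconstruction from
    Reticulate-Edge-Deleted Subnetworks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for rooted binary tree-child phylogenetic networks:
    extended-Newick input/output, structural queries (tree-child test,
    biconnected blobs and network level, up-down distances, display
    checks), the reticulation-edge deletion and cleanup calculus
    (maximum subnetworks, maximum lower-level subnetworks, cutting and
    isolating reticulated cherry shapes, cherry reduction, pendant
    collapse), blob trees and their reconstruction from subnetwork
    collections, the eight-shape leaf-pair calculus, and a
    polynomial-time algorithm that uniquely rebuilds a level-k
    tree-child network (k >= 2) from its maximum lower-level
    subnetworks, including the three-subnetwork variant.  A seeded
    generator of random tree-child networks with prescribed blob
    structure and a set of brute-force oracles support property-based
    testing of every operation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
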