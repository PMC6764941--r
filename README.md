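# tcnets — reconstructing tree-child phylogenetic networks from reticulate-edge-deleted subnetworks

Phylogenetic networks generalize phylogenetic trees to rooted directed
acyclic graphs so that reticulate events — hybridization, horizontal gene
transfer, recombination — can be represented alongside speciation.  Two
widely studied classes are the *tree-child* networks (every non-leaf node
has a child that is a tree node or a leaf) and the *level-k* networks (no
biconnected component, or *blob*, contains more than k reticulations).

`tcnets` is a toolkit for a building-block approach to network
reconstruction in these classes.  The building blocks are the
**reticulate-edge-deleted subnetworks**: deleting a single reticulation
edge (and cleaning up the two suppressed endpoints) yields a *maximum
subnetwork*; deleting one such edge from every level-k blob yields a
**maximum lower-level subnetwork (MLLS)**.  For binary level-k tree-child
networks with k ≥ 2 the MLLS set *encodes* the network — two networks with
the same MLLS set are isomorphic — and the network can be rebuilt from its
MLLSs in polynomial time.  The package implements the whole chain of
machinery behind that result:

* **Network core** — `phylo_network` objects; validation of the degree
  profile (root 0-in/1-out, leaves 1/0, tree nodes 1/2, reticulations
  2/1); the tree-child test; blob decomposition with levels, pure nodes
  and leaf-descendant sets; shortest **up-down distances**
  d<sub>N</sub>(x,y) (paths that ascend to an apex and then descend);
  a brute-force display check; extended-Newick and edge-list I/O.
* **Edit calculus** — cleanup (delete unlabelled sinks, suppress
  degree-1/1 nodes, merge parallel edges), single-edge deletion, validity
  of deletions (a deletion is *valid* when exactly 2 nodes and 3 edges
  disappear; all reticulation edges of a tree-child network are valid),
  `mlls_set()`, cutting/isolating reticulated cherry shapes,
  cherry reduction, pendant collapse/expansion.
* **Blob trees** — `blob_tree()` contracts each blob to a node labelled by
  its leaf-descendant set; the blob tree of the source network is
  recovered as the Hasse diagram of the labels common to the blob trees of
  its subnetworks (`foundation_nodes()`, `assemble_blob_tree()`), and the
  level-k blobs are identified by their changed child sets
  (`identify_level_k_blobs()`).
* **Shape calculus** — on each leaf pair {x,y} a tree-child network shows
  exactly one of eight shapes: the cherry Λ(x,y); the subdivided cherries
  λ(x,y), λ(y,x); the reticulated cherries with shared grandparent A(x,y),
  A(y,x) and without H(x,y), H(y,x); and Π(x,y) (up-down distance ≥ 4).
  `classify_pair()` computes the shape, `infer_original_shape()` recovers
  the source network's shape on a pair from the shapes observed across its
  MLLSs — including whether an H shape sits in a maximum-level blob.
* **Reconstruction** — `tcmlls_reconstruct()` runs the loop: collapse all
  maximal common pendant subnetworks, find a lowest common blob-tree
  label, locate a leaf pair whose inferred shape is H in a maximum-level
  blob, re-insert the missing reticulation edge in the subnetwork that
  shows λ/Π on that pair and transplant the rebuilt blob into the others,
  until all working networks coincide.  `reconstruct_from_three()` does
  the same from a canonical certificate of just three MLLSs plus the
  number of maximum-level blobs (`mlls_triple()` builds one).
* **Synthesis & oracles** — `generate_tcnet()` grows random tree-child
  networks with a prescribed level and blob census by seed-deterministic
  inverse cherry/reticulated-cherry expansions; `tc_isomorphic()` decides
  isomorphism through the path-count (mu) representation with a VF2
  fallback; `oracle_*()` functions recompute distances, shapes, displays
  and MLLS sets by brute force for property tests.

## Worked example

```r
library(tcnets)

N <- generate_tcnet(n_leaves = 10, level = 2, n_top_blobs = 1,
                    extra_blobs = 1, seed = 11)
summary(N)
#> 10 taxa, 26 nodes, 28 edges, 3 reticulations
#> level 2; 6 blobs (levels: 2 1 0 0 0 0)
#>   blob level 2, pure node 5, descendants {t10,t2,t3,t4,t5,t6,t7,t8,t9}
#>   blob level 1, pure node 15, descendants {t10,t4,t6,t7,t8,t9}
#>   ...

M <- mlls_set(N)          # one level-2 blob with 2 reticulations: 4 MLLSs
length(M)
#> [1] 4

R <- tcmlls_reconstruct(M, verify = TRUE)
tc_isomorphic(R, N)
#> [1] TRUE
cat(attr(R, "trace"), sep = "\n")
#> collapse {t10,t4,t6,t7,t8,t9}
#> rebuild blob {{t10,t4,t6,t7,t8,t9},t2,t3,t5} via pair (t3,{t10,t4,t6,t7,t8,t9})
#> collapse {{t10,t4,t6,t7,t8,t9},t2,t3,t5}
#> terminate: all networks isomorphic

tri <- mlls_triple(N)     # three MLLSs + blob count also suffice
tc_isomorphic(reconstruct_from_three(tri$mllss, tri$l), N)
#> [1] TRUE
```

The trace reads as the algorithm works: the level-1 blob on
{t4,t6,t7,t8,t9,t10} is identical in every MLLS, so it is collapsed to a
single synthetic leaf; the remaining lowest common blob-tree label marks
the level-2 blob, whose missing reticulation edge is re-inserted above the
pair (t3, {t10,...}); after one more collapse all working networks agree
and the collapsed pendants are expanded back.

A shell front end `exec/net` wraps the same functions
(`net validate`, `net stats`, `net mlls`, `net blobtree`, `net shape`,
`net generate`, `net reconstruct ... --verify`), reading and writing
extended Newick with `#H` tags, one network per line.

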