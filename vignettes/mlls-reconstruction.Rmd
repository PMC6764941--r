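---
title: "Reconstructing tree-child networks from their maximum lower-level subnetworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing tree-child networks from their maximum lower-level subnetworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcnets)
```

## The objects

A rooted binary phylogenetic network on a taxon set $X$ is a directed
acyclic graph in which every node is the root (indegree 0, outdegree 1),
a leaf (1, 0; bijectively labelled by $X$), a tree node (1, 2) or a
reticulation (2, 1).  The network is *tree-child* when every non-leaf
node has at least one non-reticulation child, which guarantees a tree
path (reticulation-free directed path) from every node down to a leaf.
A *blob* is a maximal biconnected component of the underlying undirected
graph (or an isolated tree node, a level-0 blob); its *level* is the
number of reticulations it contains, and the network's level is the
maximum blob level.  Every blob has a unique top ("pure") node; the edge
into a pure node is always a cut edge, so the subnetwork below a pure
node is pendant — a fact `tcnets` exploits heavily.

Deleting a reticulation edge and *cleaning up* — deleting unlabelled
sinks, suppressing indegree-1 outdegree-1 nodes and merging parallel edge
pairs to a fixpoint — yields a *maximum subnetwork*.  A deletion is
*valid* when exactly two nodes and three edges disappear, i.e. the edge
goes and its endpoints are suppressed with no further cascade; in a
tree-child network every reticulation-edge deletion is valid, because the
tree-child property forbids the triangle and diamond configurations that
trigger cascades.  A *maximum lower-level subnetwork (MLLS)* of a level-k
network deletes one valid reticulation edge from every level-k blob; for
a tree-child source every MLLS is again tree-child, of level at most
k−1.

The central fact implemented here is an encoding result: for binary
tree-child networks of level $k \ge 2$, the MLLS set determines the
network up to isomorphism, and the network is recoverable from it in
polynomial time.  Trees and level-1 networks are excluded — small-girth
level-1 networks genuinely share subnetwork sets — and the package
refuses `mlls_set()` on trees accordingly.

## Blob trees from subnetworks

`blob_tree()` contracts each blob to a node labelled by the
leaf-descendant set of its pure node, keeps an unlabelled root and drops
the leaves; for tree-child networks these labels are pairwise distinct,
so blob nodes are identified with their labels ("foundation nodes").
A label belongs to the source network's blob tree exactly when it occurs
in the blob tree of *every* maximum subnetwork (equivalently, of every
MLLS): deletions can create new pure nodes, but — as the cut/isolate
analysis of a lowest reticulated cherry shape shows — no spurious label
survives intersection, and two well-chosen subnetworks already suffice
(`canonical_maxsub_pair()`, `canonical_mlls_pair()`).  The blob tree is
then reassembled as the Hasse diagram of the intersected label family
under strict inclusion (`assemble_blob_tree()`), which also serves as a
consistency check: a non-laminar family is rejected.  A blob has level
below k exactly when its node's child set is identical in every MLLS
blob tree (`identify_level_k_blobs()`).

Internally the engine never runs a biconnectivity pass for this: a node
heads a pendant subnetwork iff it is not a reticulation and every
reticulation below it has both parents below it, and the non-leaf
pendant heads are exactly the pure nodes.  One $O(|V|^2)$ reachability
matrix per network therefore yields the pendant index, the blob-tree
labels and the path-count matrix used for isomorphism, which is what
makes the reconstruction loop cheap.

## The leaf-pair shape calculus

On any leaf pair $\{x,y\}$ of a tree-child network exactly one of eight
shapes holds, classified by the shortest up-down distance $d(x,y)$ (an
up-down path ascends from $x$ to an apex and then descends to $y$; both
leaf parents lie on every such path, so $d=2$ iff the parents coincide
and $d=3$ iff they are adjacent): the cherry $\Lambda$; the subdivided
cherry $\lambda(x,y)$ (middle tree node above $y$) or $\lambda(y,x)$; the
reticulated cherry with the reticulation on $y$, split into $A(x,y)$
(leaf parents share a common parent — always a level-1 triangle blob)
and $H(x,y)$ (they do not), plus their mirror images; and $\Pi$
($d \ge 4$).  The shape of the source network on a pair is identifiable
from the shapes its MLLSs show on that pair:

* all MLLSs show $\Lambda$ ⇔ the source has $\Lambda$;
* some MLLS shows $\lambda(x,y)$ and none shows $\lambda(y,x)$, a
  reticulated cherry, or $\Pi$ ⇔ the source has $\lambda(x,y)$;
* all show $A(x,y)$ ⇔ the source has $A(x,y)$;
* distinct MLLSs show $\Lambda(x,y)$ and $H(x,y)$ and none shows a
  reticulated cherry on $y,x$ ⇔ the source has $H(x,y)$ **in a level-k
  blob** (isolating produced the cherry);
* all show $H(x,y)$ ⇔ the source has $H(x,y)$ in a blob of level < k;
* some MLLS shows $\Pi$ and none shows $\Lambda$ ⇔ the source has $\Pi$.

`infer_original_shape()` evaluates all six cases and insists that
exactly one matches, raising "inconsistent" otherwise — this doubles as
a cheap detector for inputs that are not a genuine MLLS set.  The
H-with-level-k flag is the reconstruction trigger: such a pair pinpoints
a blob whose missing reticulation edge can be re-inserted.

## The reconstruction loop

`tcmlls_reconstruct()` iterates four steps:

1. **Collapse** every maximal common pendant subnetwork (present with an
   isomorphic copy in every working network, more than one leaf, not the
   whole network) into a synthetic leaf named by its sorted taxon set,
   e.g. `"{v,w}"`.  Common pendants are exactly the parts untouched by
   the deletions, so after this step every lowest blob has level k.
2. **Terminate** if all working networks are pairwise isomorphic: expand
   the collapse stack in reverse and return.  (The check compares
   canonical path-count strings, which also lets the engine drop
   duplicated networks — the MLLS collection is a set, and after a blob
   is finished whole families of choices become isomorphic, shrinking
   the working set geometrically.)
3. **Locate** a minimal common blob-tree label $A$ — a lowest level-k
   blob — and search the pairs below $A$ (pairs at up-down distance
   ≤ 3 in some network first) for one whose inference is H with the
   level-k flag.
4. **Rebuild**: in the network showing $\lambda$ or $\Pi$ on the pair,
   subdivide the two pendant edges and add the edge between the new
   nodes — this re-creates the missing reticulation edge exactly.  In
   every other network, the *B-part* (the component cut out between the
   tree edge into the pure node labelled $A$ and the outgoing edges of
   the pure nodes of $A$'s blob-tree children) is replaced by a fresh
   copy of the rebuilt B-part; boundaries are matched by blob-tree
   label, never by node id.  The rebuilt pendant is then common and is
   collapsed on the next iteration.

If an iteration makes no progress the engine stops with "no consistent
network"; with `verify = TRUE` the result's MLLS set is recomputed and
compared against the input, so a degenerate input can never silently
yield a wrong network.  `reconstruct_from_three()` runs the identical
loop on a three-network certificate (cut all lowest shapes / isolate
them / delete a third edge per blob keeping the shape's reticulation
parents non-adjacent) plus the number `l` of level-k blobs; it raises on
a stall and reports an over-stated `l` in the trace.

Design choices where the procedure itself leaves freedom: cleanup
applies parallel-edge merging, then suppression, then sink deletion from
a worklist — confluence over arbitrary orderings is asserted by test,
not assumed; the pair search iterates candidate pairs in canonical label
order for determinism; `mlls_set()` returns the full per-blob choice
product without isomorphism deduplication (callers compare up to
isomorphism; the engine dedupes internally); and the loop collapses
pendants rather than reducing resolved cherries — the two are
equivalent, and collapsing keeps every intermediate a genuine MLLS set
of a smaller network, which simplifies the invariants.

## Isomorphism

`tc_isomorphic()` compares tree-child networks through their path-count
(mu) representation: for each node the vector counting directed paths to
each leaf, compared as multisets together with the taxon set.  This
characterizes tree-child networks, runs in $O(|V|\,|X|)$, and reduces to
string comparison; a colour-constrained VF2 search on the directed
graphs (via igraph) is kept both as the general-network fallback and as
the independent oracle the test-suite plays against the mu route.

## The generator and what it does (not) emulate

`generate_tcnet(n_leaves, level, n_top_blobs, extra_blobs, seed)` grows a
network from a single leaf by inverse reductions: a *cherry expansion*
subdivides a pendant edge and hangs a fresh leaf; a *reticulated-cherry
expansion* subdivides the pendant edge of a leaf attached to a
designated blob and a tree edge inside that blob, joining the two fresh
nodes through a new reticulation with a fresh leaf child.  Each
reticulated expansion raises the designated blob's level by exactly one,
and blobs grown at different attachment leaves never merge, so the
requested census — level exactly `level`, exactly `n_top_blobs`
maximum-level blobs, `extra_blobs` lower-level blobs — holds by
construction rather than by rejection sampling.  A special variant
subdivides the chosen pendant edge twice, producing the self-contained
triangle blob that realizes the $A$ shapes; it is only used when a
level-1 blob is wanted, since the triangle never merges with an existing
blob.  The generator is a pure function of its arguments (the RNG state
is saved and restored), so every stochastic test is replayable from its
seed.

The generator emulates topology only: no branch lengths, no sequence
data, no sampling noise, and no attempt at uniformity over tree-child
space — expansions are chosen uniformly among the currently admissible
ones, which biases toward caterpillar-like backbones.  Passing tests
therefore certify the combinatorial machinery (encodings, shape
calculus, reconstruction), not the statistical behaviour of any
inference pipeline that would produce MLLS-like inputs from data.

## Problem sizes and numerical choices

The test-suite and the acceptance script work at the scale the theory
targets and the implementation handles comfortably on one core: networks
of level 2–4 on 6–30 taxa with 1–3 maximum-level blobs (an MLLS set of
up to $\,(2k)^3 = 512$ networks), 100 reconstruction round trips, and
brute-force oracle comparisons on 500 networks capped at 15 nodes, where
exhaustive deletion-set enumeration ($3^r$ cases) is instant.  All
arithmetic is on small integers; there are no tolerances anywhere — every
comparison in the package is exact (graph isomorphism, set equality,
integer counts).  Degenerate inputs are handled by refusal rather than
repair: `mlls_set()` raises on trees, `cleanup_graph()` raises when a
deletion sequence disconnects all leaves, collapse raises on a label-set
that heads no pendant, and the reconstruction engine raises when no
candidate step exists.

## Known limitations

* Reconstruction guarantees hold for binary tree-child sources of level
  ≥ 2 with a *complete* MLLS set (or the canonical three-MLLS
  certificate).  Arbitrary subsets may stall or, if they happen to be
  consistent with a different network, only `verify = TRUE` will flag it.
* Valid-but-not-tree-child networks are handled best-effort: blobs with
  no valid edge make `mlls_set()` raise, and the shape calculus assumes
  tree-child inputs (a 2-reticulated cherry, where both leaf parents are
  reticulations, is outside its eight-shape codomain).
* `displays()` and the `oracle_*` functions are exponential by design
  and guard against large reticulation counts; they are test
  instruments, not production queries.
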