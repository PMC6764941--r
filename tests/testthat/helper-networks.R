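## hand-built fixture networks used across the test files

## root -> a -> {x, y}
cherry_net <- function() {
  phylo_network(rbind(c(1, 2), c(2, 3), c(2, 4)), c(`3` = "x", `4` = "y"))
}

single_leaf_net <- function() {
  phylo_network(matrix(c(1L, 2L), ncol = 2), c(`2` = "x"))
}

## caterpillar tree on {a, b, c}: cherry {a, b}, then c
caterpillar3 <- function() {
  phylo_network(rbind(c(1, 2), c(2, 3), c(2, 6), c(3, 4), c(3, 5)),
                c(`4` = "a", `5` = "b", `6` = "c"))
}

## reticulated cherry with shared grandparent: A(x, y)
## root -> g; g -> p_x, p_y; p_x -> x, p_x -> p_y; p_y -> y
a_shape_net <- function() {
  phylo_network(rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 5), c(3, 4), c(4, 6)),
                c(`5` = "x", `6` = "y"))
}

## reticulated cherry without shared grandparent: H(x, y), plus a leaf z
## i(2) -> a(3), b(4); a -> x, c(6); b -> c, z; c -> y (c is the reticulation)
h_shape_net <- function() {
  phylo_network(rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 5), c(3, 6),
                      c(4, 6), c(4, 7), c(6, 8)),
                c(`5` = "x", `7` = "z", `8` = "y"))
}

## tree containing lambda(x, y): root -> a; a -> x, b; b -> y, c
lambda3 <- function() {
  phylo_network(rbind(c(1, 2), c(2, 3), c(2, 4), c(4, 5), c(4, 6)),
                c(`3` = "x", `5` = "y", `6` = "c"))
}

## diamond: the middle reticulation edge (3,4) is invalid (its deletion
## cascades: 4 nodes and 6 edges disappear); the network is not tree-child
diamond_net <- function() {
  phylo_network(rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 4), c(3, 5),
                      c(4, 5), c(5, 6)),
                c(`6` = "a"), check = FALSE)
}

## a small sample of generated tree-child networks (deterministic)
sample_nets <- function(n = 10, seed = 101, levels = c(2L, 3L, 4L),
                        max_leaves = 14L) {
  specs <- random_spec_grid(n, seed = seed, levels = levels,
                            max_leaves = max_leaves)
  lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    generate_tcnet(s$n_leaves, s$level, s$n_top_blobs, s$extra_blobs, s$seed)
  })
}

## all unordered leaf pairs of a network, as a list of label pairs
leaf_pairs <- function(net) {
  tx <- taxa(net)
  if (length(tx) < 2) return(list())
  utils::combn(tx, 2, simplify = FALSE)
}
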