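test_that("cleanup: fixpoints, traced examples, confluence", {
  ## a valid network is already a fixpoint
  n <- a_shape_net()
  out <- cleanup_graph(n$edges, n$labels, n$root)
  expect_identical(out$edges, n$edges)

  ## deleting one reticulation edge of the A(x,y) network leaves the cherry
  for (e in list(c(3L, 4L), c(2L, 4L))) {
    sub <- delete_reticulation_edge(a_shape_net(), e)
    expect_true(tc_isomorphic(sub, cherry_net()))
  }

  ## a triangle (shortcut) left after a deletion fires the parallel rule:
  ## in the diamond network, deleting the middle edge cascades down to a
  ## single pendant leaf
  sub <- delete_reticulation_edge(diamond_net(), c(3L, 4L))
  expect_identical(length(tcnets:::net_nodes(sub)), 2L)
  expect_identical(taxa(sub), "a")

  ## confluence: random rule orderings give isomorphic fixpoints
  N <- generate_tcnet(8, 2, 1, 0, seed = 31)
  re <- tcnets:::reticulation_edges(N)
  for (i in seq_len(nrow(re))) {
    ref <- delete_reticulation_edge(N, re[i, ])
    for (rep in 1:5) {
      alt <- tcnets:::delete_edges_cleanup(N, re[i, , drop = FALSE],
                                           order = "random")
      expect_true(tc_isomorphic(alt, ref))
    }
  }
})

test_that("valid deletions remove exactly 2 nodes and 3 edges", {
  for (net in sample_nets(6, seed = 37)) {
    re <- tcnets:::reticulation_edges(net)
    for (i in seq_len(nrow(re))) {
      sub <- delete_reticulation_edge(net, re[i, ])
      expect_identical(length(tcnets:::net_nodes(net)) -
                         length(tcnets:::net_nodes(sub)), 2L)
      expect_identical(nrow(net$edges) - nrow(sub$edges), 3L)
      expect_true(is_valid_edge(net, re[i, ]))
      expect_true(is_tree_child(sub))        # maximum subnetworks stay so
    }
  }
  expect_error(delete_reticulation_edge(cherry_net(), c(2L, 3L)),
               "not a reticulation edge")
})

test_that("invalid edges exist outside the tree-child class", {
  d <- diamond_net()
  expect_false(is_valid_edge(d, c(3L, 4L)))
  ## definitional and local characterizations agree everywhere
  nets <- c(list(d, a_shape_net(), h_shape_net()), sample_nets(4, seed = 41))
  for (net in nets) {
    re <- tcnets:::reticulation_edges(net)
    for (i in seq_len(nrow(re))) {
      expect_identical(is_valid_edge(net, re[i, ]),
                       tcnets:::edge_valid_local(net, re[i, ]))
    }
  }
})

test_that("maximum subnetworks: one per reticulation edge", {
  ms <- maximum_subnetworks(a_shape_net())
  expect_length(ms, 2)
  for (m in ms) expect_true(tc_isomorphic(m, cherry_net()))
  N <- generate_tcnet(10, 3, 1, 0, seed = 43)
  expect_length(maximum_subnetworks(N), 2L * n_reticulations(N))
  expect_length(maximum_subnetworks(caterpillar3()), 0)
})

test_that("MLLS enumeration: counts, level bound, tree-child closure", {
  expect_error(mlls_set(caterpillar3()), "level-0")
  ## one level-k blob with r reticulations: 2r MLLSs
  N1 <- generate_tcnet(8, 2, 1, 0, seed = 47)
  expect_length(mlls_set(N1), 4)
  ## two level-k blobs: the choice product
  N2 <- generate_tcnet(12, 2, 2, 0, seed = 53)
  expect_length(mlls_set(N2), 16)
  for (N in list(N1, N2)) {
    k <- network_level(N)
    for (m in mlls_set(N)) {
      expect_lte(network_level(m), k - 1L)
      expect_true(is_tree_child(m))
    }
  }
})

test_that("MLLS set equals the brute-force maximal lower-level subnetworks", {
  for (seed in c(59, 61)) {
    N <- generate_tcnet(5, 2, 1, 0, seed = seed)
    expect_true(tcnets:::iso_setequal(mlls_set(N), oracle_mlls_set(N)))
  }
})

test_that("single deletions reduce up-down distances by at most one", {
  for (net in sample_nets(5, seed = 67, max_leaves = 10)) {
    prs <- leaf_pairs(net)
    d0 <- vapply(prs, function(p) up_down_distance(net, p[1], p[2]),
                 numeric(1))
    for (m in maximum_subnetworks(net)) {
      d1 <- vapply(prs, function(p) up_down_distance(m, p[1], p[2]),
                   numeric(1))
      expect_true(all(d0 - d1 <= 1))
    }
  }
})

test_that("cutting and isolating reticulated cherry shapes (H case)", {
  H <- h_shape_net()
  s <- ret_cherry_shape(H, "x", "y")
  expect_false(is.null(s))
  iso <- isolate_shape(H, s)
  expect_identical(classify_pair(iso, "x", "y")$kind, "LAMBDA_CHERRY")
  cutn <- cut_shape(H, s)
  expect_true(classify_pair(cutn, "x", "y")$kind %in%
                c("lambda_xy", "lambda_yx", "PI"))
  ## on generated networks: cutting an H pair never yields a cherry or a
  ## reticulated cherry, and the other deletions preserve the cherry or H
  for (net in sample_nets(4, seed = 71)) {
    for (pr in leaf_pairs(net)) {
      sh <- classify_pair(net, pr[1], pr[2])
      if (sh$kind != "H_xy") next
      s <- ret_cherry_shape(net, pr[1], pr[2])
      expect_true(classify_pair(cut_shape(net, s), pr[1], pr[2])$kind %in%
                    c("lambda_xy", "lambda_yx", "PI"))
      expect_identical(
        classify_pair(isolate_shape(net, s), pr[1], pr[2])$kind,
        "LAMBDA_CHERRY")
      re <- tcnets:::reticulation_edges(net)
      for (i in seq_len(nrow(re))) {
        if (re[i, 2] == s$p_y) next
        other <- delete_reticulation_edge(net, re[i, ])
        expect_true(classify_pair(other, pr[1], pr[2])$kind %in%
                      c("LAMBDA_CHERRY", "H_xy"))
      }
    }
  }
})

test_that("cherry and reticulated-cherry reduction", {
  expect_true(tc_isomorphic(reduce_pair(cherry_net(), "x", "y"),
                            single_leaf_net()))
  r <- reduce_pair(a_shape_net(), "x", "y")
  expect_identical(taxa(r), "x")
  expect_error(reduce_pair(caterpillar3(), "a", "c"), "neither|do not form")

  ## reduction commutes with MLLS formation on other blobs: reducing a
  ## cherry outside the maximum-level blobs, before or after taking MLLSs,
  ## yields the same set up to isomorphism
  N <- generate_tcnet(12, 2, 1, 0, seed = 73)
  cherries <- Filter(function(p)
    classify_pair(N, p[1], p[2])$kind == "LAMBDA_CHERRY", leaf_pairs(N))
  expect_gt(length(cherries), 0)
  p <- cherries[[1]]
  s1 <- mlls_set(reduce_pair(N, p[1], p[2]))
  s2 <- lapply(mlls_set(N), reduce_pair, x = p[1], y = p[2])
  expect_true(tcnets:::iso_setequal(s1, s2))
})

test_that("pendant collapse and expansion are inverse", {
  N <- generate_tcnet(10, 2, 1, 0, seed = 79)
  ## collapse a cherry pendant
  cherries <- Filter(function(p)
    classify_pair(N, p[1], p[2])$kind == "LAMBDA_CHERRY", leaf_pairs(N))
  expect_gt(length(cherries), 0)
  A <- sort(c(cherries[[1]][1], cherries[[1]][2]))
  col <- collapse_pendant(N, A)
  expect_identical(col$label, paste0("{", paste(A, collapse = ","), "}"))
  expect_true(col$label %in% taxa(col$net))
  expect_true(tc_isomorphic(expand_pendant(col$net, col$label, col$pendant),
                            N))
  ## the blob tree loses exactly the pendant subtree rooted at A
  lab0 <- blob_tree(N)$labels[-1]
  lab1 <- lapply(blob_tree(col$net)$labels[-1], function(l) {
    sort(unlist(lapply(l, function(a) if (a == col$label) A else a)))
  })
  survive <- Filter(function(l) !all(l %in% A), lab0)
  expect_setequal(vapply(lab1, paste, character(1), collapse = ","),
                  vapply(survive, paste, character(1), collapse = ","))
  expect_error(collapse_pendant(N, c("nope1", "nope2")), "not the leaf set")
})
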