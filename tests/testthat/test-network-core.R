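test_that("validate_network accepts valid networks and names violations", {
  expect_length(validate_network(cherry_net()), 0)
  expect_length(validate_network(single_leaf_net()), 0)
  expect_length(validate_network(a_shape_net()), 0)

  ## a node of indegree 2 and outdegree 2
  bad <- structure(list(
    edges = rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L), c(3L, 5L), c(4L, 5L),
                  c(3L, 6L), c(5L, 6L), c(5L, 7L), c(6L, 8L), c(4L, 9L)),
    labels = c(`7` = "a", `8` = "b", `9` = "c"), root = 1L),
    class = "phylo_network")
  v <- validate_network(bad)
  expect_true(any(grepl("node 5", v)))

  ## a directed cycle
  cyc <- structure(list(
    edges = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 2L), c(3L, 5L)),
    labels = c(`5` = "a"), root = 1L), class = "phylo_network")
  expect_true(any(grepl("acyclic", validate_network(cyc))))
})

test_that("tree-child recognition matches the definition", {
  expect_true(is_tree_child(cherry_net()))
  expect_true(is_tree_child(caterpillar3()))
  expect_true(is_tree_child(a_shape_net()))
  expect_true(is_tree_child(h_shape_net()))
  expect_false(is_tree_child(diamond_net()))
  for (net in sample_nets(8)) expect_true(is_tree_child(net))
})

test_that("blob decomposition: levels, pure nodes, descendant sets", {
  expect_length(network_blobs(single_leaf_net()), 0)
  expect_identical(network_level(single_leaf_net()), 0L)

  ## a tree on n leaves has n - 1 level-0 blobs (internal tree nodes)
  tr <- generate_tcnet(7, level = 0, seed = 3)
  b <- network_blobs(tr)
  expect_length(b, 6)
  expect_true(all(vapply(b, function(x) x$level, integer(1)) == 0L))

  ## the A(x,y) network: one level-1 blob whose pure node is the grandparent
  b <- network_blobs(a_shape_net())
  expect_length(b, 1)
  expect_identical(b[[1]]$level, 1L)
  expect_identical(b[[1]]$pure, 2L)
  expect_identical(b[[1]]$desc, c("x", "y"))

  ## every tree node / reticulation is in exactly one blob; levels sum to
  ## the reticulation count; edges = nodes - 1 + reticulations
  for (net in sample_nets(8)) {
    b <- network_blobs(net)
    members <- unlist(lapply(b, function(x) x$members))
    expect_false(anyDuplicated(members) > 0)
    din <- tabulate(match(net$edges[, 2], sort(unique(c(net$edges)))))
    expect_identical(sum(vapply(b, function(x) x$level, integer(1))),
                     n_reticulations(net))
    expect_identical(nrow(net$edges),
                     length(tcnets:::net_nodes(net)) - 1L +
                       n_reticulations(net))
  }
})

test_that("up-down distance: axioms, examples and oracle agreement", {
  expect_equal(up_down_distance(cherry_net(), "x", "y"), 2)
  expect_equal(up_down_distance(cherry_net(), "x", "x"), 0)
  expect_equal(up_down_distance(a_shape_net(), "x", "y"), 3)
  for (net in sample_nets(6, seed = 7, max_leaves = 10)) {
    for (pr in leaf_pairs(net)) {
      d1 <- up_down_distance(net, pr[1], pr[2])
      expect_identical(d1, up_down_distance(net, pr[2], pr[1]))
      expect_equal(d1, oracle_up_down_distance(net, pr[1], pr[2]))
    }
  }
})

test_that("in a tree-child network every node has a tree path to a leaf", {
  for (net in sample_nets(6, seed = 11)) {
    nodes <- tcnets:::net_nodes(net)
    din <- stats::setNames(tabulate(match(net$edges[, 2], nodes),
                                    length(nodes)), nodes)
    for (v in nodes) {
      ## follow non-reticulation children greedily
      reached <- FALSE
      frontier <- v
      seen <- integer()
      while (length(frontier)) {
        w <- frontier[1]; frontier <- frontier[-1]
        if (as.character(w) %in% names(net$labels)) { reached <- TRUE; break }
        ch <- tcnets:::net_children(net, w)
        ch <- ch[din[as.character(ch)] <= 1L]
        frontier <- c(frontier, setdiff(ch, seen))
        seen <- c(seen, ch)
      }
      expect_true(reached)
    }
  }
})

test_that("display checks: reflexive, MLLSs displayed, negatives", {
  expect_true(displays(a_shape_net(), a_shape_net()))
  expect_true(oracle_displays(a_shape_net(), a_shape_net()))
  N <- generate_tcnet(7, 2, 1, 0, seed = 19)
  for (m in mlls_set(N)) {
    expect_true(displays(N, m))
    expect_true(oracle_displays(N, m))
  }
  ## a tree displays no tree with a different cherry structure
  t1 <- caterpillar3()                                   # cherry {a,b}
  t2 <- phylo_network(rbind(c(1, 2), c(2, 3), c(2, 6), c(3, 4), c(3, 5)),
                      c(`4` = "b", `5` = "c", `6` = "a"))  # cherry {b,c}
  expect_false(displays(t1, t2))
  expect_false(oracle_displays(t1, t2))
})

test_that("extended Newick round-trips preserve the network", {
  for (net in c(list(cherry_net(), a_shape_net(), h_shape_net(),
                     single_leaf_net()), sample_nets(6, seed = 23))) {
    s <- write_enewick(net)
    expect_true(tc_isomorphic(read_enewick(s), net))
  }
  ## labels needing quotes (as produced by pendant collapse)
  n <- phylo_network(rbind(c(1, 2), c(2, 3), c(2, 4)),
                     c(`3` = "{v,w}", `4` = "plain"))
  expect_true(tc_isomorphic(read_enewick(write_enewick(n)), n))
  ## plain Newick without the root edge is accepted and normalized
  m <- read_enewick("(x,y);")
  expect_true(tc_isomorphic(m, cherry_net()))
  ## branch lengths are parsed and discarded
  m2 <- read_enewick("((x:0.1,y:2e-3):1);")
  expect_true(tc_isomorphic(m2, cherry_net()))
})

test_that("edge-list debug format round-trips", {
  f <- withr::local_tempfile()
  net <- h_shape_net()
  write_edgelist(net, f)
  expect_true(tc_isomorphic(read_edgelist(f), net))
})
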