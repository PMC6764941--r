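## ---- the deletion / cleanup calculus ---------------------------------------

#' Clean up a directed graph into a phylogenetic network
#'
#' Applies, until none is applicable: delete an unlabelled outdegree-0 node;
#' suppress an indegree-1 outdegree-1 node; replace a pair of parallel edges
#' by a single edge (which leaves both endpoints indegree-1 outdegree-1, so
#' they are subsequently suppressed).  The fixpoint is the same for every
#' order of rule application on graphs arising from legal reticulation-edge
#' deletions; the default order applies the parallel-edge rule first, then
#' suppression, then sink deletion.
#'
#' @param edges two-column integer matrix of directed edges.
#' @param labels named character vector (leaf id -> taxon).
#' @param root root node id.
#' @param order `"priority"` (default) or `"random"`: with `"random"` one
#'   uniformly chosen applicable rule instance is applied at a time (used to
#'   assert confluence in tests; draws from the current RNG stream).
#' @return a validated `phylo_network`; an error is raised if the fixpoint
#'   violates the network invariants (which signals an illegal deletion
#'   sequence).
#' @export
cleanup_graph <- function(edges, labels, root, order = c("priority", "random")) {
  order <- match.arg(order)
  edges <- matrix(as.integer(edges), ncol = 2L)
  labelled <- as.integer(names(labels))
  repeat {
    if (nrow(edges) == 0L) stop("cleanup removed every edge: illegal deletion")
    nodes <- sort(unique(c(edges[, 1L], edges[, 2L])))
    din <- tabulate(match(edges[, 2L], nodes), length(nodes))
    dout <- tabulate(match(edges[, 1L], nodes), length(nodes))
    ## applicable rule instances
    key <- paste(edges[, 1L], edges[, 2L])
    par_rows <- which(duplicated(key))                     # parallel-edge rule
    sinks <- nodes[dout == 0L & !(nodes %in% labelled)]    # unlabelled sinks
    supp <- nodes[din == 1L & dout == 1L]                  # suppressible
    if (!length(par_rows) && !length(sinks) && !length(supp)) break
    if (order == "priority") {
      if (length(par_rows)) {
        edges <- edges[-par_rows[1L], , drop = FALSE]
      } else if (length(supp)) {
        edges <- suppress_node(edges, supp[1L])
      } else {
        edges <- edges[edges[, 1L] != sinks[1L] & edges[, 2L] != sinks[1L], ,
                       drop = FALSE]
      }
    } else {
      ops <- c(if (length(par_rows)) paste0("p", par_rows),
               if (length(sinks)) paste0("d", sinks),
               if (length(supp)) paste0("s", supp))
      pick <- ops[sample.int(length(ops), 1L)]
      what <- substr(pick, 1L, 1L)
      id <- as.integer(substring(pick, 2L))
      edges <- switch(what,
        p = edges[-id, , drop = FALSE],
        d = edges[edges[, 1L] != id & edges[, 2L] != id, , drop = FALSE],
        s = suppress_node(edges, id))
    }
  }
  nodes <- sort(unique(c(edges[, 1L], edges[, 2L])))
  if (!(root %in% nodes)) stop("cleanup deleted the root: illegal deletion")
  labels <- labels[as.integer(names(labels)) %in% nodes]
  phylo_network(edges, labels, root = root, check = TRUE)
}

suppress_node <- function(edges, v) {
  p <- edges[edges[, 2L] == v, 1L]
  c <- edges[edges[, 1L] == v, 2L]
  stopifnot(length(p) == 1L, length(c) == 1L)
  edges <- edges[edges[, 1L] != v & edges[, 2L] != v, , drop = FALSE]
  rbind(edges, c(p, c))
}

## delete the given edges (matrix rows) from net, then clean up
delete_edges_cleanup <- function(net, del, order = "priority") {
  e <- net$edges
  keep <- rep(TRUE, nrow(e))
  for (i in seq_len(nrow(del))) {
    hit <- which(e[, 1L] == del[i, 1L] & e[, 2L] == del[i, 2L] & keep)
    if (!length(hit)) stop("edge (", del[i, 1L], ",", del[i, 2L],
                           ") not present")
    keep[hit[1L]] <- FALSE
  }
  cleanup_graph(e[keep, , drop = FALSE], net$labels, net$root, order = order)
}

#' Delete a single reticulation edge (maximum subnetwork)
#'
#' Removes the given reticulation edge and cleans up; the result is the
#' maximum subnetwork of `net` associated with that edge.  For a valid edge
#' (every reticulation edge of a tree-child network is valid) the result has
#' exactly 2 nodes and 3 edges fewer than `net`.
#'
#' @param net a validated `phylo_network`.
#' @param edge length-2 integer vector `(parent, child)`; the child must be a
#'   reticulation.
#' @return a `phylo_network`.
#' @export
delete_reticulation_edge <- function(net, edge) {
  if (!is_reticulation(net, edge[2L]))
    stop("(", edge[1L], ",", edge[2L], ") is not a reticulation edge")
  delete_edges_cleanup(net, matrix(as.integer(edge), ncol = 2L))
}

#' Is a reticulation edge valid?
#'
#' A reticulation edge deletion is valid when the cleaned-up subnetwork has
#' exactly 2 nodes and 3 edges fewer than the original network, i.e. only the
#' edge itself is deleted and its endpoints suppressed.
#'
#' @inheritParams delete_reticulation_edge
#' @return logical scalar.
#' @export
is_valid_edge <- function(net, edge) {
  sub <- delete_reticulation_edge(net, edge)
  length(net_nodes(net)) - length(net_nodes(sub)) == 2L &&
    nrow(net$edges) - nrow(sub$edges) == 3L
}

## local validity test: deleting (u, v) removes exactly 2 nodes and 3 edges
## iff u is a tree node and the two suppressions create no parallel edge
## (no triangle through u or v, and (u, v) is not the middle of a diamond)
edge_valid_local <- function(net, edge) {
  u <- edge[1L]; v <- edge[2L]
  e <- net$edges
  if (sum(e[, 2L] == u) != 1L) return(FALSE)        # u must be a tree node
  pu <- e[e[, 2L] == u, 1L]
  cu <- setdiff(e[e[, 1L] == u, 2L], v)
  pv <- setdiff(e[e[, 2L] == v, 1L], u)
  cv <- e[e[, 1L] == v, 2L]
  if (any(e[, 1L] == pu & e[, 2L] == cu)) return(FALSE)
  if (any(e[, 1L] == pv & e[, 2L] == cv)) return(FALSE)
  !(pu == pv && cu == cv)
}

#' All maximum subnetworks of a network
#'
#' One subnetwork per reticulation edge (two per reticulation), each obtained
#' by deleting that edge and cleaning up.  Results may be pairwise
#' isomorphic; no deduplication is performed.
#'
#' @param net a validated `phylo_network`.
#' @return list of `phylo_network`s (empty for a tree).
#' @export
maximum_subnetworks <- function(net) {
  re <- reticulation_edges(net)
  lapply(seq_len(nrow(re)),
         function(i) delete_reticulation_edge(net, re[i, ]))
}

#' Maximum lower-level subnetworks (MLLSs)
#'
#' For a level-k network (k >= 1), an MLLS is obtained by deleting exactly
#' one valid reticulation edge from every level-k blob (and cleaning up).
#' The full choice product over blobs is returned, without deduplication up
#' to isomorphism: a level-k blob with r reticulations contributes 2r
#' choices, all of which are valid in a tree-child network.
#'
#' @param net a validated `phylo_network` of level at least 1.
#' @return list of `phylo_network`s, each of level at most k-1.
#' @export
mlls_set <- function(net) {
  k <- network_level(net)
  if (k < 1L) stop("MLLSs are undefined for a tree (level-0 network)")
  blobs <- network_blobs(net)
  top <- Filter(function(b) b$level == k, blobs)
  per_blob <- lapply(top, function(b) {
    e <- blob_ret_edges(net, b)
    ok <- vapply(seq_len(nrow(e)), function(i) edge_valid_local(net, e[i, ]),
                 logical(1))
    if (!any(ok))
      stop("a level-", k, " blob has no valid reticulation edge to delete")
    e[ok, , drop = FALSE]
  })
  idx <- lapply(per_blob, function(e) seq_len(nrow(e)))
  grid <- do.call(expand.grid, idx)
  out <- vector("list", nrow(grid))
  for (j in seq_len(nrow(grid))) {
    del <- do.call(rbind, lapply(seq_along(per_blob), function(i) {
      per_blob[[i]][grid[j, i], , drop = FALSE]
    }))
    out[[j]] <- delete_edges_cleanup(net, del)
  }
  out
}

## reticulation edges whose head lies in blob b (both endpoints are members)
blob_ret_edges <- function(net, b) {
  din <- net_indeg(net)
  ret <- b$members[din[as.character(b$members)] == 2L]
  net$edges[net$edges[, 2L] %in% ret, , drop = FALSE]
}

## ---- reticulated cherry shapes ---------------------------------------------

#' Locate a reticulated cherry shape on two nodes
#'
#' Two non-reticulation nodes `x`, `y` form a reticulated cherry shape
#' `<x,y>` when the parent `p_y` of `y` is a reticulation, the parent `p_x`
#' of `x` is also a parent of `p_y`, and `g_y` is the other parent of `p_y`
#' ("the reticulation is on `y`").
#'
#' @param net a `phylo_network`.
#' @param x,y node ids, or taxon labels for leaves.
#' @return a list with elements `x`, `y`, `p_x`, `p_y`, `g_y`, or `NULL` when
#'   the nodes do not form the shape.
#' @export
ret_cherry_shape <- function(net, x, y) {
  x <- resolve_leaf(net, x); y <- resolve_leaf(net, y)
  if (is_reticulation(net, x) || is_reticulation(net, y)) return(NULL)
  py <- net_parents(net, y)
  if (length(py) != 1L || !is_reticulation(net, py)) return(NULL)
  px <- net_parents(net, x)
  if (length(px) != 1L) return(NULL)
  gp <- net_parents(net, py)
  if (!(px %in% gp)) return(NULL)
  list(x = x, y = y, p_x = px, p_y = py, g_y = setdiff(gp, px))
}

check_shape <- function(net, shape) {
  s <- ret_cherry_shape(net, shape$x, shape$y)
  if (is.null(s) || s$p_x != shape$p_x || s$p_y != shape$p_y ||
      s$g_y != shape$g_y)
    stop("the given nodes do not form a reticulated cherry shape")
  s
}

#' Cut or isolate a reticulated cherry shape
#'
#' Cutting `<x,y>` deletes the reticulation edge `(p_x, p_y)`; isolating
#' deletes `(g_y, p_y)`.  Both are followed by cleanup and return a maximum
#' subnetwork.
#'
#' @param net a validated `phylo_network`.
#' @param shape a shape as returned by [ret_cherry_shape()].
#' @return a `phylo_network`.
#' @export
cut_shape <- function(net, shape) {
  s <- check_shape(net, shape)
  delete_reticulation_edge(net, c(s$p_x, s$p_y))
}

#' @rdname cut_shape
#' @export
isolate_shape <- function(net, shape) {
  s <- check_shape(net, shape)
  delete_reticulation_edge(net, c(s$g_y, s$p_y))
}

#' Reduce a cherry or reticulated cherry on a leaf pair
#'
#' A cherry on leaves `{x, y}` is reduced by deleting `y` and cleaning up.  A
#' reticulated cherry with the reticulation on `y` is reduced by isolating
#' `<x,y>` and then reducing the resulting cherry.  The result is a network
#' on one fewer taxon, and is tree-child whenever the input is.
#'
#' @param net a validated `phylo_network`.
#' @param x,y leaf labels (or ids); the reticulation, if any, must be on `y`.
#' @return a `phylo_network`.
#' @export
reduce_pair <- function(net, x, y) {
  x <- resolve_leaf(net, x); y <- resolve_leaf(net, y)
  px <- net_parents(net, x); py <- net_parents(net, y)
  if (length(px) == 1L && length(py) == 1L && px == py) {
    ## cherry: delete leaf y, clean up
    e <- net$edges
    e <- e[!(e[, 1L] == py & e[, 2L] == y), , drop = FALSE]
    labels <- net$labels[names(net$labels) != as.character(y)]
    return(cleanup_graph(e, labels, net$root))
  }
  s <- ret_cherry_shape(net, x, y)
  if (is.null(s)) stop("leaves do not form a cherry or reticulated cherry ",
                       "with the reticulation on the second leaf")
  iso <- isolate_shape(net, s)
  Recall(iso, x, y)
}

## ---- pendant subnetworks ---------------------------------------------------

## pendant subnetworks: label-set key -> list(root_edge_head, nodes).
## The edge into a node v heads a pendant subnetwork exactly when v is not a
## reticulation and every reticulation strictly below v has both parents
## below v (so the only edge entering the set of descendants of v is the
## edge into v itself).
pendant_index <- function(net, B = NULL) {
  if (is.null(B)) B <- below_matrix(net)
  nodes <- net_nodes(net)
  din <- tabulate(match(net$edges[, 2L], nodes), length(nodes))
  ret_pos <- which(din == 2L)
  rp_pos <- lapply(ret_pos, function(i)
    match(net_parents(net, nodes[i]), nodes))
  ## leaf ids arranged by sorted taxon label, so selections stay sorted
  lab_sorted <- net$labels[order(unname(net$labels))]
  leaf_pos <- match(as.integer(names(lab_sorted)), nodes)
  out <- list()
  for (vp in which(din == 1L)) {
    vb <- B[vp, ]
    ok <- TRUE
    for (i in seq_along(ret_pos)) {
      if (ret_pos[i] != vp && vb[ret_pos[i]] &&
          !all(vb[rp_pos[[i]]])) { ok <- FALSE; break }
    }
    if (!ok) next
    labs <- unname(lab_sorted[vb[leaf_pos]])
    out[[paste(labs, collapse = "\r")]] <-
      list(head = nodes[vp], labs = labs, desc_pos = which(vb))
  }
  out
}

## standalone network for the pendant rooted at node v (fresh root above v)
extract_pendant <- function(net, v) {
  nodes <- descendant_nodes(net, v)
  e <- net$edges[net$edges[, 1L] %in% nodes & net$edges[, 2L] %in% nodes, ,
                 drop = FALSE]
  root <- max(net_nodes(net)) + 1L
  e <- rbind(matrix(c(root, v), ncol = 2L), e)
  labels <- net$labels[as.integer(names(net$labels)) %in% nodes]
  phylo_network(e, labels, root = root, check = FALSE)
}

## replace the pendant rooted at node v (leaf set A) by a synthetic leaf
collapse_at <- function(net, v, A) {
  pendant <- extract_pendant(net, v)
  nodes <- setdiff(descendant_nodes(net, v), v)
  e <- net$edges
  e <- e[!(e[, 1L] %in% nodes | e[, 2L] %in% nodes), , drop = FALSE]
  lab <- synthetic_label(A)
  if (lab %in% net$labels) stop("synthetic label collision: ", lab)
  labels <- net$labels[!(as.integer(names(net$labels)) %in% nodes)]
  labels[as.character(v)] <- lab
  list(net = phylo_network(e, labels, root = net$root, check = FALSE),
       pendant = pendant, label = lab)
}

descendant_nodes <- function(net, v) {
  seen <- v; frontier <- v
  while (length(frontier)) {
    nxt <- setdiff(unique(net$edges[net$edges[, 1L] %in% frontier, 2L]), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  seen
}

## canonical synthetic leaf label for a collapsed pendant on label set labs
synthetic_label <- function(labs) paste0("{", paste(sort(labs), collapse = ","), "}")

#' Collapse or expand a pendant subnetwork
#'
#' `collapse_pendant` replaces the pendant subnetwork whose leaf-descendant
#' set is `A` by a single fresh leaf labelled with the canonical sorted
#' rendering of `A` (e.g. `"{v,w}"`), and returns both the collapsed network
#' and the detached pendant (as a standalone network with its own root
#' edge).  `expand_pendant` is the exact inverse: it substitutes a pendant
#' network back for a leaf.
#'
#' @param net a validated `phylo_network`.
#' @param A character vector of taxon labels; must be the leaf-descendant set
#'   of the head of some cut-edge of `net`.
#' @return for `collapse_pendant`, a list `list(net =, pendant =, label =)`;
#'   for `expand_pendant`, a `phylo_network`.
#' @export
collapse_pendant <- function(net, A) {
  idx <- pendant_index(net)
  hit <- idx[[label_key(A)]]
  if (is.null(hit))
    stop("{", paste(A, collapse = ","), "} is not the leaf set of a pendant ",
         "subnetwork")
  out <- collapse_at(net, hit$head, A)
  bad <- validate_network(out$net)
  if (length(bad)) stop("collapse produced an invalid network: ",
                        paste(bad, collapse = "; "))
  out
}

#' @rdname collapse_pendant
#' @param leaf_label label of the leaf of `net` to be expanded.
#' @param pendant a standalone pendant network (with its own root edge) whose
#'   root child replaces the leaf.
#' @export
expand_pendant <- function(net, leaf_label, pendant) {
  v <- resolve_leaf(net, leaf_label)
  off <- max(net_nodes(net)) + 1L
  pc <- net_children(pendant, pendant$root)   # child of the pendant root
  pe <- pendant$edges
  pe <- pe[pe[, 1L] != pendant$root, , drop = FALSE]
  remap <- function(id) id + off
  pe <- matrix(remap(pe), ncol = 2L)
  ## reuse the id of leaf v for the pendant root child
  pe[pe == remap(pc)] <- v
  labels <- net$labels[names(net$labels) != as.character(v)]
  plabs <- pendant$labels
  pids <- remap(as.integer(names(plabs)))
  pids[as.integer(names(plabs)) == pc] <- v
  names(plabs) <- as.character(pids)
  phylo_network(rbind(net$edges, pe), c(labels, plabs), root = net$root)
}
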