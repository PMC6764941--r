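#' @importFrom stats setNames
NULL

#' Construct a rooted binary phylogenetic network
#'
#' A `phylo_network` is a rooted binary directed acyclic graph in which every
#' node is the root (indegree 0, outdegree 1), a leaf (indegree 1, outdegree
#' 0, labelled by a taxon), a tree node (indegree 1, outdegree 2) or a
#' reticulation (indegree 2, outdegree 1).  Node ids are opaque positive
#' integers and are stable across operations that do not delete them;
#' operations that delete nodes return fresh copies.
#'
#' @param edges two-column integer matrix of directed edges (parent, child).
#' @param labels named character vector mapping leaf node ids (names, coerced
#'   with `as.character`) to taxon labels.
#' @param root integer id of the root node.  If `NULL`, the unique node of
#'   indegree 0 is used.
#' @param check if `TRUE` (default) the invariants are verified with
#'   [validate_network()] and construction fails on any violation.
#' @return an object of class `phylo_network`.
#' @examples
#' cherry <- phylo_network(rbind(c(1, 2), c(2, 3), c(2, 4)),
#'                         c(`3` = "x", `4` = "y"))
#' @export
phylo_network <- function(edges, labels, root = NULL, check = TRUE) {
  edges <- matrix(as.integer(edges), ncol = 2)
  labels <- stats::setNames(as.character(labels), as.character(names(labels)))
  if (is.null(root)) {
    heads <- unique(edges[, 2L])
    tails <- unique(edges[, 1L])
    r <- setdiff(tails, heads)
    if (length(r) != 1L) stop("cannot identify a unique root")
    root <- r
  }
  net <- structure(list(edges = edges, labels = labels,
                        root = as.integer(root),
                        nodes = sort(unique(c(edges[, 1L], edges[, 2L],
                                              as.integer(root))))),
                   class = "phylo_network")
  if (check) {
    bad <- validate_network(net)
    if (length(bad)) stop("invalid network: ", paste(bad, collapse = "; "))
  }
  net
}

net_nodes <- function(net) {
  if (!is.null(net$nodes)) return(net$nodes)
  sort(unique(c(net$edges[, 1L], net$edges[, 2L], net$root)))
}

## Kahn topological order of the node ids (children after parents);
## returns NULL when the graph has a directed cycle
topo_order <- function(edges, nodes) {
  n <- length(nodes)
  din <- tabulate(match(edges[, 2L], nodes), n)
  kid_idx <- split(match(edges[, 2L], nodes), match(edges[, 1L], nodes))
  ord <- integer(n)
  ready <- which(din == 0L)
  m <- 0L
  while (length(ready)) {
    i <- ready[1L]; ready <- ready[-1L]
    m <- m + 1L; ord[m] <- i
    for (j in kid_idx[[as.character(i)]]) {
      din[j] <- din[j] - 1L
      if (din[j] == 0L) ready <- c(ready, j)
    }
  }
  if (m < n) return(NULL)
  nodes[ord]
}

net_children <- function(net, v) net$edges[net$edges[, 1L] == v, 2L]

net_parents <- function(net, v) net$edges[net$edges[, 2L] == v, 1L]

net_indeg <- function(net) {
  nodes <- net_nodes(net)
  stats::setNames(tabulate(match(net$edges[, 2L], nodes), length(nodes)), nodes)
}

net_outdeg <- function(net) {
  nodes <- net_nodes(net)
  stats::setNames(tabulate(match(net$edges[, 1L], nodes), length(nodes)), nodes)
}

#' Leaf node ids of a network
#' @param net a `phylo_network`.
#' @return integer vector of leaf node ids, named by taxon label.
#' @export
leaves <- function(net) {
  ids <- as.integer(names(net$labels))
  stats::setNames(ids, unname(net$labels))
}

#' Taxon set of a network
#' @param net a `phylo_network`.
#' @return sorted character vector of taxon labels.
#' @export
taxa <- function(net) sort(unname(net$labels))

## resolve a leaf given as a taxon label or a node id
resolve_leaf <- function(net, x) {
  if (is.character(x)) {
    hit <- names(net$labels)[net$labels == x]
    if (length(hit) != 1L) stop("no unique leaf labelled ", x)
    return(as.integer(hit))
  }
  as.integer(x)
}

is_reticulation <- function(net, v) {
  sum(net$edges[, 2L] == v) == 2L
}

is_leaf_node <- function(net, v) as.character(v) %in% names(net$labels)

#' Validate the structural invariants of a network
#'
#' Checks the degree profile of every node (one indegree-0 outdegree-1 root;
#' leaves with indegree 1 and outdegree 0; tree nodes 1-in 2-out;
#' reticulations 2-in 1-out), acyclicity, absence of parallel edges, the
#' bijection between leaf nodes and taxon labels, and reachability of every
#' node from the root.
#'
#' @param net a `phylo_network` (possibly malformed; this is a diagnostic).
#' @return character vector of human-readable violations; empty when valid.
#' @export
validate_network <- function(net) {
  bad <- character()
  e <- net$edges
  if (!is.matrix(e) || ncol(e) != 2L || nrow(e) < 1L)
    return("edge set must be a non-empty two-column matrix")
  if (anyDuplicated(paste(e[, 1L], e[, 2L])))
    bad <- c(bad, "parallel edges present")
  nodes <- net_nodes(net)
  din <- net_indeg(net)
  dout <- net_outdeg(net)
  roots <- nodes[din == 0L]
  if (length(roots) != 1L) {
    bad <- c(bad, paste0(length(roots), " nodes of indegree 0 (need exactly 1)"))
  } else {
    if (roots != net$root)
      bad <- c(bad, paste0("stored root ", net$root,
                           " is not the indegree-0 node ", roots))
    if (dout[as.character(roots)] != 1L)
      bad <- c(bad, paste0("root ", roots, " has outdegree ",
                           dout[as.character(roots)], " (need 1)"))
  }
  labelled <- as.integer(names(net$labels))
  if (anyDuplicated(unname(net$labels)))
    bad <- c(bad, "leaf labels are not unique")
  if (length(labelled) < 1L) bad <- c(bad, "no leaves")
  for (v in nodes) {
    if (length(roots) == 1L && v == roots) next
    i <- din[as.character(v)]; o <- dout[as.character(v)]
    lab <- v %in% labelled
    ok <- (lab && i == 1L && o == 0L) ||       # leaf
      (!lab && i == 1L && o == 2L) ||          # tree node
      (!lab && i == 2L && o == 1L)             # reticulation
    if (!ok)
      bad <- c(bad, paste0("node ", v, " has indegree ", i, ", outdegree ", o,
                           if (lab) " (labelled)" else " (unlabelled)",
                           ": not a leaf, tree node or reticulation"))
  }
  bad_leaf <- labelled[!(labelled %in% nodes)]
  if (length(bad_leaf))
    bad <- c(bad, paste0("labelled node(s) absent from graph: ",
                         paste(bad_leaf, collapse = ",")))
  acyclic <- !is.null(topo_order(e, nodes))
  if (!acyclic) bad <- c(bad, "not acyclic")
  if (length(roots) == 1L && acyclic) {
    seen <- roots; frontier <- roots
    while (length(frontier)) {
      nxt <- setdiff(unique(e[e[, 1L] %in% frontier, 2L]), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) != length(nodes))
      bad <- c(bad, "not all nodes reachable from the root")
  }
  bad
}

#' Test the tree-child property
#'
#' A network is tree-child when every non-leaf node has at least one child
#' that is a tree node or a leaf (equivalently, a non-reticulation child), so
#' that every node has a tree path down to some leaf.
#'
#' @param net a validated `phylo_network`.
#' @return logical scalar.
#' @export
is_tree_child <- function(net) {
  din <- net_indeg(net)
  for (v in unique(net$edges[, 1L])) {
    ch <- net_children(net, v)
    if (!any(din[as.character(ch)] <= 1L)) return(FALSE)
  }
  TRUE
}

## leaf-descendant labels of node v, sorted
desc_leaves <- function(net, v) {
  seen <- v
  frontier <- v
  while (length(frontier)) {
    nxt <- unique(net$edges[net$edges[, 1L] %in% frontier, 2L])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(unname(net$labels[as.character(seen)[as.character(seen) %in%
                                              names(net$labels)]]))
}

label_key <- function(labs) paste(sort(labs), collapse = "\r")

## logical matrix below[v, w]: is w a descendant of v (or v itself)?
below_matrix <- function(net) {
  nodes <- net_nodes(net)
  n <- length(nodes)
  B <- diag(n) > 0
  dimnames(B) <- list(nodes, nodes)
  ord <- topo_order(net$edges, nodes)
  ei <- match(net$edges[, 1L], nodes)
  ej <- match(net$edges[, 2L], nodes)
  for (v in rev(match(ord, nodes))) {
    for (j in ej[ei == v]) B[v, ] <- B[v, ] | B[j, ]
  }
  B
}

#' Blob decomposition of a network
#'
#' A blob is either a maximal biconnected component (at least three nodes) of
#' the underlying undirected graph, or a tree node contained in no such
#' component (a level-0 blob).  The level of a blob is the number of
#' reticulations among its members; the network level is the maximum blob
#' level.  Each blob records its pure node (the unique member with no parent
#' inside the blob) and the leaf-descendant set of that node.  Every tree
#' node and reticulation belongs to exactly one blob; the root and the
#' leaves belong to none.
#'
#' @param net a validated `phylo_network`.
#' @return list of blobs, each a list with elements `members` (integer node
#'   ids), `level`, `pure` (pure node id), `desc` (sorted taxon labels below
#'   the pure node).
#' @export
network_blobs <- function(net) {
  g <- igraph::graph_from_edgelist(matrix(as.character(net$edges), ncol = 2L),
                                   directed = FALSE)
  bc <- igraph::biconnected_components(g)
  comp_members <- list()
  for (comp in bc$components) {
    ids <- as.integer(names(comp))
    if (length(ids) >= 3L) comp_members[[length(comp_members) + 1L]] <- ids
  }
  din <- net_indeg(net)
  in_big <- unique(unlist(comp_members))
  nodes <- net_nodes(net)
  singles <- nodes[!(nodes %in% in_big) & nodes != net$root &
                     !(nodes %in% as.integer(names(net$labels)))]
  blobs <- list()
  for (ids in comp_members) {
    nret <- sum(din[as.character(ids)] == 2L)
    pure <- ids[vapply(ids, function(v) {
      !any(net_parents(net, v) %in% ids)
    }, logical(1))]
    stopifnot(length(pure) == 1L)
    blobs[[length(blobs) + 1L]] <-
      list(members = sort(ids), level = nret, pure = pure,
           desc = desc_leaves(net, pure))
  }
  for (v in singles) {
    blobs[[length(blobs) + 1L]] <-
      list(members = v, level = 0L, pure = v, desc = desc_leaves(net, v))
  }
  if (length(blobs))
    blobs <- blobs[order(vapply(blobs, function(b) b$pure, integer(1)))]
  blobs
}

#' Network level
#'
#' The maximum blob level, i.e. the maximum number of reticulations in any
#' biconnected component; 0 for a tree.
#' @param net a validated `phylo_network`.
#' @return integer scalar.
#' @export
network_level <- function(net) {
  blobs <- network_blobs(net)
  if (!length(blobs)) return(0L)
  max(vapply(blobs, function(b) b$level, integer(1)))
}

#' Number of reticulations
#' @param net a `phylo_network`.
#' @return integer scalar.
#' @export
n_reticulations <- function(net) {
  sum(tabulate(match(net$edges[, 2L], net_nodes(net))) == 2L)
}

## all reticulation edges, as a 2-column matrix
reticulation_edges <- function(net) {
  din <- net_indeg(net)
  ret <- as.integer(names(din)[din == 2L])
  net$edges[net$edges[, 2L] %in% ret, , drop = FALSE]
}

#' Shortest up-down distance between two nodes
#'
#' An up-down path from `u` to `v` first ascends along edges (child to
#' parent) to an apex and then descends (parent to child) to `v`; either part
#' may be empty.  The up-down distance is the length of a shortest such path
#' (`0` when `u == v`), or `Inf` if none exists.  Between two leaves of a
#' connected rooted network the distance is always finite.
#'
#' @param net a `phylo_network`.
#' @param u,v node ids, or taxon labels for leaves.
#' @return a non-negative number, possibly `Inf`.
#' @export
up_down_distance <- function(net, u, v) {
  u <- resolve_leaf(net, u); v <- resolve_leaf(net, v)
  if (u == v) return(0)
  nodes <- net_nodes(net)
  idx <- stats::setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  ## state = node index + (phase - 1) * n ; phase 1 ascending, 2 descending
  dist <- rep(NA_integer_, 2L * n)
  start <- idx[as.character(u)]
  dist[start] <- 0L
  queue <- start
  target <- idx[as.character(v)]
  while (length(queue)) {
    s <- queue[1L]; queue <- queue[-1L]
    ph <- if (s > n) 2L else 1L
    w <- nodes[if (ph == 2L) s - n else s]
    d <- dist[s]
    nbr <- integer()
    if (ph == 1L) {
      nbr <- c(idx[as.character(net_parents(net, w))],
               idx[as.character(net_children(net, w))] + n)
    } else {
      nbr <- idx[as.character(net_children(net, w))] + n
    }
    for (t in nbr) {
      if (is.na(dist[t])) {
        dist[t] <- d + 1L
        tn <- if (t > n) t - n else t
        if (tn == target) return(d + 1L)
        queue <- c(queue, t)
      }
    }
  }
  Inf
}

#' Does a network display another network?
#'
#' `net` displays `candidate` when some choice of deleting, for each
#' reticulation of `net`, at most one of its two incoming edges, followed by
#' cleanup, yields a network isomorphic to `candidate`.  This is a
#' brute-force check over all per-reticulation deletion choices and is
#' intended for validation and tests at small scale.
#'
#' @param net,candidate `phylo_network`s on the same taxon set.
#' @return logical scalar.
#' @export
displays <- function(net, candidate) {
  if (!identical(taxa(net), taxa(candidate)))
    stop("networks are not on the same taxon set")
  re <- reticulation_edges(net)
  rets <- unique(re[, 2L])
  r <- length(rets)
  if (r == 0L) return(tc_isomorphic(net, candidate))
  choices <- vector("list", r)
  for (i in seq_len(r)) {
    inc <- which(re[, 2L] == rets[i])
    choices[[i]] <- c(0L, inc)    # 0 = keep both incoming edges
  }
  grid <- do.call(expand.grid, choices)
  for (j in seq_len(nrow(grid))) {
    del <- as.integer(unlist(grid[j, ]))
    del <- del[del != 0L]
    sub <- tryCatch(
      delete_edges_cleanup(net, re[del, , drop = FALSE]),
      error = function(e) NULL)
    if (!is.null(sub) && tc_isomorphic(sub, candidate)) return(TRUE)
  }
  FALSE
}

#' @export
print.phylo_network <- function(x, ...) {
  nl <- length(x$labels)
  cat(sprintf(
    "rooted binary phylogenetic network: %d taxa, %d reticulations, level %d\n",
    nl, n_reticulations(x), network_level(x)))
  cat("taxa:", paste(taxa(x), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.phylo_network <- function(object, ...) {
  blobs <- network_blobs(object)
  lv <- vapply(blobs, function(b) b$level, integer(1))
  cat(sprintf("%d taxa, %d nodes, %d edges, %d reticulations\n",
              length(object$labels), length(net_nodes(object)),
              nrow(object$edges), n_reticulations(object)))
  cat(sprintf("level %d; %d blobs (levels: %s)\n",
              network_level(object), length(blobs),
              paste(sort(lv, decreasing = TRUE), collapse = " ")))
  for (b in blobs[order(-lv)]) {
    cat(sprintf("  blob level %d, pure node %d, descendants {%s}\n",
                b$level, b$pure, paste(b$desc, collapse = ",")))
  }
  invisible(object)
}
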