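## ---- isomorphism of networks -----------------------------------------------

## path-count (mu) matrix: one row per node, one column per taxon, entry =
## number of directed paths from the node to that leaf
mu_matrix <- function(net) {
  nodes <- net_nodes(net)
  taxa <- taxa(net)
  idx <- stats::setNames(seq_along(nodes), nodes)
  mu <- matrix(0, nrow = length(nodes), ncol = length(taxa),
               dimnames = list(nodes, taxa))
  for (l in names(net$labels)) mu[l, net$labels[[l]]] <- 1
  ## process in reverse topological order (children before parents)
  ord <- rev(topo_order(net$edges, nodes))
  for (v in ord) {
    ch <- net_children(net, v)
    if (length(ch))
      mu[as.character(v), ] <- colSums(mu[as.character(ch), , drop = FALSE])
  }
  mu
}

## per-row strings of a count matrix (vectorized row paste)
mu_row_strings <- function(mu) {
  do.call(paste, c(lapply(seq_len(ncol(mu)), function(j) mu[, j]), sep = ","))
}

## canonical string of the path-count representation (characterizes
## tree-child networks up to isomorphism, together with the taxon set)
mu_canonical <- function(net, mu = NULL) {
  if (is.null(mu)) mu <- mu_matrix(net)
  paste(c(colnames(mu), sort(mu_row_strings(mu))), collapse = ";")
}

#' Are two networks isomorphic?
#'
#' Tests for a label-preserving digraph isomorphism.  For two tree-child
#' networks this uses the canonical path-count representation (the multiset,
#' over nodes, of vectors counting directed paths from the node to each
#' leaf), which characterizes tree-child networks and is comparable in
#' O(|X|^2); for general networks it falls back to a VF2 search on the
#' directed graphs with leaf labels encoded as vertex colours.
#'
#' @param n1,n2 `phylo_network`s.  An error is raised when the taxon sets
#'   differ.
#' @param method `"auto"` (path counts when both networks are tree-child),
#'   `"mu"` or `"vf2"`.
#' @return logical scalar.
#' @export
tc_isomorphic <- function(n1, n2, method = c("auto", "mu", "vf2")) {
  method <- match.arg(method)
  if (!identical(taxa(n1), taxa(n2)))
    stop("networks are not on the same taxon set")
  if (length(net_nodes(n1)) != length(net_nodes(n2)) ||
      nrow(n1$edges) != nrow(n2$edges)) return(FALSE)
  if (method == "auto")
    method <- if (is_tree_child(n1) && is_tree_child(n2)) "mu" else "vf2"
  if (method == "mu")
    return(identical(mu_canonical(n1), mu_canonical(n2)))
  iso_vf2(n1, n2)
}

iso_vf2 <- function(n1, n2) {
  colour <- function(net) {
    tx <- taxa(net)
    nodes <- as.character(net_nodes(net))
    cl <- integer(length(nodes))
    for (i in seq_along(nodes)) {
      lb <- net$labels[nodes[i]]
      if (!is.na(lb)) cl[i] <- match(unname(lb), tx)
    }
    stats::setNames(cl, nodes)
  }
  g1 <- igraph::graph_from_edgelist(matrix(as.character(n1$edges), ncol = 2L),
                                    directed = TRUE)
  g2 <- igraph::graph_from_edgelist(matrix(as.character(n2$edges), ncol = 2L),
                                    directed = TRUE)
  c1 <- colour(n1)[igraph::V(g1)$name]
  c2 <- colour(n2)[igraph::V(g2)$name]
  igraph::isomorphic(g1, g2, method = "vf2",
                     vertex.color1 = c1, vertex.color2 = c2)
}

## is network `x` isomorphic to some element of list `lst`?
iso_in <- function(x, lst) {
  for (y in lst) if (tc_isomorphic(x, y)) return(TRUE)
  FALSE
}

## do two lists of networks coincide as sets up to isomorphism?
iso_setequal <- function(a, b) {
  all(vapply(a, iso_in, logical(1), lst = b)) &&
    all(vapply(b, iso_in, logical(1), lst = a))
}
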