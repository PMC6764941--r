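## ---- brute-force oracles ---------------------------------------------------
## Independent small-scale recomputations of the mainline operations, used by
## the property tests.  They deliberately take different routes: all-pairs
## directed distances instead of the two-phase search, motif matching
## instead of the distance-driven classifier, and exhaustive deletion-set
## enumeration instead of the per-blob choice product.

## all-pairs shortest directed-path distance matrix (Inf when unreachable)
directed_distances <- function(net) {
  nodes <- net_nodes(net)
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(n)) {
    frontier <- nodes[i]; d <- 0
    while (length(frontier)) {
      nxt <- unique(net$edges[net$edges[, 1L] %in% frontier, 2L])
      nxt <- nxt[!is.finite(D[i, as.character(nxt)])]
      d <- d + 1
      D[i, as.character(nxt)] <- d
      frontier <- nxt
    }
  }
  D
}

#' Brute-force oracles
#'
#' `oracle_up_down_distance` computes the shortest up-down distance as the
#' minimum over all apex nodes of the sum of directed-path distances from
#' the apex to the two endpoints.  `oracle_classify_pair` classifies a leaf
#' pair by direct motif matching of the eight shape definitions.
#' `oracle_displays` enumerates all subsets of reticulation edges (not just
#' one-per-reticulation choices), cleaning up tolerantly.
#' `oracle_mlls_set` enumerates every per-reticulation deletion choice and
#' keeps the subnetworks of level at most k-1 with the maximum number of
#' edges, deduplicated up to isomorphism.  All are exponential and intended
#' for small test networks only.
#'
#' @param net a `phylo_network`.
#' @param u,v,x,y nodes / leaves.
#' @param candidate a `phylo_network` on the same taxa.
#' @name oracles
NULL

#' @rdname oracles
#' @export
oracle_up_down_distance <- function(net, u, v) {
  u <- resolve_leaf(net, u); v <- resolve_leaf(net, v)
  D <- directed_distances(net)
  min(D[, as.character(u)] + D[, as.character(v)])
}

#' @rdname oracles
#' @export
oracle_classify_pair <- function(net, x, y) {
  xi <- resolve_leaf(net, x); yi <- resolve_leaf(net, y)
  px <- net_parents(net, xi); py <- net_parents(net, yi)
  has_edge <- function(a, b) any(net$edges[, 1L] == a & net$edges[, 2L] == b)
  if (px == py) return(new_shape("LAMBDA_CHERRY", x, y))
  rx <- is_reticulation(net, px); ry <- is_reticulation(net, py)
  if (!rx && !ry) {
    if (has_edge(px, py)) return(new_shape("lambda_xy", x, y))
    if (has_edge(py, px)) return(new_shape("lambda_yx", x, y))
  }
  if (ry && px %in% net_parents(net, py)) {
    g <- setdiff(net_parents(net, py), px)
    kind <- if (identical(net_parents(net, px), g)) "A_xy" else "H_xy"
    return(new_shape(kind, x, y))
  }
  if (rx && py %in% net_parents(net, px)) {
    g <- setdiff(net_parents(net, px), py)
    kind <- if (identical(net_parents(net, py), g)) "A_yx" else "H_yx"
    return(new_shape(kind, x, y))
  }
  stopifnot(oracle_up_down_distance(net, xi, yi) >= 4)
  new_shape("PI", x, y)
}

#' @rdname oracles
#' @export
oracle_displays <- function(net, candidate) {
  re <- reticulation_edges(net)
  nre <- nrow(re)
  if (nre > 12L) stop("oracle_displays: too many reticulation edges")
  for (mask in 0:(2^nre - 1)) {
    rows <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nre) - 1L)) != 0L)
    sub <- tryCatch(delete_edges_cleanup(net, re[rows, , drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(sub) && identical(taxa(sub), taxa(candidate)) &&
        tc_isomorphic(sub, candidate, method = "vf2")) return(TRUE)
  }
  FALSE
}

#' @rdname oracles
#' @export
oracle_mlls_set <- function(net) {
  k <- network_level(net)
  if (k < 1L) stop("MLLSs are undefined for a tree")
  re <- reticulation_edges(net)
  rets <- unique(re[, 2L])
  choices <- lapply(rets, function(r) c(0L, which(re[, 2L] == r)))
  grid <- do.call(expand.grid, choices)
  subs <- list()
  for (j in seq_len(nrow(grid))) {
    rows <- as.integer(unlist(grid[j, ]))
    rows <- rows[rows != 0L]
    if (!length(rows)) next                 # the network itself
    sub <- tryCatch(delete_edges_cleanup(net, re[rows, , drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(sub) && network_level(sub) <= k - 1L)
      subs[[length(subs) + 1L]] <- sub
  }
  ne <- vapply(subs, function(s) nrow(s$edges), integer(1))
  subs <- subs[ne == max(ne)]
  out <- list()
  for (s in subs) if (!iso_in(s, out)) out[[length(out) + 1L]] <- s
  out
}
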