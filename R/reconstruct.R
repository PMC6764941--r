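## ---- reconstruction from MLLSs (TCMLLS reconstruction) ---------------------

## lowest reticulated cherry shape of a blob: a tree node of the blob with no
## tree node of the blob below it has one reticulation child c (in the blob)
## and one non-reticulation child x; the shape is <x, child(c)>
lowest_shape_of_blob <- function(net, blob) {
  din <- net_indeg(net)
  tn <- blob$members[din[as.character(blob$members)] == 1L]
  lowest <- tn[vapply(tn, function(t) {
    !any(setdiff(descendant_nodes(net, t), t) %in% tn)
  }, logical(1))]
  for (t in sort(lowest)) {
    ch <- net_children(net, t)
    ret <- ch[vapply(ch, is_reticulation, logical(1), net = net)]
    if (length(ret) != 1L) next
    x <- setdiff(ch, ret)
    y <- net_children(net, ret)
    g <- setdiff(net_parents(net, ret), t)
    return(list(x = x, y = y, p_x = t, p_y = ret, g_y = g))
  }
  stop("blob has no lowest reticulated cherry shape")
}

## a lowest reticulation of the network (no reticulation strictly below it),
## together with its reticulated cherry shape
lowest_reticulation_shape <- function(net) {
  din <- net_indeg(net)
  rets <- as.integer(names(din)[din == 2L])
  if (!length(rets)) stop("network has no reticulation")
  low <- rets[vapply(rets, function(r) {
    !any(setdiff(descendant_nodes(net, r), r) %in% rets)
  }, logical(1))]
  r <- min(low)
  y <- net_children(net, r)
  for (t in sort(net_parents(net, r))) {
    x <- setdiff(net_children(net, t), r)
    if (!is_reticulation(net, x)) {
      return(list(x = x, y = y, p_x = t, p_y = r,
                  g_y = setdiff(net_parents(net, r), t)))
    }
  }
  stop("internal error: no parent of a lowest reticulation admits the shape")
}

#' Canonical cut/isolate subnetwork pairs
#'
#' `canonical_maxsub_pair` returns the two maximum subnetworks obtained by
#' cutting and isolating the reticulated cherry shape of a lowest
#' reticulation; the intersection of the labels of their blob trees is
#' already the full foundation-node set of the network.
#' `canonical_mlls_pair` returns the two MLLSs obtained by cutting
#' (respectively isolating) a lowest reticulated cherry shape in every
#' maximum-level blob, which likewise suffice to reconstruct the blob tree.
#'
#' @param net a validated tree-child `phylo_network` with at least one
#'   reticulation (level at least 1 for the maximum-subnetwork pair; any
#'   level >= 1 for the MLLS pair).
#' @return list of two `phylo_network`s (`cut`, `isolate`).
#' @export
canonical_maxsub_pair <- function(net) {
  s <- lowest_reticulation_shape(net)
  list(cut = delete_reticulation_edge(net, c(s$p_x, s$p_y)),
       isolate = delete_reticulation_edge(net, c(s$g_y, s$p_y)))
}

#' @rdname canonical_maxsub_pair
#' @export
canonical_mlls_pair <- function(net) {
  shapes <- lowest_shapes_of_top_blobs(net)
  cut_e <- do.call(rbind, lapply(shapes, function(s) c(s$p_x, s$p_y)))
  iso_e <- do.call(rbind, lapply(shapes, function(s) c(s$g_y, s$p_y)))
  list(cut = delete_edges_cleanup(net, cut_e),
       isolate = delete_edges_cleanup(net, iso_e))
}

lowest_shapes_of_top_blobs <- function(net) {
  k <- network_level(net)
  if (k < 1L) stop("network has no reticulation")
  blobs <- Filter(function(b) b$level == k, network_blobs(net))
  lapply(blobs, function(b) lowest_shape_of_blob(net, b))
}

#' Canonical three-MLLS certificate
#'
#' Builds the three MLLSs that suffice for reconstruction when the number of
#' maximum-level blobs is known: per maximum-level blob, the first cuts a
#' lowest reticulated cherry shape, the second isolates it, and the third
#' deletes a reticulation edge not incident to that shape's reticulation,
#' chosen so that the reticulation's parents remain non-adjacent.
#'
#' @param net a validated tree-child `phylo_network` of level k >= 2.
#' @return list with elements `mllss` (list of the three networks) and `l`
#'   (the number of maximum-level blobs).
#' @export
mlls_triple <- function(net) {
  k <- network_level(net)
  if (k < 2L) stop("the three-MLLS certificate requires level >= 2")
  blobs <- Filter(function(b) b$level == k, network_blobs(net))
  shapes <- lapply(blobs, function(b) lowest_shape_of_blob(net, b))
  cut_e <- do.call(rbind, lapply(shapes, function(s) c(s$p_x, s$p_y)))
  iso_e <- do.call(rbind, lapply(shapes, function(s) c(s$g_y, s$p_y)))
  third <- vector("list", length(blobs))
  for (i in seq_along(blobs)) {
    s <- shapes[[i]]
    e <- blob_ret_edges(net, blobs[[i]])
    e <- e[e[, 2L] != s$p_y, , drop = FALSE]
    found <- FALSE
    for (j in seq_len(nrow(e))) {
      m <- delete_reticulation_edge(net, e[j, ])
      pr <- net_parents(m, s$p_y)
      adj <- any(m$edges[, 1L] == pr[1L] & m$edges[, 2L] == pr[2L]) ||
        any(m$edges[, 1L] == pr[2L] & m$edges[, 2L] == pr[1L])
      if (!adj) { third[[i]] <- e[j, ]; found <- TRUE; break }
    }
    if (!found) stop("no third deletion keeps the shape parents non-adjacent")
  }
  third_e <- do.call(rbind, third)
  list(mllss = list(delete_edges_cleanup(net, cut_e),
                    delete_edges_cleanup(net, iso_e),
                    delete_edges_cleanup(net, third_e)),
       l = length(blobs))
}

## ---- blob rebuilding -------------------------------------------------------

#' Rebuild a maximum-level blob across the MLLSs
#'
#' For a pair `(x, y)` whose inferred original shape is a reticulated cherry
#' `H(x,y)` in a maximum-level blob with leaf-descendant set `A`: in the
#' MLLS exhibiting a subdivided cherry or a distance >= 4 shape on the pair,
#' subdivide the pendant edges of `x` and `y` with fresh nodes `a`, `c` and
#' add the edge `(a, c)` — this restores the missing reticulation edge and
#' carries the fully reconstructed blob.  In every other MLLS, the component
#' obtained by detaching the tree edge into the pure node with label `A` and
#' the outgoing edges of the pure nodes of `A`'s blob-tree children (the
#' B-part) is replaced by the reconstructed B-part.
#'
#' @param mllss list of `phylo_network`s (the MLLSs, possibly with other
#'   blobs already collapsed).
#' @param x,y leaf labels; the reticulation of the inferred shape is on `y`.
#' @param A character vector: the leaf-descendant set of the blob being
#'   rebuilt (a common blob-tree label of the inputs).
#' @return list of updated networks, pairwise isomorphic on the blob.
#' @export
rebuild_blob <- function(mllss, x, y, A, surveys = NULL) {
  kinds <- vapply(mllss, function(m) classify_pair(m, x, y)$kind, character(1))
  donor <- which(kinds %in% c("lambda_xy", "lambda_yx", "PI"))
  if (!length(donor))
    stop("no MLLS exhibits a subdivided cherry or distance >= 4 on (",
         x, ",", y, "): inconsistent input")
  donor <- donor[1L]
  mstar <- insert_ret_edge_above(mllss[[donor]], x, y)
  ## children of A in the rebuilt network's blob tree: maximal blob labels
  ## properly contained in A (blob labels are the leaf-descendant sets of
  ## the non-leaf pendant heads)
  idx_star <- pendant_index(mstar)
  labsets <- Filter(function(l) length(l) > 1L,
                    lapply(idx_star, function(h) h$labs))
  inside <- Filter(function(l) length(l) < length(A) && all(l %in% A), labsets)
  gamma <- Filter(function(l) {
    !any(vapply(inside, function(o)
      length(o) > length(l) && all(l %in% o), logical(1)))
  }, inside)
  out <- mllss
  out[[donor]] <- mstar
  star <- donor_bpart(mstar, A, gamma, idx_star)
  for (i in seq_along(out)) {
    if (i == donor) next
    out[[i]] <- transplant_bpart(out[[i]], star, A, gamma,
                                 if (!is.null(surveys)) surveys[[i]]$idx)
  }
  out
}

## subdivide the pendant edges of x and y and add the edge (a, c); the new
## node above y becomes the restored reticulation
insert_ret_edge_above <- function(net, x, y) {
  xi <- resolve_leaf(net, x); yi <- resolve_leaf(net, y)
  s1 <- subdivide_edge(net, net_parents(net, xi), xi)
  s2 <- subdivide_edge(s1$net, net_parents(s1$net, yi), yi)
  e <- rbind(s2$net$edges, c(s1$mid, s2$mid))
  phylo_network(e, s2$net$labels, root = net$root)
}

## pure node of the (unique) blob of net with leaf-descendant set A: the
## head of the pendant subnetwork with that leaf set
pure_node_of_label <- function(net, A, idx = NULL) {
  if (is.null(idx)) idx <- pendant_index(net)
  hit <- idx[[label_key(A)]]
  if (is.null(hit))
    stop("no blob with leaf-descendant set {", paste(A, collapse = ","), "}")
  hit$head
}

## B-part node set: reachable from q without expanding the boundary nodes qs
bpart_nodes <- function(net, q, qs) {
  seen <- q
  frontier <- setdiff(q, qs)
  while (length(frontier)) {
    nxt <- unique(net$edges[net$edges[, 1L] %in% frontier, 2L])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- setdiff(nxt, qs)
  }
  seen
}

## the donor's B-part: node set, internal edges, top node and boundary nodes
donor_bpart <- function(mstar, A, gamma, idx_star = NULL) {
  p <- pure_node_of_label(mstar, A, idx_star)
  pi_ <- vapply(gamma, function(C) pure_node_of_label(mstar, C, idx_star),
                integer(1))
  spart <- bpart_nodes(mstar, p, pi_)
  se <- mstar$edges[mstar$edges[, 1L] %in% spart &
                      mstar$edges[, 2L] %in% spart, , drop = FALSE]
  se <- se[!(se[, 1L] %in% pi_), , drop = FALSE]
  labels <- mstar$labels[as.integer(names(mstar$labels)) %in% spart]
  list(nodes = spart, edges = se, top = p, boundary = pi_, labels = labels)
}

transplant_bpart <- function(m, star, A, gamma, idx_m = NULL) {
  if (is.null(idx_m)) idx_m <- pendant_index(m)
  q <- pure_node_of_label(m, A, idx_m)
  u <- net_parents(m, q)
  qi <- vapply(gamma, function(C) pure_node_of_label(m, C, idx_m), integer(1))
  part <- bpart_nodes(m, q, qi)
  ch <- lapply(qi, function(v) net_children(m, v))
  if (any(unlist(ch) %in% part))
    stop("B-part boundary is not clean in an input network")
  ## no edge may enter the B-part other than (u, q)
  enter <- m$edges[!(m$edges[, 1L] %in% part) & m$edges[, 2L] %in% part, ,
                   drop = FALSE]
  if (!(nrow(enter) == 1L && enter[1L] == u && enter[2L] == q))
    stop("B-part of an input network is not pendant below its pure node")
  ## donor B-part
  p <- star$top
  pi_ <- star$boundary
  spart <- star$nodes
  se <- star$edges
  ## graft with fresh ids
  off <- max(net_nodes(m)) + 1L
  map <- stats::setNames(seq_along(spart) + off, spart)
  e <- m$edges[!(m$edges[, 1L] %in% part | m$edges[, 2L] %in% part), ,
               drop = FALSE]
  if (nrow(se))
    e <- rbind(e, matrix(map[as.character(se)], ncol = 2L))
  e <- rbind(e, c(u, map[[as.character(p)]]))
  for (i in seq_along(pi_)) {
    for (c0 in ch[[i]]) e <- rbind(e, c(map[[as.character(pi_[i])]], c0))
  }
  labels <- m$labels[!(as.integer(names(m$labels)) %in% part)]
  slab <- star$labels
  if (length(slab)) {
    names(slab) <- as.character(map[names(slab)])
    labels <- c(labels, slab)
  }
  res <- phylo_network(e, labels, root = m$root)
  if (!identical(taxa(res), taxa(m)))
    stop("B-part transplant changed the taxon set")
  res
}

## ---- the main reconstruction loop ------------------------------------------

## per-network working summary: descendant matrix, pendant index, path
## counts (rows ordered as B)
net_survey <- function(net) {
  B <- below_matrix(net)
  list(net = net, B = B, idx = pendant_index(net, B), mu = mu_matrix(net))
}

## canonical string of the pendant subnetwork headed at idx entry `h`,
## derived from the full network's path counts: the pendant's nodes are the
## descendants of the head, its taxa the head's leaf set, and the fresh
## pendant root duplicates the head's counts
survey_pendant_canon <- function(sv, h) {
  mu <- sv$mu[h$desc_pos, h$labs, drop = FALSE]
  paste(c(h$labs,
          sort(c(mu_row_strings(mu),
                 paste(sv$mu[as.character(h$head), h$labs], collapse = ",")))),
        collapse = ";")
}

## collapse all maximal common pendant subnetworks (isomorphic in every
## network, more than one leaf, not the full taxon set); one survey pass per
## round, repeated until a fixpoint.  Returns list(nets, steps, surveys).
collapse_common_pendants <- function(nets) {
  steps <- list()
  repeat {
    ## drop duplicated (isomorphic) networks before the expensive pass
    mus <- lapply(nets, function(n) mu_matrix(n))
    canon <- vapply(seq_along(nets), function(i)
      mu_canonical(nets[[i]], mus[[i]]), character(1))
    keep <- !duplicated(canon)
    nets <- nets[keep]; mus <- mus[keep]
    sv <- lapply(seq_along(nets), function(i) {
      B <- below_matrix(nets[[i]])
      list(net = nets[[i]], B = B, idx = pendant_index(nets[[i]], B),
           mu = mus[[i]])
    })
    common <- Reduce(intersect, lapply(sv, function(s) names(s$idx)))
    full <- label_key(taxa(nets[[1L]]))
    sizes <- vapply(common, function(k)
      length(strsplit(k, "\r", fixed = TRUE)[[1L]]), integer(1))
    keep <- sizes > 1L & common != full
    common <- common[keep]; sizes <- sizes[keep]
    collapsed_any <- FALSE
    done_regions <- list()     # label sets already collapsed this round
    for (key in common[order(-sizes)]) {
      A <- sv[[1L]]$idx[[key]]$labs
      if (any(vapply(done_regions, function(R) any(A %in% R), logical(1))))
        next                                   # inside a collapsed region
      c1 <- survey_pendant_canon(sv[[1L]], sv[[1L]]$idx[[key]])
      same <- TRUE
      for (s in sv[-1L]) {
        if (survey_pendant_canon(s, s$idx[[key]]) != c1) {
          same <- FALSE; break
        }
      }
      if (same) {
        pendant <- extract_pendant(nets[[1L]], sv[[1L]]$idx[[key]]$head)
        nets <- lapply(seq_along(nets), function(i)
          collapse_at(nets[[i]], sv[[i]]$idx[[key]]$head, A)$net)
        steps[[length(steps) + 1L]] <-
          list(label = synthetic_label(A), pendant = pendant)
        done_regions[[length(done_regions) + 1L]] <- A
        collapsed_any <- TRUE
      }
    }
    if (!collapsed_any)
      return(list(nets = nets, steps = steps, surveys = sv))
  }
}

## leaf pairs below A worth classifying: those at up-down distance <= 3 in at
## least one of the first few networks, then all remaining pairs
candidate_pairs <- function(nets, A) {
  A <- sort(A)
  if (length(A) < 2L) return(list())
  pairs <- utils::combn(A, 2L, simplify = FALSE)
  near <- logical(length(pairs))
  for (m in nets[seq_len(min(3L, length(nets)))]) {
    for (j in seq_along(pairs)) {
      if (near[j]) next
      px <- net_parents(m, resolve_leaf(m, pairs[[j]][1L]))
      py <- net_parents(m, resolve_leaf(m, pairs[[j]][2L]))
      if (px == py ||
          any(m$edges[, 1L] == px & m$edges[, 2L] == py) ||
          any(m$edges[, 1L] == py & m$edges[, 2L] == px)) near[j] <- TRUE
    }
  }
  c(pairs[near], pairs[!near])
}

reconstruct_engine <- function(mllss, max_iter = 10000L) {
  stopifnot(length(mllss) >= 1L)
  tx <- taxa(mllss[[1L]])
  for (m in mllss) if (!identical(taxa(m), tx))
    stop("all input networks must share one taxon set")
  nets <- mllss
  stack <- list()
  trace <- character()
  rebuilds <- 0L
  for (it in seq_len(max_iter)) {
    progressed <- FALSE
    ## (1) collapse all maximal common pendant subnetworks
    col <- collapse_common_pendants(nets)
    nets <- col$nets
    for (s in col$steps) {
      stack[[length(stack) + 1L]] <- s
      trace <- c(trace, paste0("collapse ", s$label))
      progressed <- TRUE
    }
    ## (2) termination: all working networks pairwise isomorphic
    canon <- vapply(col$surveys, function(s) mu_canonical(s$net, s$mu),
                    character(1))
    if (all(canon == canon[1L])) {
      net <- nets[[1L]]
      for (s in rev(stack)) net <- expand_pendant(net, s$label, s$pendant)
      trace <- c(trace, "terminate: all networks isomorphic")
      return(list(net = net, trace = trace, rebuilds = rebuilds))
    }
    ## drop duplicated (isomorphic) working networks: the MLLS collection
    ## is a set, and every step commutes with deduplication
    keep <- !duplicated(canon)
    nets <- nets[keep]
    col$surveys <- col$surveys[keep]
    ## (3) lowest common blob-tree label.  Blob-tree labels are exactly the
    ## leaf-descendant sets of the non-leaf pendant heads, so the pendant
    ## indexes of the final collapse round already carry them.
    keysets <- lapply(col$surveys, function(s) {
      labs <- lapply(s$idx, function(h) h$labs)
      names(s$idx)[vapply(labs, length, integer(1)) > 1L]
    })
    common <- Reduce(intersect, keysets)
    F <- lapply(common, function(k) strsplit(k, "\r", fixed = TRUE)[[1L]])
    minimal <- Filter(function(A) {
      !any(vapply(F, function(B)
        length(B) < length(A) && all(B %in% A), logical(1)))
    }, F)
    minimal <- minimal[order(vapply(minimal, label_key, character(1)))]
    ## (4) find a pair inferring an H shape in a maximum-level blob; rebuild
    done <- FALSE
    for (A in minimal) {
      for (pr in candidate_pairs(nets, A)) {
        shp <- tryCatch(
          infer_original_shape(shapes_across(nets, pr[1L], pr[2L])),
          error = function(e) NULL)
        if (is.null(shp) || is.na(shp$levelk) || !shp$levelk) next
        if (shp$shape$kind == "H_xy") { x <- pr[1L]; y <- pr[2L] }
        else { x <- pr[2L]; y <- pr[1L] }
        nets <- rebuild_blob(nets, x, y, A, col$surveys)
        rebuilds <- rebuilds + 1L
        trace <- c(trace, paste0("rebuild blob {", paste(A, collapse = ","),
                                 "} via pair (", x, ",", y, ")"))
        progressed <- TRUE
        done <- TRUE
        break
      }
      if (done) break
    }
    if (!progressed)
      stop("no consistent network: reconstruction stalled")
  }
  stop("reconstruction did not terminate")
}

#' Reconstruct a tree-child network from its MLLS set
#'
#' Implements the reconstruction loop for level-k tree-child networks
#' (k >= 2): repeatedly collapse all maximal common pendant subnetworks,
#' locate a lowest common blob-tree label, find a leaf pair below it whose
#' inferred shape is a reticulated cherry in a maximum-level blob, rebuild
#' that blob in every working network, and stop when all working networks
#' are pairwise isomorphic; finally re-expand the collapsed pendants.  The
#' output is isomorphic to the unique source network.  Duplicated (pairwise
#' isomorphic) inputs are tolerated.
#'
#' @param mllss list of `phylo_network`s: the complete MLLS set of some
#'   level-k (k >= 2) tree-child network (duplicates allowed).
#' @param verify when `TRUE`, recompute the MLLS set of the result and check
#'   it equals the input as a set up to isomorphism; an error is raised on
#'   mismatch.
#' @return a `phylo_network`, with attributes `trace` (the action log) and
#'   `rebuilds` (number of blobs rebuilt).
#' @export
tcmlls_reconstruct <- function(mllss, verify = FALSE) {
  res <- reconstruct_engine(mllss)
  if (verify && !iso_setequal(mlls_set(res$net), mllss))
    stop("no consistent network: the result's MLLS set does not match the ",
         "input")
  structure(res$net, trace = res$trace, rebuilds = res$rebuilds)
}

#' Reconstruct from three MLLSs and the number of maximum-level blobs
#'
#' Runs the reconstruction loop on a three-element MLLS certificate (see
#' [mlls_triple()]); with a certificate of the required form the loop
#' terminates after exactly `l` blob rebuilds.  An error is raised if the
#' loop stalls; if it terminates after fewer than `l` rebuilds (an
#' over-stated `l`), this is reported in the trace attribute.
#'
#' @param triple list of three `phylo_network`s.
#' @param l the number of maximum-level blobs of the source network.
#' @return a `phylo_network` with attributes `trace` and `rebuilds`.
#' @export
reconstruct_from_three <- function(triple, l) {
  stopifnot(length(triple) == 3L)
  res <- reconstruct_engine(triple)
  trace <- res$trace
  if (res$rebuilds < l)
    trace <- c(trace, paste0("terminated after ", res$rebuilds,
                             " rebuilds; l = ", l, " was over-stated"))
  structure(res$net, trace = trace, rebuilds = res$rebuilds)
}
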