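## ---- random tree-child network generator -----------------------------------

## The generator grows a network by inverse cherry / reticulated-cherry
## reductions, which keeps the tree-child property by construction:
##   - a cherry expansion subdivides the pendant edge of a leaf and hangs a
##     fresh leaf off the new tree node (adds one leaf, no reticulation);
##   - a reticulated-cherry expansion subdivides the pendant edge of a leaf
##     attached to a designated blob and a tree edge inside that blob, and
##     joins the two new nodes through a fresh reticulation with a fresh
##     leaf child (adds one leaf and raises that blob's level by one).
## Steering every reticulated expansion at one designated blob therefore
## builds a blob of any prescribed level, and blobs built at different
## attachment leaves never merge.

next_node <- function(net) max(net_nodes(net)) + 1L

## sample one element of a vector (safe for length-1 vectors)
pick1 <- function(x) x[sample.int(length(x), 1L)]

## subdivide directed edge (u, v) with a fresh node; returns list(net, mid)
subdivide_edge <- function(net, u, v) {
  mid <- next_node(net)
  e <- net$edges
  hit <- which(e[, 1L] == u & e[, 2L] == v)
  stopifnot(length(hit) == 1L)
  e <- e[-hit, , drop = FALSE]
  e <- rbind(e, c(u, mid), c(mid, v))
  list(net = phylo_network(e, net$labels, root = net$root, check = FALSE),
       mid = mid)
}

## cherry expansion at leaf id `at`; new leaf labelled `lab`
expand_cherry <- function(net, at, lab) {
  p <- net_parents(net, at)
  s <- subdivide_edge(net, p, at)
  leaf <- next_node(s$net)
  e <- rbind(s$net$edges, c(s$mid, leaf))
  labels <- s$net$labels
  labels[as.character(leaf)] <- lab
  phylo_network(e, labels, root = net$root, check = FALSE)
}

## reticulated-cherry expansion: subdivide the pendant edge of leaf `at`
## (s above the leaf) and the tree edge (u, v) (g in between), then add a
## reticulation with parents s, g and a fresh leaf child labelled `lab`
expand_ret_cherry <- function(net, at, u, v, lab) {
  p <- net_parents(net, at)
  s1 <- subdivide_edge(net, p, at)
  ## the chosen tree edge may be the pendant edge of `at` itself: subdivide
  ## its upper half, which makes the two new parents adjacent (an A shape)
  if (u == p && v == at) v <- s1$mid
  s2 <- subdivide_edge(s1$net, u, v)
  ret <- next_node(s2$net)
  leaf <- ret + 1L
  e <- rbind(s2$net$edges, c(s1$mid, ret), c(s2$mid, ret), c(ret, leaf))
  labels <- s2$net$labels
  labels[as.character(leaf)] <- lab
  phylo_network(e, labels, root = net$root, check = FALSE)
}

#' Generate a random tree-child network with prescribed blob structure
#'
#' Builds a seed-deterministic rooted binary tree-child network with
#' `n_leaves` taxa (labelled `t1, t2, ...`), of level exactly `level`, with
#' exactly `n_top_blobs` blobs of that level and `extra_blobs` further blobs
#' of levels drawn from `1 .. level-1` (when `level >= 2`).  The network is
#' grown by inverse cherry / reticulated-cherry reductions, so the
#' tree-child property and the blob census hold by construction; every
#' output passes [validate_network()] and [is_tree_child()].
#'
#' @param n_leaves number of taxa (at least 2); must satisfy
#'   `n_leaves >= 1 + n_top_blobs * (level + 1) + extra_blobs * 2`.
#' @param level target network level (0 for a random tree).
#' @param n_top_blobs number of maximum-level blobs (>= 1 when `level > 0`).
#' @param extra_blobs number of additional lower-level blobs (each of a
#'   random level in `1 .. level-1`; requires `level >= 2` when positive).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return a validated tree-child `phylo_network`.
#' @export
generate_tcnet <- function(n_leaves, level = 2L, n_top_blobs = 1L,
                           extra_blobs = 0L, seed = 1L) {
  n_leaves <- as.integer(n_leaves); level <- as.integer(level)
  n_top_blobs <- as.integer(n_top_blobs); extra_blobs <- as.integer(extra_blobs)
  if (level == 0L && (n_top_blobs != 0L || extra_blobs != 0L))
    n_top_blobs <- 0L
  if (level > 0L && n_top_blobs < 1L)
    stop("a level-", level, " network needs at least one top blob")
  if (extra_blobs > 0L && level < 2L)
    stop("extra lower-level blobs require level >= 2")
  budget <- n_leaves - 1L
  need <- n_top_blobs * (level + 1L) + extra_blobs * 2L
  if (budget < need || n_leaves < 2L)
    stop("infeasible: ", n_leaves, " leaves cannot host the requested blobs")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)

  lab_i <- 0L
  new_lab <- function() { lab_i <<- lab_i + 1L; paste0("t", lab_i) }
  net <- phylo_network(matrix(c(1L, 2L), ncol = 2L),
                       stats::setNames(new_lab(), "2"), root = 1L,
                       check = FALSE)
  ## extra blobs default to level 1 (2 leaves each); raise their levels
  ## only while the leaf budget allows it
  avail <- budget - need
  extra_lv <- rep(1L, extra_blobs)
  for (i in seq_len(extra_blobs)) {
    bump <- min(level - 2L, avail)
    if (bump > 0L) {
      bump <- sample.int(bump + 1L, 1L) - 1L
      extra_lv[i] <- extra_lv[i] + bump
      avail <- avail - bump
    }
  }
  spare <- avail                  # free cherry expansions
  ## sprinkle some free leaves first so blob attachment points vary
  pre <- if (spare > 0L) sample.int(spare + 1L, 1L) - 1L else 0L
  for (i in seq_len(pre)) {
    at <- pick1(unname(leaves(net)))
    net <- expand_cherry(net, at, new_lab())
  }
  spare <- spare - pre
  blob_levels <- c(rep(level, n_top_blobs), extra_lv)
  for (bl in blob_levels) {
    net <- grow_blob(net, bl, new_lab)
  }
  for (i in seq_len(spare)) {
    at <- pick1(unname(leaves(net)))
    net <- expand_cherry(net, at, new_lab())
  }
  bad <- validate_network(net)
  if (length(bad)) stop("generator produced an invalid network: ",
                        paste(bad, collapse = "; "))
  net
}

## grow a blob of level `bl` at a random attachment leaf
grow_blob <- function(net, bl, new_lab) {
  at <- pick1(unname(leaves(net)))
  ## seed cherry: its parent is the nucleus of the new blob
  net <- expand_cherry(net, at, new_lab())
  members <- net_parents(net, at)       # the new tree node
  for (r in seq_len(bl)) {
    din <- net_indeg(net)
    ## leaves pendant from the current blob
    pl <- as.integer(names(net$labels))
    pl <- pl[vapply(pl, function(l) net_parents(net, l) %in% members,
                    logical(1))]
    lf <- pick1(pl)
    pend <- c(net_parents(net, lf), lf)
    if (bl == 1L && sample.int(2L, 1L) == 1L) {
      ## A-variant: subdivide the pendant edge of `lf` twice, making the
      ## two fresh parents adjacent -- a self-contained triangle blob
      ## (exactly the A shape).  Only admissible for level-1 blobs, since
      ## the triangle never merges with an existing blob.
      u <- pend[1L]; v <- pend[2L]
    } else {
      ## tree edges with tail in the blob and head a non-reticulation in
      ## the blob or a pendant leaf (never the chosen pendant edge: its
      ## subdivision would detach a separate triangle blob)
      e <- net$edges
      cand <- which(e[, 1L] %in% members &
                      din[as.character(e[, 2L])] <= 1L &
                      (e[, 2L] %in% members | e[, 2L] %in% pl) &
                      !(e[, 1L] == pend[1L] & e[, 2L] == pend[2L]))
      j <- pick1(cand)
      u <- e[j, 1L]; v <- e[j, 2L]
    }
    pre_ids <- net_nodes(net)
    net <- expand_ret_cherry(net, lf, u, v, new_lab())
    added <- setdiff(net_nodes(net), pre_ids)
    ## the two subdividers and the reticulation join the blob; the leaf does
    new_leaf <- as.integer(names(net$labels)[length(net$labels)])
    members <- c(members, setdiff(added, new_leaf))
  }
  net
}

#' Generator/oracle helpers for property tests
#'
#' `random_spec_grid` enumerates a small grid of feasible generator settings
#' used by the test-suite and the acceptance experiments.
#'
#' @param seed base seed; each row of the grid derives its own sub-seed.
#' @param n number of specs to return.
#' @param levels candidate network levels.
#' @param max_leaves cap on the number of taxa.
#' @return data.frame with columns `n_leaves`, `level`, `n_top_blobs`,
#'   `extra_blobs`, `seed`.
#' @export
random_spec_grid <- function(n, seed = 1L, levels = c(2L, 3L, 4L),
                             max_leaves = 30L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      k <- pick1(levels)
      b <- sample.int(3L, 1L, prob = c(0.5, 0.35, 0.15))
      x <- sample.int(2L, 1L) - 1L             # 0 or 1 extra blob
      need <- 1L + b * (k + 1L) + x * 2L
      if (need <= max_leaves) break
    }
    nl <- pick1(seq(max(need, min(6L, max_leaves)), max_leaves))
    rows[[i]] <- data.frame(n_leaves = nl, level = k, n_top_blobs = b,
                            extra_blobs = x,
                            seed = (seed %% 190000L) * 10000L + i)
  }
  do.call(rbind, rows)
}
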