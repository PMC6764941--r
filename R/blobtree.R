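## ---- blob trees ------------------------------------------------------------

new_blob_tree <- function(labels, parent) {
  structure(list(labels = labels, parent = as.integer(parent)),
            class = "blob_tree")
}

#' Blob tree of a network
#'
#' Contract every blob of the network into a single node labelled by the
#' leaf-descendant set of its pure node, keep the (unlabelled) root, and
#' delete the leaf nodes.  For a tree-child network the labels are pairwise
#' distinct, so blob nodes are identified with their labels.
#'
#' @param net a validated tree-child `phylo_network`.
#' @return an object of class `blob_tree`: node 1 is the unlabelled root;
#'   `labels` is a list of sorted taxon-label vectors (`NULL` for the root)
#'   and `parent` the parent index of each node (0 for the root).
#' @export
blob_tree <- function(net) {
  blobs <- network_blobs(net)
  if (!length(blobs)) return(new_blob_tree(list(NULL), 0L))
  node_blob <- integer()              # network node id -> blob index
  for (i in seq_along(blobs))
    node_blob[as.character(blobs[[i]]$members)] <- i
  labels <- c(list(NULL), lapply(blobs, function(b) b$desc))
  parent <- integer(length(blobs) + 1L)
  for (i in seq_along(blobs)) {
    q <- net_parents(net, blobs[[i]]$pure)
    parent[i + 1L] <- if (q == net$root) 1L else node_blob[as.character(q)] + 1L
  }
  new_blob_tree(labels, parent)
}

bt_keys <- function(bt) {
  vapply(bt$labels[-1L], label_key, character(1))
}

## children keys of the node with label key `key` (use key = NA for the root)
bt_children_keys <- function(bt, key) {
  keys <- c(NA_character_, bt_keys(bt))
  at <- if (is.na(key)) 1L else match(key, keys)
  if (is.na(at)) stop("no blob node with the requested label")
  sort(keys[which(bt$parent == at)])
}

#' Foundation nodes from a collection of blob trees
#'
#' The foundation nodes of a network are the labels of its blob tree; they
#' are recoverable as the labels common to the blob trees of all its maximum
#' subnetworks (or of all its MLLSs).
#'
#' @param blob_trees list of `blob_tree`s.
#' @return list of sorted taxon-label vectors (the intersection of the label
#'   sets), in canonical order.
#' @export
foundation_nodes <- function(blob_trees) {
  stopifnot(length(blob_trees) >= 1L)
  keysets <- lapply(blob_trees, bt_keys)
  common <- Reduce(intersect, keysets)
  labs <- lapply(sort(common), function(k) strsplit(k, "\r", fixed = TRUE)[[1L]])
  labs[order(vapply(labs, length, integer(1)),
             vapply(labs, label_key, character(1)))]
}

#' Assemble a blob tree from a family of label sets
#'
#' Builds the Hasse diagram of the family under strict inclusion (an edge
#' from `A` down to `B` precisely when `B` is a proper subset of `A` with no
#' intermediate set in the family), rooted at an unlabelled root above the
#' maximal sets.  An error is raised when the family is not laminar (two
#' sets overlap without containment), which signals inconsistent inputs.
#'
#' @param F list of character vectors (taxon label sets), e.g. from
#'   [foundation_nodes()].
#' @return a `blob_tree`.
#' @export
assemble_blob_tree <- function(F) {
  F <- unique(lapply(F, sort))
  if (!length(F)) return(new_blob_tree(list(NULL), 0L))
  sizes <- vapply(F, length, integer(1))
  F <- F[order(-sizes, vapply(F, label_key, character(1)))]
  sizes <- vapply(F, length, integer(1))
  n <- length(F)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    common <- length(intersect(F[[i]], F[[j]]))
    if (common > 0L && common != min(sizes[i], sizes[j]))
      stop("label family is not laminar: {",
           paste(F[[i]], collapse = ","), "} overlaps {",
           paste(F[[j]], collapse = ","), "}")
  }
  parent <- integer(n + 1L)
  for (i in seq_len(n)) {
    sup <- which(sizes > sizes[i] &
                   vapply(seq_len(n), function(j)
                     all(F[[i]] %in% F[[j]]), logical(1)))
    if (!length(sup)) { parent[i + 1L] <- 1L; next }
    parent[i + 1L] <- sup[which.min(sizes[sup])] + 1L
  }
  new_blob_tree(c(list(NULL), F), parent)
}

#' Identify the level-k blobs from MLLS blob trees
#'
#' A blob of the original network has level strictly below k exactly when
#' the child set of its blob node is identical, in every MLLS blob tree, to
#' its child set in the original blob tree.  The labels whose child sets
#' differ in at least one input are therefore the level-k blobs.
#'
#' @param blob_trees_of_mllss list of `blob_tree`s of all MLLSs.
#' @param bt_of_net the blob tree of the original network (e.g. assembled
#'   via [foundation_nodes()] and [assemble_blob_tree()] from the same
#'   inputs).
#' @return list of taxon-label vectors: the labels of the level-k blobs.
#' @export
identify_level_k_blobs <- function(blob_trees_of_mllss, bt_of_net) {
  out <- list()
  for (i in seq_along(bt_of_net$labels)[-1L]) {
    A <- bt_of_net$labels[[i]]
    key <- label_key(A)
    ch0 <- bt_children_keys(bt_of_net, key)
    flagged <- FALSE
    for (bt in blob_trees_of_mllss) {
      if (!setequal(bt_children_keys(bt, key), ch0)) { flagged <- TRUE; break }
    }
    if (flagged) out[[length(out) + 1L]] <- A
  }
  out
}

#' @export
print.blob_tree <- function(x, ...) {
  cat("blob tree with", length(x$labels) - 1L, "blob nodes\n")
  rec <- function(i, depth) {
    lab <- if (is.null(x$labels[[i]])) "(root)" else
      paste0("{", paste(x$labels[[i]], collapse = ","), "}")
    cat(strrep("  ", depth), lab, "\n", sep = "")
    for (j in which(x$parent == i)) rec(j, depth + 1L)
  }
  rec(1L, 0L)
  invisible(x)
}

## equality of blob trees (same label family and parent relation)
bt_equal <- function(a, b) {
  ka <- bt_keys(a); kb <- bt_keys(b)
  if (!setequal(ka, kb)) return(FALSE)
  pk <- function(bt, keys) {
    allk <- c(NA_character_, bt_keys(bt))
    vapply(keys, function(k) allk[bt$parent[match(k, allk)]], character(1))
  }
  keys <- sort(ka)
  identical(pk(a, keys), pk(b, keys))
}
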