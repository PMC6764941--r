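## ---- leaf-pair shape calculus ----------------------------------------------

## shape kinds; the ordered pair (x, y) in lambda/A/H/K means the middle
## tree node (lambda) or the reticulation (A/H/K) is on y
SHAPE_KINDS <- c("LAMBDA_CHERRY", "lambda_xy", "lambda_yx",
                 "A_xy", "A_yx", "H_xy", "H_yx", "PI")

new_shape <- function(kind, x, y) {
  structure(list(kind = kind, pair = c(x, y)), class = "leaf_pair_shape")
}

#' @export
print.leaf_pair_shape <- function(x, ...) {
  cat("shape", x$kind, "on pair (", x$pair[1L], ",", x$pair[2L], ")\n")
  invisible(x)
}

## swap the orientation of a shape kind (x <-> y)
swap_kind <- function(kind) {
  switch(kind,
         lambda_xy = "lambda_yx", lambda_yx = "lambda_xy",
         A_xy = "A_yx", A_yx = "A_xy",
         H_xy = "H_yx", H_yx = "H_xy",
         kind)
}

#' Classify the shape on a leaf pair
#'
#' In a tree-child network exactly one of eight shapes holds on any leaf
#' pair `{x, y}`, determined by the shortest up-down distance d between the
#' leaves: d = 2 is a cherry; d = 3 with no reticulation among the two leaf
#' parents is a subdivided cherry (`lambda_xy` when the middle tree node is
#' the parent of `y`); d = 3 with the parent of one leaf a reticulation is a
#' reticulated cherry, split into `A_xy` (the two leaf parents share a
#' common parent) and `H_xy` (they do not), with the reticulation on `y`;
#' and d >= 4 is `PI`.
#'
#' @param net a validated tree-child `phylo_network`.
#' @param x,y distinct leaves (labels or ids).
#' @return a `leaf_pair_shape` with elements `kind` (one of
#'   `"LAMBDA_CHERRY"`, `"lambda_xy"`, `"lambda_yx"`, `"A_xy"`, `"A_yx"`,
#'   `"H_xy"`, `"H_yx"`, `"PI"`) and `pair` (the ordered query pair).
#' @export
classify_pair <- function(net, x, y) {
  xi <- resolve_leaf(net, x); yi <- resolve_leaf(net, y)
  if (xi == yi) stop("the two leaves must be distinct")
  px <- net_parents(net, xi); py <- net_parents(net, yi)
  ## the leaf parents lie on every up-down path between two leaves, so
  ## d = 2 iff they coincide and d = 3 iff they are adjacent
  if (px == py) return(new_shape("LAMBDA_CHERRY", x, y))
  if (any(net$edges[, 1L] == px & net$edges[, 2L] == py)) {
    lower <- py; ornt <- "xy"
  } else if (any(net$edges[, 1L] == py & net$edges[, 2L] == px)) {
    lower <- px; ornt <- "yx"
  } else return(new_shape("PI", x, y))
  if (!is_reticulation(net, lower))
    return(new_shape(paste0("lambda_", ornt), x, y))
  ## reticulated cherry; reticulation on the leaf below `lower`
  upper <- if (ornt == "xy") px else py
  g <- setdiff(net_parents(net, lower), upper)
  i <- net_parents(net, upper)
  kind <- if (length(g) == 1L && length(i) == 1L && g == i) "A_" else "H_"
  new_shape(paste0(kind, ornt), x, y)
}

## is the kind one of the reticulated-cherry kinds K(x,y) (retic on y)?
is_K_xy <- function(kind) kind %in% c("A_xy", "H_xy")
is_K_yx <- function(kind) kind %in% c("A_yx", "H_yx")

#' Infer the original shape from the MLLS shapes of a pair
#'
#' Given the shape on a fixed pair `(x, y)` in every MLLS of a level-k
#' tree-child network (k >= 2), returns the unique shape the original
#' network must contain on that pair, by case analysis on the observed
#' shape set:
#' all cherries imply a cherry; a subdivided cherry with neither the
#' opposite subdivision nor any reticulated cherry nor a distance >= 4 pair
#' observed implies the same subdivided cherry; all `A` implies `A`;
#' cherries and `H_xy` observed together, with no `K(y,x)`, imply `H_xy`
#' with the containing blob of level exactly k; all `H_xy` implies `H_xy`
#' in a blob of level below k; a distance >= 4 pair with no cherry implies
#' distance >= 4 in the original.
#'
#' @param mlls_shapes list of `leaf_pair_shape`s (one per MLLS, same ordered
#'   query pair).  Keyed by MLLS identity: distinct list elements represent
#'   distinct MLLSs.
#' @return a list with elements `shape` (a `leaf_pair_shape` on the original
#'   network) and `levelk` (`TRUE`/`FALSE` for the `H` sub-cases, `NA`
#'   otherwise).  An error ("inconsistent") is raised when no case matches,
#'   which signals that the input is not a genuine MLLS set.
#' @export
infer_original_shape <- function(mlls_shapes) {
  kinds <- vapply(mlls_shapes, function(s) s$kind, character(1))
  pair <- mlls_shapes[[1L]]$pair
  has <- function(k) any(kinds == k)
  matches <- list()
  add <- function(kind, levelk) matches[[length(matches) + 1L]] <<-
    list(shape = new_shape(kind, pair[1L], pair[2L]), levelk = levelk)
  ## cherry: all MLLSs show the cherry
  if (all(kinds == "LAMBDA_CHERRY")) add("LAMBDA_CHERRY", NA)
  ## subdivided cherry, either orientation
  if (has("lambda_xy") && !has("lambda_yx") && !any(is_K_xy(kinds)) &&
      !any(is_K_yx(kinds)) && !has("PI")) add("lambda_xy", NA)
  if (has("lambda_yx") && !has("lambda_xy") && !any(is_K_xy(kinds)) &&
      !any(is_K_yx(kinds)) && !has("PI")) add("lambda_yx", NA)
  ## A: level-1 blob, intact in every MLLS
  if (all(kinds == "A_xy")) add("A_xy", NA)
  if (all(kinds == "A_yx")) add("A_yx", NA)
  ## H with the blob of level k: cherry and H coexist, no opposite K
  if (has("LAMBDA_CHERRY") && has("H_xy") && !any(is_K_yx(kinds)))
    add("H_xy", TRUE)
  if (has("LAMBDA_CHERRY") && has("H_yx") && !any(is_K_xy(kinds)))
    add("H_yx", TRUE)
  ## H with the blob of level < k: intact everywhere
  if (all(kinds == "H_xy")) add("H_xy", FALSE)
  if (all(kinds == "H_yx")) add("H_yx", FALSE)
  ## PI
  if (has("PI") && !has("LAMBDA_CHERRY")) add("PI", NA)
  if (length(matches) != 1L)
    stop("inconsistent MLLS shape set on pair (", pair[1L], ",", pair[2L],
         "): ", length(matches), " cases match")
  matches[[1L]]
}

## shapes of one ordered pair across a list of networks
shapes_across <- function(nets, x, y) {
  lapply(nets, classify_pair, x = x, y = y)
}
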