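## ---- extended Newick I/O ---------------------------------------------------

needs_quote <- function(s) grepl("[](),:;#'[{}[:space:]]", s)

quote_label <- function(s) {
  if (needs_quote(s)) paste0("'", gsub("'", "''", s), "'") else s
}

#' Serialize a network to extended Newick
#'
#' Reticulations are written with `#H<k>` tags, each appearing exactly twice:
#' once with its subtree (below the parent first reached in a preorder
#' traversal) and once as a bare tag.  The root's single child edge is
#' retained, so the serialization always has an extra pair of outer
#' parentheses.  Labels containing Newick metacharacters (such as the
#' synthetic `"{v,w}"` labels of collapsed pendants) are single-quoted.
#'
#' @param net a `phylo_network`, or a list of them.
#' @param file optional path; when given, one network is written per line.
#' @return character vector of Newick strings (invisibly, when `file` is
#'   given).
#' @export
write_enewick <- function(net, file = NULL) {
  nets <- if (inherits(net, "phylo_network")) list(net) else net
  out <- vapply(nets, write_enewick_one, character(1))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

write_enewick_one <- function(net) {
  din <- net_indeg(net)
  hyb <- new.env(parent = emptyenv())
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  rec <- function(v) {
    key <- as.character(v)
    if (!is.na(net$labels[key]) && key %in% names(net$labels))
      return(quote_label(unname(net$labels[key])))
    if (din[key] == 2L) {
      if (!is.null(hyb[[key]]))
        return(paste0("#H", hyb[[key]]))
      counter$n <- counter$n + 1L
      hyb[[key]] <- counter$n
      ch <- net_children(net, v)
      return(paste0("(", rec(ch), ")#H", hyb[[key]]))
    }
    ch <- net_children(net, v)
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")")
  }
  paste0("(", rec(net_children(net, net$root)), ");")
}

#' Read extended Newick networks
#'
#' Parses one network per line.  Reticulations must use the `#H<k>`
#' convention (the tag appears once with a subtree and once bare); internal
#' node names are ignored, branch lengths are parsed and discarded.  A
#' serialization whose top-level node has two children (plain Newick) is
#' accepted and a root is added above it; one whose top-level node has a
#' single child is taken to include the root edge.
#'
#' @param text character vector of Newick strings, or `NULL`.
#' @param file path to a file with one network per line (used when `text` is
#'   `NULL`).
#' @param check validate each parsed network (default `TRUE`).
#' @return a list of `phylo_network`s (a single network if only one line).
#' @export
read_enewick <- function(text = NULL, file = NULL, check = TRUE) {
  if (is.null(text)) text <- readLines(file)
  text <- trimws(text)
  text <- text[nzchar(text)]
  out <- lapply(text, parse_enewick_one, check = check)
  if (length(out) == 1L) out[[1L]] else out
}

parse_enewick_one <- function(str, check = TRUE) {
  env <- new.env(parent = emptyenv())
  env$pos <- 1L
  env$chars <- strsplit(str, "")[[1L]]
  env$next_id <- 0L
  env$edges <- matrix(integer(), ncol = 2L)
  env$labels <- character()
  env$hyb <- list()   # tag -> node id

  peek <- function() if (env$pos <= length(env$chars)) env$chars[env$pos] else ""
  advance <- function() env$pos <- env$pos + 1L
  new_id <- function() { env$next_id <- env$next_id + 1L; env$next_id }
  add_edge <- function(u, v) env$edges <- rbind(env$edges, c(u, v))

  read_label <- function() {
    if (peek() == "'") {
      advance()
      out <- character()
      repeat {
        ch <- peek()
        if (ch == "") stop("unterminated quoted label")
        advance()
        if (ch == "'") {
          if (peek() == "'") { out <- c(out, "'"); advance() } else break
        } else out <- c(out, ch)
      }
      return(paste(out, collapse = ""))
    }
    out <- character()
    while (!(peek() %in% c("", "(", ")", ",", ":", ";"))) {
      out <- c(out, peek()); advance()
    }
    paste(out, collapse = "")
  }

  skip_branch_length <- function() {
    if (peek() == ":") {
      advance()
      while (grepl("[-0-9.eE+]", peek())) advance()
    }
  }

  ## returns the node id of the parsed clade
  clade <- function() {
    kids <- integer()
    if (peek() == "(") {
      advance()
      repeat {
        kids <- c(kids, clade())
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("malformed Newick near position ", env$pos)
      }
    }
    lab <- read_label()
    skip_branch_length()
    m <- regmatches(lab, regexec("^(.*)#H([0-9]+)$", lab))[[1L]]
    if (length(m)) {                        # hybrid tag
      tag <- m[3L]; name <- m[2L]
      v <- env$hyb[[tag]]
      if (is.null(v)) { v <- new_id(); env$hyb[[tag]] <- v }
      for (k in kids) add_edge(v, k)
      if (nzchar(name) && !length(kids)) {  # "x#H1": leaf below the hybrid
        l <- new_id(); add_edge(v, l); env$labels[as.character(l)] <- name
      }
      return(v)
    }
    v <- new_id()
    for (k in kids) add_edge(v, k)
    if (!length(kids)) {
      if (!nzchar(lab)) stop("leaf without a label near position ", env$pos)
      env$labels[as.character(v)] <- lab
    }
    v
  }

  top <- clade()
  if (peek() == ";") advance()
  nkids <- sum(env$edges[, 1L] == top)
  if (nkids == 1L) {
    root <- top
  } else {
    root <- new_id()
    add_edge(root, top)
  }
  phylo_network(env$edges, env$labels, root = root, check = check)
}

## ---- plain edge-list format (debugging) ------------------------------------

#' Read/write the tab-separated edge-list debug format
#'
#' Edge lines are `parent<TAB>child` (integer ids); leaf label lines are
#' `node<TAB>label` where `label` is non-numeric.  The root is inferred.
#'
#' @param net a `phylo_network`.
#' @param file a path.
#' @return `read_edgelist` returns a `phylo_network`.
#' @export
write_edgelist <- function(net, file) {
  lines <- c(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"),
             paste(names(net$labels), unname(net$labels), sep = "\t"))
  writeLines(lines, file)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(file) {
  parts <- strsplit(readLines(file), "\t", fixed = TRUE)
  edges <- matrix(integer(), ncol = 2L)
  labels <- character()
  for (p in parts) {
    if (length(p) != 2L) next
    if (grepl("^[0-9]+$", p[2L])) {
      edges <- rbind(edges, as.integer(p))
    } else {
      labels[p[1L]] <- p[2L]
    }
  }
  phylo_network(edges, labels)
}
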