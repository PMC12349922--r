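#' Parse a Newick string into a tree
#'
#' A from-scratch, fully iterative Newick parser (no recursion, so
#' pathologically deep trees such as 10,000-node caterpillars parse
#' without hitting expression-depth limits). Supports branch lengths
#' (\code{:0.123}), internal-node labels/support values, single-quoted
#' labels and arbitrary whitespace. Child order is preserved.
#'
#' The tree is stored in a flat, vectorized form (the natural R analogue
#' of a node-and-children class): parallel vectors over node indices plus
#' a list of child-index vectors.
#'
#' @param text A Newick string ending in \code{;}.
#' @return An object of class \code{ltr_tree}: a list with \code{label}
#'   (character), \code{parent} (integer, NA at the root),
#'   \code{branch_length} (numeric, NA when absent), \code{children}
#'   (list of integer vectors, empty at leaves), \code{root} (integer
#'   index) and \code{n} (node count).
#' @export
parse_newick <- function(text) {
  text <- paste(text, collapse = "")
  chars <- strsplit(text, "")[[1]]
  n_alloc <- 64L
  label <- character(n_alloc)
  parent <- integer(n_alloc)
  blen <- rep(NA_real_, n_alloc)
  n_nodes <- 0L

  new_node <- function(par) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > n_alloc) {
      n_alloc <<- n_alloc * 2L
      length(label) <<- n_alloc
      length(parent) <<- n_alloc
      length(blen) <<- n_alloc
      blen[(n_nodes):n_alloc] <<- NA_real_
    }
    label[n_nodes] <<- ""
    parent[n_nodes] <<- if (is.na(par)) NA_integer_ else par
    n_nodes
  }

  perr <- function(i, msg) {
    stop(sprintf("newick parse error at character %d: %s", i, msg), call. = FALSE)
  }

  root <- new_node(NA)
  cur <- root
  depth <- 0L
  i <- 1L
  nchars <- length(chars)
  finished <- FALSE
  while (i <= nchars) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (finished) perr(i, "trailing content after ';'")
    if (ch == "(") {
      depth <- depth + 1L
      cur <- new_node(cur)
      i <- i + 1L
    } else if (ch == ",") {
      if (is.na(parent[cur])) perr(i, "',' outside parentheses")
      cur <- new_node(parent[cur])
      i <- i + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) perr(i, "unbalanced ')'")
      cur <- parent[cur]
      i <- i + 1L
    } else if (ch == ";") {
      if (depth != 0L) perr(i, "unbalanced parentheses at ';'")
      finished <- TRUE
      i <- i + 1L
    } else if (ch == ":") {
      j <- i + 1L
      while (j <= nchars && !chars[j] %in% c(",", ")", ";", "(")) j <- j + 1L
      val <- suppressWarnings(as.numeric(trimws(paste(chars[(i + 1L):(j - 1L)],
                                                      collapse = ""))))
      if (is.na(val)) perr(i, "invalid branch length")
      blen[cur] <- val
      i <- j
    } else if (ch == "'") {
      j <- i + 1L
      while (j <= nchars && chars[j] != "'") j <- j + 1L
      if (j > nchars) perr(i, "unterminated quoted label")
      label[cur] <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      i <- j + 1L
    } else {
      j <- i
      while (j <= nchars && !chars[j] %in% c(",", ")", ";", ":", "(")) j <- j + 1L
      label[cur] <- trimws(paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  if (!finished) perr(nchars, "missing terminating ';'")

  label <- label[seq_len(n_nodes)]
  parent <- parent[seq_len(n_nodes)]
  blen <- blen[seq_len(n_nodes)]
  children <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) children[[k]] <- integer(0)
  for (k in seq_len(n_nodes)) {
    p <- parent[k]
    if (!is.na(p)) children[[p]] <- c(children[[p]], k)
  }
  structure(list(label = label, parent = parent, branch_length = blen,
                 children = children, root = root, n = n_nodes),
            class = "ltr_tree")
}

#' Serialize a tree back to Newick
#'
#' Iterative (explicit-stack) serialization; \code{parse_newick} composed
#' with \code{serialize_newick} preserves topology, labels and branch
#' lengths.
#'
#' @param tree An \code{ltr_tree}.
#' @return A Newick string ending in \code{;}.
#' @export
serialize_newick <- function(tree) {
  quote_label <- function(x) {
    if (grepl("[ ,():;']", x)) paste0("'", x, "'") else x
  }
  piece <- character(tree$n)
  # post-order via two-pass explicit stack
  stack <- tree$root
  order_out <- integer(tree$n)
  filled <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    filled <- filled + 1L
    order_out[filled] <- v
    stack <- c(stack, tree$children[[v]])
  }
  for (v in rev(order_out)) {
    kids <- tree$children[[v]]
    s <- if (length(kids)) {
      paste0("(", paste(piece[kids], collapse = ","), ")")
    } else ""
    s <- paste0(s, quote_label(tree$label[v]))
    if (!is.na(tree$branch_length[v])) {
      s <- paste0(s, ":", format(tree$branch_length[v], scientific = FALSE))
    }
    piece[v] <- s
  }
  paste0(piece[tree$root], ";")
}

#' Leaf test for tree nodes
#' @param tree An \code{ltr_tree}.
#' @return Logical vector over node indices.
#' @keywords internal
is_leaf <- function(tree) lengths(tree$children) == 0L

#' Default REXdb-style clade marker pattern
#'
#' Marker leaves are recognized by a \code{#<clade>} label suffix; the
#' default vocabulary covers the six Ty1/Copia clades (Ale, Tork, Ikeros,
#' TAR, Ivana, SIRE) and five Ty3/Gypsy clades (Galadriel, Reina, CRM,
#' Tekay, Athila) defined for flowering plants.
#'
#' @return A regular expression with the clade as capture group 1.
#' @export
default_marker_pattern <- function() {
  "#(Ale|Tork|Ikeros|TAR|Ivana|SIRE|Galadriel|Reina|CRM|Tekay|Athila)$"
}

#' Root-to-marker paths for every marker leaf
#'
#' Traverses the tree with a stack-based depth-first search (O(height)
#' working space, no recursion) maintaining the current root-to-node
#' path, and records the full path for every leaf whose label matches the
#' marker pattern. Purely numeric labels (support values) are never
#' treated as markers.
#'
#' @param tree An \code{ltr_tree}.
#' @param marker_pattern Regular expression matched against leaf labels;
#'   capture group 1, when present, yields the clade (default
#'   [default_marker_pattern()]).
#' @return Named list: marker label -> integer vector of node indices
#'   from the root (first) to the marker leaf (last).
#' @export
collect_label_paths <- function(tree, marker_pattern = default_marker_pattern()) {
  leaf <- is_leaf(tree)
  paths <- list()
  # stack of nodes; path maintained alongside via depth bookkeeping
  stack_node <- tree$root
  stack_depth <- 1L
  path <- integer(0)
  while (length(stack_node)) {
    k <- length(stack_node)
    v <- stack_node[k]; d <- stack_depth[k]
    stack_node <- stack_node[-k]; stack_depth <- stack_depth[-k]
    path <- c(path[seq_len(d - 1L)], v)
    if (leaf[v]) {
      lab <- tree$label[v]
      if (nzchar(lab) && !is_support_label(lab) && grepl(marker_pattern, lab)) {
        paths[[lab]] <- path
      }
    } else {
      kids <- tree$children[[v]]
      # push children in reverse so DFS visits them left-to-right
      stack_node <- c(stack_node, rev(kids))
      stack_depth <- c(stack_depth, rep(d + 1L, length(kids)))
    }
  }
  if (!length(paths)) {
    stop("no marker leaves match the pattern; classification impossible",
         call. = FALSE)
  }
  paths
}

is_support_label <- function(x) grepl("^[0-9.eE+-]+$", x)

common_prefix_length <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}
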