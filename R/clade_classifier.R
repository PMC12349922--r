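#' Classify one query path against the marker paths
#'
#' The overlap between a query and a marker is the length of the longest
#' common prefix of their root-anchored paths, i.e. the depth of their
#' most recent common ancestor plus one. The marker with maximal overlap
#' wins; ties are broken in favour of the deeper (longer-path) marker,
#' then the lexicographically smallest marker label. A query whose best
#' overlap does not exceed \code{min_overlap - 1} shares only nodes near
#' the root with every marker and is reported "unclassified".
#'
#' @param query_path Integer vector of node indices, root first.
#' @param label_paths Named list of marker paths from
#'   [collect_label_paths()].
#' @param query_label Label to report for the query.
#' @param min_overlap Minimum overlap for a clade call (default 2: the
#'   root alone is never evidence).
#' @return A one-row data frame: \code{query_label}, \code{clade},
#'   \code{overlap}, \code{winning_marker}.
#' @export
classify_node <- function(query_path, label_paths, query_label = "",
                          min_overlap = 2L) {
  if (!length(label_paths)) stop("no marker paths supplied", call. = FALSE)
  labs <- names(label_paths)
  ov <- vapply(label_paths, common_prefix_length, integer(1), b = query_path)
  depths <- lengths(label_paths)
  ord <- order(-ov, -depths, labs)
  best <- ord[1]
  if (ov[best] < min_overlap) {
    return(data.frame(query_label = query_label, clade = "unclassified",
                      overlap = ov[best], winning_marker = "",
                      stringsAsFactors = FALSE))
  }
  data.frame(query_label = query_label,
             clade = clade_from_label(labs[best]),
             overlap = ov[best],
             winning_marker = labs[best],
             stringsAsFactors = FALSE)
}

clade_from_label <- function(label) sub("^.*#", "", label)

#' Clade classification of every query leaf in a tree
#'
#' Collects root-to-marker paths, then traverses the tree depth-first
#' (explicit stack, O(height) space) and classifies every non-marker leaf
#' by its path overlap with the markers (see [classify_node()]).
#' Output order is DFS (left-to-right) leaf order, so identical input
#' text yields byte-identical output.
#'
#' @param tree An \code{ltr_tree} from [parse_newick()], or a Newick
#'   string.
#' @param marker_pattern Regular expression identifying marker leaves
#'   (default [default_marker_pattern()]).
#' @param min_overlap See [classify_node()].
#' @param csv Optional path; when given, the assignments are written as
#'   CSV (columns \code{query_label}, \code{clade}, \code{overlap},
#'   \code{winning_marker}).
#' @return Data frame of assignments, one row per non-marker leaf.
#' @export
classify_tree <- function(tree, marker_pattern = default_marker_pattern(),
                          min_overlap = 2L, csv = NULL) {
  if (is.character(tree)) tree <- parse_newick(tree)
  label_paths <- collect_label_paths(tree, marker_pattern)
  leaf <- is_leaf(tree)

  # Pre-sort markers by the tie-break order (deeper path first, then label)
  # and pad their paths into a matrix: the winner for a query is then the
  # FIRST marker attaining the maximal common-prefix length, and the prefix
  # lengths for all markers are computed in one vectorized sweep per query.
  labs <- names(label_paths)
  depths <- lengths(label_paths)
  ord <- order(-depths, labs)
  labs <- labs[ord]; depths <- depths[ord]; label_paths_s <- label_paths[ord]
  max_d <- max(depths)
  pmat <- matrix(NA_integer_, nrow = length(labs), ncol = max_d)
  for (k in seq_along(labs)) pmat[k, seq_len(depths[k])] <- label_paths_s[[k]]

  best_marker <- function(query_path) {
    L <- length(query_path)
    ov <- integer(length(labs))
    alive <- rep(TRUE, length(labs))
    for (j in seq_len(min(L, max_d))) {
      alive <- alive & !is.na(pmat[, j]) & pmat[, j] == query_path[j]
      if (!any(alive)) break
      ov <- ov + alive
    }
    b <- which.max(ov)
    c(b, ov[b])
  }

  q_label <- character(0); q_best <- integer(0); q_ov <- integer(0)
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
      is_marker <- nzchar(lab) && !is_support_label(lab) &&
        grepl(marker_pattern, lab)
      if (!is_marker) {
        hit <- best_marker(path)
        q_label <- c(q_label, lab)
        q_best <- c(q_best, hit[1])
        q_ov <- c(q_ov, hit[2])
      }
    } else {
      kids <- tree$children[[v]]
      stack_node <- c(stack_node, rev(kids))
      stack_depth <- c(stack_depth, rep(d + 1L, length(kids)))
    }
  }
  if (!length(q_label)) {
    res <- data.frame(query_label = character(), clade = character(),
                      overlap = integer(), winning_marker = character(),
                      stringsAsFactors = FALSE)
    if (!is.null(csv)) utils::write.csv(res, csv, row.names = FALSE, quote = FALSE)
    return(res)
  }
  classified <- q_ov >= min_overlap
  res <- data.frame(
    query_label = q_label,
    clade = ifelse(classified, clade_from_label(labs[q_best]), "unclassified"),
    overlap = q_ov,
    winning_marker = ifelse(classified, labs[q_best], ""),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  if (!is.null(csv)) {
    utils::write.csv(res, csv, row.names = FALSE, quote = FALSE)
  }
  res
}
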