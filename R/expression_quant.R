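#' Fragment-to-locus compatibility from RNA-seq alignments
#'
#' An alignment record is compatible with an element when at least
#' \code{min_frac} of its aligned reference span (from the CIGAR) lies
#' inside the element's \code{[start, end]}. A fragment (read name; a
#' pair is one fragment) is compatible with an element when any of its
#' records — primary or secondary, so multimappers contribute all their
#' candidate loci — is compatible. Fragments compatible with no element
#' are dropped from element counting but still count in
#' \code{total_mapped_fragments}.
#'
#' @param sam Result of [read_sam_alignments()].
#' @param elements Element data frame (see [read_pass_list()]).
#' @param min_frac Minimum fraction of the aligned span inside the
#'   element (default 0.5).
#' @return A list with \code{pairs} (data frame \code{read_id},
#'   \code{element_id}: the sparse compatibility matrix),
#'   \code{total_mapped_fragments}, and \code{unique_counts} (named
#'   vector: fragments compatible with exactly one element, by element).
#' @export
assign_fragments <- function(sam, elements, min_frac = 0.5) {
  aln <- sam$alignments
  aln <- aln[aln$is_mapped & aln$span_width > 0, , drop = FALSE]

  known <- aln$chrom %in% unique(elements$chrom)
  if (any(!known)) {
    for (ch in unique(aln$chrom[!known])) {
      warning(sprintf("alignments on chromosome '%s' overlap no annotated element",
                      ch))
    }
  }

  pairs <- NULL
  if (nrow(aln)) {
    rec_gr <- GenomicRanges::GRanges(
      rep(aln$chrom, vapply(aln$span, length, integer(1))),
      do.call(c, unname(aln$span))
    )
    rec_idx <- rep(seq_len(nrow(aln)), vapply(aln$span, length, integer(1)))
    el_gr <- GenomicRanges::GRanges(elements$chrom,
                                    IRanges::IRanges(elements$start, elements$end))
    ov <- GenomicRanges::findOverlaps(rec_gr, el_gr)
    if (length(ov)) {
      inter <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(rec_gr)[S4Vectors::queryHits(ov)],
        IRanges::ranges(el_gr)[S4Vectors::subjectHits(ov)]
      ))
      df <- data.frame(rec = rec_idx[S4Vectors::queryHits(ov)],
                       el = S4Vectors::subjectHits(ov), w = inter)
      agg <- stats::aggregate(w ~ rec + el, data = df, FUN = sum)
      ok <- agg$w >= min_frac * aln$span_width[agg$rec]
      if (any(ok)) {
        pairs <- unique(data.frame(
          read_id = aln$read_id[agg$rec[ok]],
          element_id = elements$element_id[agg$el[ok]],
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  if (is.null(pairs)) {
    pairs <- data.frame(read_id = character(), element_id = character(),
                        stringsAsFactors = FALSE)
  }
  pairs <- pairs[order(pairs$read_id, pairs$element_id), , drop = FALSE]
  rownames(pairs) <- NULL

  k <- table(pairs$read_id)
  uniq <- pairs[pairs$read_id %in% names(k)[k == 1], ]
  unique_counts <- stats::setNames(rep(0, nrow(elements)), elements$element_id)
  if (nrow(uniq)) {
    tab <- table(uniq$element_id)
    unique_counts[names(tab)] <- as.numeric(tab)
  }

  list(pairs = pairs, total_mapped_fragments = sam$total_mapped_fragments,
       unique_counts = unique_counts)
}

#' EM reassignment of ambiguous fragments
#'
#' Expectation-maximization on a uniform-prior mixture over loci: each
#' k-way ambiguous fragment starts at weight 1/k per compatible element;
#' the E-step reweights fragments proportionally to current element
#' abundances (count / length) and the M-step sums weights into new
#' counts. The total count equals the number of element-compatible
#' fragments at every iteration. This is a deliberately simple fractional
#' reassignment model, not a reimplementation of Telescope's full
#' Bayesian machinery.
#'
#' @param pairs Compatibility data frame (\code{read_id},
#'   \code{element_id}) from [assign_fragments()].
#' @param lengths Named numeric vector of element lengths (bp) covering
#'   every element in \code{pairs}.
#' @param tol Convergence tolerance on the max absolute count change
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @return Named numeric vector of expected fragment counts per element
#'   (zero for elements in \code{lengths} with no compatible fragment),
#'   with attributes \code{iterations} and \code{sum_trace} (total count
#'   at each iteration, for conservation checks).
#' @export
em_reassign <- function(pairs, lengths, tol = 1e-6, max_iter = 100L) {
  counts <- stats::setNames(rep(0, length(lengths)), names(lengths))
  if (!nrow(pairs)) {
    attr(counts, "iterations") <- 0L
    attr(counts, "sum_trace") <- numeric(0)
    return(counts)
  }
  stopifnot(all(pairs$element_id %in% names(lengths)))

  # collapse fragments into equivalence classes by compatibility set
  sets <- split(pairs$element_id, pairs$read_id)
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "\r"), character(1))
  class_n <- table(keys)
  class_members <- strsplit(names(class_n), "\r", fixed = TRUE)
  n_frag <- sum(class_n)

  el_idx <- lapply(class_members, match, table = names(lengths))
  counts[] <- 0
  for (j in seq_along(el_idx)) {
    counts[el_idx[[j]]] <- counts[el_idx[[j]]] +
      as.numeric(class_n[j]) / length(el_idx[[j]])
  }

  sum_trace <- sum(counts)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    theta <- counts / lengths
    new_counts <- stats::setNames(rep(0, length(lengths)), names(lengths))
    for (j in seq_along(el_idx)) {
      idx <- el_idx[[j]]
      w <- theta[idx]
      w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(idx), length(idx))
      new_counts[idx] <- new_counts[idx] + as.numeric(class_n[j]) * w
    }
    sum_trace <- c(sum_trace, sum(new_counts))
    delta <- max(abs(new_counts - counts))
    counts <- new_counts
    if (delta < tol || iter >= max_iter) break
  }
  stopifnot(abs(sum(counts) - n_frag) < 1e-6)
  attr(counts, "iterations") <- iter
  attr(counts, "sum_trace") <- sum_trace
  counts
}

#' Per-locus FPKM table
#'
#' FPKM = fragments x 1e9 / (length_bp x total mapped fragments). The
#' same fragment-based value is reported whether reads are single- or
#' paired-end (the unit is often printed RPKM for single-end data).
#'
#' @param counts Named numeric vector of per-element fragment counts
#'   (possibly fractional after EM).
#' @param lengths Named numeric vector of element lengths (bp).
#' @param total_mapped_fragments Positive total of mapped fragments.
#' @param expressed_min Minimum count for an element to be called
#'   expressed (default 1).
#' @return A data frame sorted by \code{element_id}: \code{element_id},
#'   \code{length_bp}, \code{raw_fragments}, \code{fpkm},
#'   \code{expressed}; the number of expressed elements is attached as
#'   attribute \code{"n_expressed"}.
#' @export
compute_fpkm <- function(counts, lengths, total_mapped_fragments,
                         expressed_min = 1) {
  stopifnot(total_mapped_fragments > 0)
  lengths <- lengths[names(counts)]
  if (any(is.na(lengths) | lengths <= 0)) {
    stop("zero-length or unknown element in FPKM computation", call. = FALSE)
  }
  out <- data.frame(
    element_id = names(counts),
    length_bp = as.numeric(lengths),
    raw_fragments = as.numeric(counts),
    stringsAsFactors = FALSE
  )
  out$fpkm <- out$raw_fragments * 1e9 / (out$length_bp * total_mapped_fragments)
  out$expressed <- out$raw_fragments >= expressed_min
  out <- out[order(out$element_id), ]
  rownames(out) <- NULL
  attr(out, "n_expressed") <- sum(out$expressed)
  out
}

#' Quantify per-element expression from a SAM file
#'
#' Convenience wrapper: compatibility, EM reassignment, FPKM.
#'
#' @param sam Result of [read_sam_alignments()] or a SAM file path.
#' @param elements Element data frame.
#' @inheritParams assign_fragments
#' @inheritParams em_reassign
#' @inheritParams compute_fpkm
#' @return The [compute_fpkm()] table with an extra
#'   \code{unique_fragments} column (counts before reassignment,
#'   unique-compatible fragments only).
#' @export
quantify_expression <- function(sam, elements, min_frac = 0.5, tol = 1e-6,
                                max_iter = 100L, expressed_min = 1) {
  if (is.character(sam)) sam <- read_sam_alignments(sam)
  lengths <- stats::setNames(as.numeric(elements$end - elements$start + 1),
                             elements$element_id)
  comp <- assign_fragments(sam, elements, min_frac = min_frac)
  counts <- em_reassign(comp$pairs, lengths, tol = tol, max_iter = max_iter)
  tab <- compute_fpkm(counts, lengths, comp$total_mapped_fragments,
                      expressed_min = expressed_min)
  tab$unique_fragments <- as.numeric(comp$unique_counts[tab$element_id])
  attr(tab, "n_expressed") <- sum(tab$expressed)
  tab
}
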