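#' Pairwise local-alignment identity between two nucleotide sequences
#'
#' Computes the best local (Smith-Waterman) alignment under the scoring
#' scheme match +2, mismatch -3, gap open -5, gap extend -2 (a gap of
#' length L costs 5 + 2L) and reports the alignment-column identity
#' (matches / alignment columns, internal gaps counted as columns) plus
#' the fraction of the longer sequence covered by the alignment. The
#' longer-sequence coverage is what cd-hit's \code{-aL} threshold applies
#' to when the longer sequence is the cluster representative.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings.
#' @return Named numeric vector with \code{identity} and
#'   \code{coverage_longer}, both fractions in [0, 1]. An empty best local
#'   alignment (score 0) yields 0 for both.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  # canonical orientation (longer sequence first, ties by content) so that
  # among co-optimal alignments the same one is reported for (a,b) and
  # (b,a): identity is then well-defined and symmetric
  if (nchar(seq_b) > nchar(seq_a) ||
      (nchar(seq_b) == nchar(seq_a) && seq_b < seq_a)) {
    tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp
  }
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "local",
    substitutionMatrix = dna_submat(),
    gapOpening = 5, gapExtension = 2
  )
  ncols <- Biostrings::nchar(aln)
  if (Biostrings::score(aln) <= 0 || ncols == 0) {
    return(c(identity = 0, coverage_longer = 0))
  }
  identity <- Biostrings::pid(aln, type = "PID1") / 100
  aligned_on_longer <- IRanges::width(Biostrings::pattern(aln))
  c(identity = identity,
    coverage_longer = aligned_on_longer / nchar(seq_a))
}

dna_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE)
    }
    cache
  }
})

#' Greedy incremental clustering of LTR sequences into families
#'
#' Clusters sequences with cd-hit-est semantics: sequences are sorted by
#' length descending (ties by id ascending) and processed in order; each
#' sequence joins the first existing cluster whose representative aligns
#' with identity >= \code{c} and with the alignment covering at least
#' \code{aL} of the representative (the longer sequence), otherwise it
#' founds a new cluster with itself as representative. The k-mer
#' prefilter heuristics of cd-hit are not reproduced; alignments are
#' exact local alignments, so the method is intended for desk-scale
#' inputs (thousands of LTRs, not millions).
#'
#' @param sequences Named character vector of nucleotide sequences
#'   (names are element ids).
#' @param c Minimum identity fraction (default 0.8).
#' @param aL Minimum alignment coverage of the representative (default 0.8).
#' @return A data frame of clusters sorted by member count descending
#'   (ties by representative length descending, then representative id),
#'   with columns \code{family_id} ("FAM_<n>" in that order),
#'   \code{representative_id}, \code{n_members}, \code{copy_number},
#'   \code{coverage_bp} (both NA until filled in from masking) and
#'   list-column \code{member_ids}.
#' @export
greedy_cluster <- function(sequences, c = 0.8, aL = 0.8) {
  if (length(sequences) == 0) stop("no sequences to cluster", call. = FALSE)
  stopifnot(c > 0, c <= 1, aL > 0, aL <= 1, !is.null(names(sequences)))

  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]

  rep_ids <- character(0)
  members <- list()
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    placed <- FALSE
    for (k in seq_along(rep_ids)) {
      m <- pairwise_identity(sequences[[i]], sequences[[rep_ids[k]]])
      if (m["identity"] >= c && m["coverage_longer"] >= aL) {
        members[[k]] <- c(members[[k]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_ids <- c(rep_ids, id)
      members[[length(rep_ids)]] <- id
    }
  }

  sizes <- lengths(members)
  rep_len <- nchar(sequences[rep_ids])
  ord2 <- order(-sizes, -rep_len, rep_ids)
  out <- data.frame(
    family_id = sprintf("FAM_%d", seq_along(ord2)),
    representative_id = rep_ids[ord2],
    n_members = sizes[ord2],
    copy_number = NA_integer_,
    coverage_bp = NA_integer_,
    stringsAsFactors = FALSE
  )
  out$member_ids <- members[ord2]
  out
}

#' Build a family library and element-to-family mapping from clusters
#'
#' Emits one FASTA record per cluster, headed \code{FAM_<n>#LTR} and
#' carrying the representative (seed) sequence, together with a mapping of
#' every input element id to its family id.
#'
#' @param clusters Output of [greedy_cluster()].
#' @param sequences The named character vector that was clustered.
#' @return A list with \code{library} (named character vector of FASTA
#'   records) and \code{mapping} (data frame with \code{element_id},
#'   \code{family_id}, one row per clustered element).
#' @export
build_library <- function(clusters, sequences) {
  lib <- stats::setNames(
    as.character(sequences[clusters$representative_id]),
    paste0(clusters$family_id, "#LTR")
  )
  mapping <- data.frame(
    element_id = unlist(clusters$member_ids, use.names = FALSE),
    family_id = rep(clusters$family_id, lengths(clusters$member_ids)),
    stringsAsFactors = FALSE
  )
  list(library = lib, mapping = mapping)
}

#' Extract 5'-LTR sequences for a set of elements
#'
#' Pulls the 5'-LTR interval of each element out of the genome; elements
#' without LTR interval annotation fall back to their full span.
#'
#' @param elements Element data frame (see [read_pass_list()]).
#' @param genome Named character vector of chromosome sequences.
#' @return Named character vector of 5'-LTR sequences keyed by element id.
#' @export
extract_ltr5_sequences <- function(elements, genome) {
  vapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    if (!e$chrom %in% names(genome)) {
      stop(sprintf("element %s on unknown chromosome '%s'", e$element_id, e$chrom),
           call. = FALSE)
    }
    s <- if (!is.na(e$ltr5_start)) e$ltr5_start else e$start
    t <- if (!is.na(e$ltr5_end)) e$ltr5_end else e$end
    substr(genome[[e$chrom]], s, t)
  }, character(1)) |> stats::setNames(elements$element_id)
}
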