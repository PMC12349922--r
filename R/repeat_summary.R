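#' Per-family copy number and merged genome coverage from repeat hits
#'
#' Copy number counts hit rows (the way repeat annotation tools report
#' "copies"; fragmented alignments inflate it). Coverage is the length of
#' the union of each family's intervals per chromosome, so overlapping
#' hits are never double-counted; genome-wide totals additionally take the
#' union across all families, so nested or overlapping families do not
#' double-count either.
#'
#' @param hits Hit data frame (see [read_repeatmasker_out()] /
#'   [naive_mask()]).
#' @param genome_sizes Named integer vector of chromosome lengths (bp).
#' @return A list with \code{families} (data frame: \code{family_id},
#'   \code{copy_number}, \code{coverage_bp}, \code{coverage_pct}) sorted
#'   by coverage descending, and \code{genome} (list: \code{genome_bp},
#'   \code{total_hits}, \code{total_coverage_bp}, \code{total_pct}).
#' @export
summarize_hits <- function(hits, genome_sizes) {
  genome_bp <- sum(as.numeric(genome_sizes))
  if (genome_bp <= 0) stop("genome size must be positive", call. = FALSE)

  if (nrow(hits)) {
    unknown <- setdiff(unique(hits$chrom), names(genome_sizes))
    if (length(unknown)) {
      stop(sprintf("hit on unknown chromosome '%s'", unknown[1]), call. = FALSE)
    }
    beyond <- hits$end > genome_sizes[hits$chrom]
    if (any(beyond)) {
      i <- which(beyond)[1]
      stop(sprintf("hit beyond end of %s: %d > %d", hits$chrom[i],
                   hits$end[i], genome_sizes[[hits$chrom[i]]]), call. = FALSE)
    }
  }

  union_bp <- function(df) {
    if (!nrow(df)) return(0L)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    sum(IRanges::width(GenomicRanges::reduce(gr)))
  }

  fam_ids <- sort(unique(hits$family_id))
  families <- data.frame(
    family_id = fam_ids,
    copy_number = vapply(fam_ids, function(f) sum(hits$family_id == f), integer(1)),
    coverage_bp = vapply(fam_ids, function(f) union_bp(hits[hits$family_id == f, ]),
                         integer(1)),
    stringsAsFactors = FALSE
  )
  families$coverage_pct <- families$coverage_bp / genome_bp
  families <- families[order(-families$coverage_bp, families$family_id), ]
  rownames(families) <- NULL

  total_cov <- union_bp(hits)
  list(
    families = families,
    genome = list(genome_bp = genome_bp, total_hits = nrow(hits),
                  total_coverage_bp = total_cov,
                  total_pct = total_cov / genome_bp)
  )
}

#' Genome-wide LTR-RT percentage
#'
#' @param total_ltr_bp Total masked LTR-RT bases (merged union, bp).
#' @param genome_bp Genome size (bp).
#' @return Percentage, \code{100 * total_ltr_bp / genome_bp}.
#' @export
genome_ltr_percentage <- function(total_ltr_bp, genome_bp) {
  if (genome_bp == 0) stop("genome size is zero", call. = FALSE)
  stopifnot(total_ltr_bp >= 0, total_ltr_bp <= genome_bp)
  100 * total_ltr_bp / genome_bp
}

#' Mean cluster size from intact-element and cluster counts
#'
#' @param n_intact Number of intact elements.
#' @param n_clusters Number of clusters.
#' @return Average number of elements per cluster.
#' @export
mean_cluster_size <- function(n_intact, n_clusters) {
  if (n_clusters <= 0) stop("cluster count must be positive", call. = FALSE)
  n_intact / n_clusters
}

#' Naive genome masking against a repeat library
#'
#' A desk-scale testing device standing in for a full repeat masker: each
#' library record is scanned against both strands of each chromosome
#' allowing substitutions only (no indels), and matches with identity >=
#' \code{min_identity} and length >= \code{min_length} are kept,
#' greedily selecting non-overlapping hits by score. Suitable for small
#' synthetic genomes; it is not a RepeatMasker replacement.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param library Named character vector of library sequences.
#' @param min_identity Minimum identity fraction (default 0.8).
#' @param min_length Minimum hit length in bp (default 100).
#' @return Hit data frame in the same layout as
#'   [read_repeatmasker_out()]; \code{score_or_divergence} holds the
#'   mismatch fraction.
#' @export
naive_mask <- function(genome, library, min_identity = 0.8, min_length = 100L) {
  if (!length(library)) return(empty_hits())
  cand <- list()
  for (lib_name in names(library)) {
    fam <- sub("#.*$", "", lib_name)
    pat <- library[[lib_name]]
    plen <- nchar(pat)
    if (plen < min_length) next
    max_mm <- floor(plen * (1 - min_identity))
    for (chrom in names(genome)) {
      subj <- Biostrings::DNAString(genome[[chrom]])
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(pat)))
        m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mm,
                                      with.indels = FALSE)
        if (!length(m)) next
        mm <- Biostrings::neditStartingAt(p, subj,
                                          starting.at = Biostrings::start(m))
        keep <- (1 - mm / plen) >= min_identity
        if (!any(keep)) next
        cand[[length(cand) + 1]] <- data.frame(
          chrom = chrom,
          start = Biostrings::start(m)[keep], end = Biostrings::end(m)[keep],
          family_id = fam,
          score_or_divergence = mm[keep] / plen,
          strand = strand,
          score = 2 * (plen - mm[keep]) - 3 * mm[keep],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(cand)) return(empty_hits())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$chrom, cand$start), ]

  # greedy non-overlapping selection by score
  kept <- logical(nrow(cand))
  occupied <- list()
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]
    occ <- occupied[[ch]]
    ir <- IRanges::IRanges(cand$start[i], cand$end[i])
    if (is.null(occ) || !length(IRanges::findOverlaps(ir, occ))) {
      kept[i] <- TRUE
      occupied[[ch]] <- if (is.null(occ)) ir else c(occ, ir)
    }
  }
  out <- cand[kept, c("chrom", "start", "end", "family_id",
                      "score_or_divergence", "strand")]
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}
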