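#' Longest open reading frame across all six frames
#'
#' Scans the three forward and three reverse-complement frames for ORFs
#' running from an ATG to the next in-frame stop codon (the stop is
#' required and excluded from the protein). Returns the longest ORF; ties
#' are broken by frame order +1, +2, +3, -1, -2, -3, then by leftmost
#' start within the frame. Ambiguous codons translate to X.
#'
#' @param seq Nucleotide string, length >= 3.
#' @param min_aa Minimum protein length in amino acids (default 100);
#'   \code{NULL} is returned when the longest ORF falls short.
#' @return \code{NULL}, or a list with \code{frame} (+1..+3, -1..-3),
#'   \code{nt_start}, \code{nt_end} (1-based inclusive on the forward
#'   strand of \code{seq}, excluding the stop codon) and \code{protein}.
#' @export
longest_orf <- function(seq, min_aa = 100L) {
  stopifnot(nchar(seq) >= 3)
  seq <- toupper(seq)
  n <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

  best <- NULL
  frames <- list(c(1L, 0L), c(1L, 1L), c(1L, 2L), c(-1L, 0L), c(-1L, 1L), c(-1L, 2L))
  for (fr in frames) {
    dir <- fr[1]; off <- fr[2]
    s <- if (dir > 0) seq else rc
    usable <- n - off
    if (usable < 3) next
    sub <- substr(s, off + 1L, off + (usable %/% 3L) * 3L)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                               if.fuzzy.codon = "X",
                                               no.init.codon = TRUE))
    # ORF = M...* ; lazy match so each M pairs with the nearest stop
    hits <- gregexpr("M[^*]*\\*", prot, perl = TRUE)[[1]]
    if (hits[1] == -1) next
    lens <- attr(hits, "match.length") - 1L  # drop the stop
    for (j in seq_along(hits)) {
      if (!is.null(best) && lens[j] <= best$aa_len) next
      aa_start <- hits[j]
      # coordinates in the scanned strand
      cs <- off + (aa_start - 1L) * 3L + 1L
      ce <- cs + lens[j] * 3L - 1L
      if (dir > 0) {
        nt_start <- cs; nt_end <- ce
      } else {
        nt_start <- n - ce + 1L; nt_end <- n - cs + 1L
      }
      best <- list(
        frame = dir * (off + 1L),
        nt_start = nt_start, nt_end = nt_end,
        protein = substr(prot, aa_start, aa_start + lens[j] - 1L),
        aa_len = lens[j]
      )
    }
  }
  if (is.null(best) || best$aa_len < min_aa) return(NULL)
  best$aa_len <- NULL
  best
}

#' Longest ORFs for a set of element sequences
#'
#' @param sequences Named character vector of element sequences.
#' @inheritParams longest_orf
#' @return Data frame with one row per element that has a qualifying ORF:
#'   \code{element_id}, \code{frame}, \code{nt_start}, \code{nt_end},
#'   \code{protein}.
#' @export
find_orfs <- function(sequences, min_aa = 100L) {
  rows <- lapply(names(sequences), function(id) {
    o <- longest_orf(sequences[[id]], min_aa = min_aa)
    if (is.null(o)) return(NULL)
    data.frame(element_id = id, frame = o$frame, nt_start = o$nt_start,
               nt_end = o$nt_end, protein = o$protein, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(element_id = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the reverse-transcriptase domain of an ORF by marker alignment
#'
#' Aligns the ORF protein locally (BLOSUM62, gap open -11, extend -1)
#' against every clade-tagged marker protein and returns the best hit.
#' Marker ids must carry a \code{#<clade>} suffix (REXdb-style tagging);
#' the aligned ORF subsequence is reported as the domain.
#'
#' @param orf A row of [find_orfs()] output (or list with
#'   \code{element_id} and \code{protein}).
#' @param markers Named character vector of marker proteins; names are
#'   \code{<id>#<clade>}.
#' @param min_score Minimum alignment score to accept (default 50).
#' @return \code{NULL} if no marker scores at or above \code{min_score},
#'   else a list with \code{element_id}, \code{marker_id},
#'   \code{marker_clade}, \code{score}, \code{identity},
#'   \code{domain_protein}.
#' @export
extract_rt_domain <- function(orf, markers, min_score = 50) {
  if (!length(markers)) stop("no marker sequences supplied", call. = FALSE)
  clades <- parse_clade_tag(names(markers))
  best <- NULL
  for (k in seq_along(markers)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(orf$protein), Biostrings::AAString(markers[[k]]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1
    )
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score) {
      best <- list(
        element_id = orf$element_id,
        marker_id = names(markers)[k],
        marker_clade = clades[k],
        score = sc,
        identity = Biostrings::pid(aln, type = "PID1") / 100,
        domain_protein = gsub("-", "", as.character(Biostrings::pattern(aln)),
                              fixed = TRUE)
      )
    }
  }
  if (best$score < min_score) return(NULL)
  best
}

#' Parse the clade tag out of REXdb-style marker identifiers
#'
#' @param ids Character vector of \code{<id>#<clade>} identifiers.
#' @return Character vector of clade labels.
#' @export
parse_clade_tag <- function(ids) {
  ok <- grepl("#[^#]+$", ids)
  if (any(!ok)) {
    stop(sprintf("marker '%s' has no parsable #<clade> tag", ids[!ok][1]),
         call. = FALSE)
  }
  sub("^.*#", "", ids)
}

#' RT-domain hits for a table of ORFs
#'
#' @param orfs Output of [find_orfs()].
#' @inheritParams extract_rt_domain
#' @return Data frame of hits (one row per element with a hit):
#'   \code{element_id}, \code{marker_id}, \code{marker_clade},
#'   \code{score}, \code{identity}, \code{domain_protein}.
#' @export
extract_rt_domains <- function(orfs, markers, min_score = 50) {
  rows <- lapply(seq_len(nrow(orfs)), function(i) {
    hit <- extract_rt_domain(orfs[i, ], markers, min_score = min_score)
    if (is.null(hit)) return(NULL)
    as.data.frame(hit, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(element_id = character(), marker_id = character(),
                      marker_clade = character(), score = numeric(),
                      identity = numeric(), domain_protein = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
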