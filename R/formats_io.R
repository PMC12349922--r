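#' Read an LTR_retriever-style pass.list summary table
#'
#' Parses the tab-separated summary of intact LTR retrotransposons produced
#' by LTR_retriever ("pass.list"). The first column is a locus token of the
#' form \code{chrom:start..end}. Remaining columns are located by name when
#' a \code{#}-prefixed header line is present (matched case-insensitively on
#' "identity", "strand", "super", "insertion" and "internal"), otherwise by
#' the positional layout LTR_retriever writes (internal region in column 7,
#' identity 8, strand 9, superfamily 10, insertion time 12).
#'
#' LTR intervals are derived from the internal-region token
#' (\code{IN:a..b}): the 5' LTR spans \code{start..a-1} and the 3' LTR
#' \code{b+1..end}. Identity values greater than 1 are interpreted as
#' percentages and divided by 100.
#'
#' @param path Path to a pass.list file.
#' @return A data frame of intact elements, one row per non-comment line,
#'   with columns \code{element_id} ("LTRRT_<n>" in file order),
#'   \code{chrom}, \code{start}, \code{end}, \code{strand},
#'   \code{ltr5_start}, \code{ltr5_end}, \code{ltr3_start},
#'   \code{ltr3_end}, \code{ltr_identity}, \code{superfamily},
#'   \code{insertion_time_years}, \code{family_id}, \code{clade}.
#'   Coordinates are 1-based inclusive. An empty file yields a zero-row
#'   data frame.
#' @export
read_pass_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- NULL
  is_comment <- startsWith(trimws(lines), "#")
  if (any(is_comment)) {
    header <- strsplit(sub("^#+\\s*", "", lines[which(is_comment)[1]]), "\t")[[1]]
  }
  keep <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(keep)) return(empty_elements())

  find_col <- function(pattern, fallback) {
    if (!is.null(header)) {
      hit <- grep(pattern, header, ignore.case = TRUE)
      if (length(hit)) return(hit[1])
    }
    fallback
  }
  col_internal  <- find_col("internal", 7L)
  col_identity  <- find_col("identity", 8L)
  col_strand    <- find_col("strand", 9L)
  col_superfam  <- find_col("super", 10L)
  col_instime   <- find_col("insertion", 12L)

  rows <- lapply(seq_along(keep), function(i) {
    ln <- keep[i]
    fields <- strsplit(lines[ln], "\t")[[1]]
    loc <- parse_locus_token(fields[1])
    if (is.null(loc)) {
      stop(sprintf("malformed locus token '%s' on line %d of %s",
                   fields[1], ln, path), call. = FALSE)
    }
    get <- function(j) if (j <= length(fields)) fields[j] else NA_character_
    identity <- suppressWarnings(as.numeric(get(col_identity)))
    if (!is.na(identity) && identity > 1) identity <- identity / 100
    strand <- get(col_strand)
    if (is.na(strand) || !strand %in% c("+", "-")) strand <- "?"
    superfam <- normalize_superfamily(get(col_superfam))
    instime <- suppressWarnings(as.numeric(get(col_instime)))
    internal <- parse_internal_token(get(col_internal))
    ltr5 <- c(NA_integer_, NA_integer_)
    ltr3 <- c(NA_integer_, NA_integer_)
    if (!is.null(internal)) {
      ltr5 <- c(loc$start, internal[1] - 1L)
      ltr3 <- c(internal[2] + 1L, loc$end)
    }
    data.frame(
      element_id = sprintf("LTRRT_%d", i),
      chrom = loc$chrom, start = loc$start, end = loc$end, strand = strand,
      ltr5_start = ltr5[1], ltr5_end = ltr5[2],
      ltr3_start = ltr3[1], ltr3_end = ltr3[2],
      ltr_identity = identity, superfamily = superfam,
      insertion_time_years = instime,
      family_id = NA_character_, clade = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_elements <- function() {
  data.frame(
    element_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    ltr5_start = integer(), ltr5_end = integer(),
    ltr3_start = integer(), ltr3_end = integer(),
    ltr_identity = numeric(), superfamily = character(),
    insertion_time_years = numeric(),
    family_id = character(), clade = character(),
    stringsAsFactors = FALSE
  )
}

parse_locus_token <- function(token) {
  m <- regmatches(token, regexec("^(\\S+?):(\\d+)\\.\\.(\\d+)$", token))[[1]]
  if (length(m) != 4) return(NULL)
  start <- as.integer(m[3]); end <- as.integer(m[4])
  if (is.na(start) || is.na(end) || start > end) return(NULL)
  list(chrom = m[2], start = start, end = end)
}

parse_internal_token <- function(token) {
  if (is.na(token)) return(NULL)
  m <- regmatches(token, regexec("(?:IN:)?(\\d+)\\.\\.(\\d+)", token))[[1]]
  if (length(m) != 3) return(NULL)
  c(as.integer(m[2]), as.integer(m[3]))
}

normalize_superfamily <- function(x) {
  if (is.na(x)) return("unknown")
  if (grepl("copia", x, ignore.case = TRUE)) return("Copia")
  if (grepl("gypsy", x, ignore.case = TRUE)) return("Gypsy")
  "unknown"
}

#' Read intact elements from an LTR_retriever-style GFF3
#'
#' Reconstructs intact elements from a \code{pass.list.gff3} file:
#' \code{repeat_region} features define elements and
#' \code{long_terminal_repeat} child features (linked by
#' \code{Parent}/\code{ID}) supply the two LTR intervals. Regions lacking
#' an \code{ID} attribute are skipped with a warning; the number skipped is
#' attached as attribute \code{"skipped"}.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @return A data frame with the same columns as [read_pass_list()].
#' @export
read_gff3_ltr <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  regions <- gr[type == "repeat_region"]
  ltrs <- gr[type == "long_terminal_repeat"]

  ids <- if (!is.null(regions$ID)) as.character(regions$ID) else
    rep(NA_character_, length(regions))
  missing_id <- is.na(ids) | !nzchar(ids)
  n_skipped <- sum(missing_id)
  if (n_skipped > 0) {
    warning(sprintf("%d repeat_region feature(s) lacking an ID attribute were skipped",
                    n_skipped))
  }
  regions <- regions[!missing_id]
  ids <- ids[!missing_id]

  parents <- if (length(ltrs) && !is.null(ltrs$Parent)) {
    vapply(ltrs$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else character(0)

  rows <- lapply(seq_along(regions), function(i) {
    r <- regions[i]
    kid <- ltrs[!is.na(parents) & parents == ids[i]]
    kid <- kid[order(GenomicRanges::start(kid))]
    l5 <- c(NA_integer_, NA_integer_); l3 <- c(NA_integer_, NA_integer_)
    if (length(kid) >= 2) {
      l5 <- c(GenomicRanges::start(kid)[1], GenomicRanges::end(kid)[1])
      l3 <- c(GenomicRanges::start(kid)[length(kid)], GenomicRanges::end(kid)[length(kid)])
    }
    strand <- as.character(GenomicRanges::strand(r))
    if (!strand %in% c("+", "-")) strand <- "?"
    data.frame(
      element_id = ids[i],
      chrom = as.character(GenomicRanges::seqnames(r)),
      start = GenomicRanges::start(r), end = GenomicRanges::end(r),
      strand = strand,
      ltr5_start = l5[1], ltr5_end = l5[2], ltr3_start = l3[1], ltr3_end = l3[2],
      ltr_identity = NA_real_, superfamily = "unknown",
      insertion_time_years = NA_real_,
      family_id = NA_character_, clade = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty_elements()
  rownames(out) <- NULL
  attr(out, "skipped") <- n_skipped
  out
}

#' Read and write FASTA files
#'
#' `read_fasta()` returns a named character vector of uppercased sequences
#' (IUPAC ambiguity letters preserved); duplicate record ids are an error.
#' `write_fasta()` writes a named character vector; the two functions
#' round-trip.
#'
#' @param path File path.
#' @param records Named character vector of sequences.
#' @param width Line width for sequence wrapping.
#' @return `read_fasta()`: named character vector. `write_fasta()`: the
#'   path, invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate FASTA id: %s", dup[1]), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(!is.null(names(records)), all(nzchar(names(records))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a RepeatMasker .out hit table
#'
#' Parses the whitespace-delimited RepeatMasker \code{.out} dialect with its
#' three header lines. Query coordinates are 1-based inclusive; a strand
#' field of \code{C} denotes the minus strand; the matching-repeat column
#' supplies \code{family_id} with any \code{#class} suffix stripped.
#'
#' @param path Path to a \code{.out} file.
#' @return A data frame of hits with columns \code{chrom}, \code{start},
#'   \code{end}, \code{family_id}, \code{score_or_divergence},
#'   \code{strand}.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # dialect: 2 header lines + 1 blank before data rows
  body <- lines[-seq_len(min(3L, length(lines)))]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(empty_hits())
  rows <- lapply(seq_along(body), function(i) {
    fields <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(fields) < 10) {
      stop(sprintf("line %d of %s has %d fields (expected >= 10)",
                   i + 3L, path, length(fields)), call. = FALSE)
    }
    strand <- if (fields[9] %in% c("C", "-")) "-" else "+"
    data.frame(
      chrom = fields[5],
      start = as.integer(fields[6]), end = as.integer(fields[7]),
      family_id = sub("#.*$", "", fields[10]),
      score_or_divergence = suppressWarnings(as.numeric(fields[2])),
      strand = strand, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             family_id = character(), score_or_divergence = numeric(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Read RNA-seq alignments from a SAM text file
#'
#' Reads a SAM file (text only) and computes the reference span of each
#' record from its CIGAR: M, =, X and D consume reference; I, S, H and P do
#' not; N splits the span. Secondary (0x100) and supplementary (0x800)
#' records are flagged \code{is_secondary}. The mapped-fragment total
#' counts distinct read names with at least one mapped primary record, so a
#' read pair counts as one fragment.
#'
#' @param path Path to a SAM file.
#' @return A list with elements \code{alignments} (data frame with columns
#'   \code{read_id}, \code{chrom}, \code{start}, \code{is_mapped},
#'   \code{is_secondary}, \code{span_width}, and list-column \code{span}
#'   holding an [IRanges::IRanges] per record), \code{total_mapped_fragments},
#'   and \code{seq_lengths} (named vector from \code{@SQ} header lines).
#' @export
read_sam_alignments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]

  seq_lengths <- integer(0)
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq)) {
    sn <- sub("^.*\\bSN:([^\t]+).*$", "\\1", sq)
    ln <- as.integer(sub("^.*\\bLN:(\\d+).*$", "\\1", sq))
    seq_lengths <- stats::setNames(ln, sn)
  }

  if (!length(body)) {
    return(list(alignments = data.frame(read_id = character(), chrom = character(),
                                        start = integer(), is_mapped = logical(),
                                        is_secondary = logical(), span_width = integer()),
                total_mapped_fragments = 0L, seq_lengths = seq_lengths))
  }

  fields <- strsplit(body, "\t")
  read_id <- vapply(fields, `[`, character(1), 1L)
  flag <- as.integer(vapply(fields, `[`, character(1), 2L))
  chrom <- vapply(fields, `[`, character(1), 3L)
  start <- as.integer(vapply(fields, `[`, character(1), 4L))
  cigar <- vapply(fields, `[`, character(1), 6L)
  seqs <- vapply(fields, `[`, character(1), 10L)

  is_mapped <- bitwAnd(flag, 4L) == 0L
  is_secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L

  # CIGAR length must agree with SEQ when both are present
  has_cigar <- is_mapped & cigar != "*"
  qlen <- rep(NA_integer_, length(body))
  if (any(has_cigar)) {
    qlen[has_cigar] <- GenomicAlignments::cigarWidthAlongQuerySpace(
      cigar[has_cigar], after.soft.clipping = FALSE)
  }
  bad <- has_cigar & seqs != "*" & nchar(seqs) != qlen
  if (any(bad)) {
    stop(sprintf("CIGAR/sequence length mismatch for read '%s'",
                 read_id[which(bad)[1]]), call. = FALSE)
  }

  span <- vector("list", length(body))
  empty <- IRanges::IRanges()
  for (i in seq_along(body)) span[[i]] <- empty
  if (any(has_cigar)) {
    rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar[has_cigar], pos = start[has_cigar],
      ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
    span[which(has_cigar)] <- as.list(rl)
  }
  span_width <- vapply(span, function(r) sum(IRanges::width(r)), integer(1))

  aln <- data.frame(read_id = read_id, chrom = chrom, start = start,
                    is_mapped = is_mapped, is_secondary = is_secondary,
                    span_width = span_width, stringsAsFactors = FALSE)
  aln$span <- span

  total <- length(unique(read_id[is_mapped & !is_secondary]))
  list(alignments = aln, total_mapped_fragments = total, seq_lengths = seq_lengths)
}
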