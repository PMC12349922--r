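#' Deterministic synthetic LTR-RT genome fixture
#'
#' Builds a small random genome with planted intact LTR retrotransposons
#' and writes (optionally) every upstream input the pipeline consumes:
#' genome FASTA, a pass.list summary table, its GFF3, and a ground-truth
#' table. Per family an ancestral element (two identical LTRs flanking an
#' internal region) is generated; each copy diverges from the ancestor by
#' per-base substitution at \code{sub_rate}, and its two LTRs then
#' diverge from each other independently at a per-copy "age" rate drawn
#' uniformly in \code{[0, sub_rate]}, so the measured inter-LTR identity
#' varies across copies the way insertion ages do in real genomes. With
#' \code{sub_rate = 0} every copy is identical to its ancestor.
#' Substitution-only by default; \code{indel_rate > 0} additionally
#' applies small 1-3 bp indels (restricted to the internal region so LTR
#' coordinates stay exact).
#'
#' All randomness derives from \code{seed} via one private RNG stream, so
#' regeneration is byte-identical and independent of the caller's RNG
#' state.
#'
#' @param n_families Number of planted families.
#' @param copies_per_family Copies per family.
#' @param ltr_len LTR length (bp, default 400).
#' @param internal_len Internal-region length (bp, default 3000).
#' @param sub_rate Per-base substitution rate per copy (default 0.05).
#' @param indel_rate Per-copy probability of a small internal indel
#'   (default 0).
#' @param gap_len Background gap between planted elements (default 300 bp).
#' @param seed Integer seed.
#' @param dir Optional output directory; when given,
#'   \code{genome.fa}, \code{pass.list}, \code{pass.list.gff3} and
#'   \code{truth.csv} are written there.
#' @return List with \code{genome} (named character vector),
#'   \code{elements} (element table in [read_pass_list()] layout plus a
#'   \code{true_family} column), \code{element_seqs} (named character
#'   vector of full element sequences) and, when \code{dir} is given,
#'   \code{paths}.
#' @export
make_toy_genome <- function(n_families = 4, copies_per_family = 10,
                            ltr_len = 400L, internal_len = 3000L,
                            sub_rate = 0.05, indel_rate = 0,
                            gap_len = 300L, seed = 1L, dir = NULL) {
  stopifnot(n_families >= 1, copies_per_family >= 1, ltr_len >= 50,
            internal_len >= 0)
  rng <- local_rng(seed)

  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  mutate <- function(s, rate) {
    if (rate <= 0) return(s)
    v <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(v)) < rate)
    if (length(hit)) {
      v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1),
                       character(1))
    }
    paste(v, collapse = "")
  }

  anc_ltr <- replicate(n_families, rand_seq(ltr_len))
  anc_int <- replicate(n_families, rand_seq(internal_len))

  rows <- list()
  seqs <- character(0)
  chunks <- character(0)
  pos <- 0L
  eid <- 0L
  for (f in seq_len(n_families)) {
    for (cp in seq_len(copies_per_family)) {
      eid <- eid + 1L
      ltr_base <- mutate(anc_ltr[f], sub_rate)
      internal <- mutate(anc_int[f], sub_rate)
      age <- stats::runif(1)
      ltr5 <- mutate(ltr_base, age * sub_rate)
      ltr3 <- mutate(ltr_base, age * sub_rate)
      if (indel_rate > 0 && stats::runif(1) < indel_rate && nchar(internal) > 10) {
        at <- sample(nchar(internal) - 4L, 1)
        if (stats::runif(1) < 0.5) {
          internal <- paste0(substr(internal, 1, at),
                             substr(internal, at + sample(3L, 1) + 1L,
                                    nchar(internal)))
        } else {
          internal <- paste0(substr(internal, 1, at), rand_seq(sample(3L, 1)),
                             substr(internal, at + 1L, nchar(internal)))
        }
      }
      el <- paste0(ltr5, internal, ltr3)
      gap <- rand_seq(gap_len)
      start <- pos + gap_len + 1L
      end <- start + nchar(el) - 1L
      chunks <- c(chunks, gap, el)
      pos <- end

      ident <- hamming_identity(ltr5, ltr3)
      rows[[eid]] <- data.frame(
        element_id = sprintf("LTRRT_%d", eid), chrom = "chr1",
        start = start, end = end, strand = "+",
        ltr5_start = start, ltr5_end = start + ltr_len - 1L,
        ltr3_start = end - ltr_len + 1L, ltr3_end = end,
        ltr_identity = ident,
        superfamily = if (f %% 2 == 1) "Copia" else "Gypsy",
        insertion_time_years = round(insertion_time_mya(ident) * 1e6),
        family_id = NA_character_, clade = NA_character_,
        true_family = sprintf("TRUEFAM_%d", f),
        stringsAsFactors = FALSE
      )
      seqs[sprintf("LTRRT_%d", eid)] <- el
    }
  }
  chunks <- c(chunks, rand_seq(gap_len))
  genome <- c(chr1 = paste(chunks, collapse = ""))
  elements <- do.call(rbind, rows)
  rownames(elements) <- NULL

  out <- list(genome = genome, elements = elements, element_seqs = seqs,
              seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      pass_list = file.path(dir, "pass.list"),
      gff3 = file.path(dir, "pass.list.gff3"),
      truth = file.path(dir, "truth.csv")
    )
    write_fasta(genome, paths$genome)
    write_pass_list(elements, paths$pass_list)
    write_pass_gff3(elements, paths$gff3)
    utils::write.csv(elements[, c("element_id", "true_family", "ltr_identity")],
                     paths$truth, row.names = FALSE, quote = FALSE)
    out$paths <- paths
  }
  out
}

hamming_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  mean(va == vb)
}

# private RNG stream: seed deterministically, restore caller RNG on exit
local_rng <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  restore <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(seed)
  invisible(seed)
}

#' Write elements as an LTR_retriever-style pass.list
#'
#' @param elements Element table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pass_list <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#LTR_loc", "Category", "Motif", "TSD", "5_TSD", "3_TSD",
                   "Internal", "Identity", "Strand", "SuperFamily", "TE_type",
                   "Insertion_Time", sep = "\t"), con)
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    internal <- if (!is.na(e$ltr5_end)) {
      sprintf("IN:%d..%d", e$ltr5_end + 1L, e$ltr3_start - 1L)
    } else "NA"
    writeLines(paste(sprintf("%s:%d..%d", e$chrom, e$start, e$end), "pass",
                     "motif:TGCA", "TSD:NA", "NA", "NA", internal,
                     sprintf("%.4f", e$ltr_identity), e$strand, e$superfamily,
                     "LTR",
                     if (is.na(e$insertion_time_years)) "NA" else
                       format(e$insertion_time_years, scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write elements as a pass.list-style GFF3
#'
#' @param elements Element table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pass_gff3 <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    strand <- if (e$strand %in% c("+", "-")) e$strand else "."
    writeLines(sprintf("%s\tltrfam\trepeat_region\t%d\t%d\t.\t%s\t.\tID=%s",
                       e$chrom, e$start, e$end, strand, e$element_id), con)
    if (!is.na(e$ltr5_start)) {
      writeLines(sprintf(
        "%s\tltrfam\tlong_terminal_repeat\t%d\t%d\t.\t%s\t.\tParent=%s",
        e$chrom, e$ltr5_start, e$ltr5_end, strand, e$element_id), con)
      writeLines(sprintf(
        "%s\tltrfam\tlong_terminal_repeat\t%d\t%d\t.\t%s\t.\tParent=%s",
        e$chrom, e$ltr3_start, e$ltr3_end, strand, e$element_id), con)
    }
  }
  invisible(path)
}

#' Synthetic clade-tagged marker proteins
#'
#' Random amino-acid marker sequences with REXdb-style
#' \code{MRK<i>#<clade>} identifiers, for exercising the RT-domain
#' search without a reference database.
#'
#' @param clades Character vector of clade labels.
#' @param markers_per_clade Markers per clade (default 2).
#' @param aa_len Marker length in amino acids (default 150).
#' @param seed Integer seed.
#' @param path Optional FASTA output path.
#' @return Named character vector of proteins.
#' @export
make_marker_proteins <- function(clades, markers_per_clade = 2, aa_len = 150L,
                                 seed = 1L, path = NULL) {
  if (!length(clades)) stop("clade list is empty", call. = FALSE)
  local_rng(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- character(0)
  for (cl in clades) {
    for (i in seq_len(markers_per_clade)) {
      out[sprintf("MRK%d#%s", i, cl)] <-
        paste(sample(aa, aa_len, replace = TRUE), collapse = "")
    }
  }
  if (!is.null(path)) write_fasta(out, path)
  out
}

#' Synthetic clade-marker tree fixture
#'
#' Builds a Newick tree in which each clade is a monophyletic subtree
#' containing its markers (\code{MRK<i>#<clade>}) and its planted query
#' leaves (\code{Q_<clade>_<j>}), with random within-clade topology,
#' random branch lengths and a few unplanted background leaves attached
#' near the root. The truth table records each query's clade.
#'
#' @param clades Character vector of clade labels.
#' @param queries_per_clade Queries planted per clade (default 3).
#' @param markers_per_clade Markers per clade (default 2).
#' @param n_background Background leaves outside every clade subtree
#'   (default 2).
#' @param seed Integer seed.
#' @param path Optional output path for the Newick text.
#' @return List with \code{newick} (string), \code{truth} (data frame
#'   \code{query_label}, \code{clade}) and optionally \code{path}.
#' @export
make_marker_tree <- function(clades, queries_per_clade = 3,
                             markers_per_clade = 2, n_background = 2,
                             seed = 1L, path = NULL) {
  if (!length(clades)) stop("clade list is empty", call. = FALSE)
  local_rng(seed)

  join_random <- function(leaves) {
    # random sequential pairing into a binary subtree
    parts <- as.list(leaves)
    while (length(parts) > 1) {
      i <- sample(length(parts), 2)
      merged <- sprintf("(%s:%.3f,%s:%.3f)", parts[[i[1]]], stats::runif(1, 0.01, 0.5),
                        parts[[i[2]]], stats::runif(1, 0.01, 0.5))
      parts <- c(parts[-i], merged)
    }
    parts[[1]]
  }

  subtrees <- character(0)
  truth <- list()
  for (cl in clades) {
    markers <- sprintf("MRK%d#%s", seq_len(markers_per_clade), cl)
    queries <- if (queries_per_clade > 0) {
      sprintf("Q_%s_%d", cl, seq_len(queries_per_clade))
    } else character(0)
    subtrees <- c(subtrees, join_random(c(markers, queries)))
    if (length(queries)) {
      truth[[cl]] <- data.frame(query_label = queries, clade = cl,
                                stringsAsFactors = FALSE)
    }
  }
  background <- if (n_background > 0) sprintf("BG%d", seq_len(n_background)) else
    character(0)
  newick <- paste0("(", paste(c(subtrees, background), collapse = ","), ");")
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(query_label = character(), clade = character(),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  out <- list(newick = newick, truth = truth)
  if (!is.null(path)) {
    writeLines(newick, path)
    out$path <- path
  }
  out
}

#' Simulate RNA-seq reads from planted elements as SAM text
#'
#' Draws single-end reads uniformly within their source element and
#' emits SAM records with \code{@SQ} header lines. A read whose source
#' element has near-identical partners (full-sequence identity >=
#' \code{multimap_identity} within the same true family, equal length)
#' is a multimapper: it gets one primary record at its true locus and
#' secondary records (flag 0x100) at the same offset in every partner.
#' Optionally adds background reads mapping outside every element, which
#' count toward the mapped total but toward no element.
#'
#' @param fixture Result of [make_toy_genome()].
#' @param abundances Named integer vector: fragments per element id
#'   (elements absent get 0).
#' @param read_len Read length (default 100).
#' @param n_background Background reads from inter-element gaps
#'   (default 0).
#' @param multimap_identity Identity above which two copies are
#'   near-identical (default 0.98).
#' @param seed Integer seed.
#' @param path Optional output path for the SAM text.
#' @return List with \code{sam} (character vector of lines),
#'   \code{truth} (named vector of true per-element fragment counts) and
#'   optionally \code{path}.
#' @export
simulate_reads <- function(fixture, abundances, read_len = 100L,
                           n_background = 0L, multimap_identity = 0.98,
                           seed = 1L, path = NULL) {
  unknown <- setdiff(names(abundances), fixture$elements$element_id)
  if (length(unknown)) {
    stop(sprintf("abundance given for unknown element '%s'", unknown[1]),
         call. = FALSE)
  }
  local_rng(seed)
  el <- fixture$elements
  genome <- fixture$genome

  # near-identical partners: same true family, equal length, high identity
  partners <- lapply(seq_len(nrow(el)), function(i) {
    same <- which(el$true_family == el$true_family[i] &
                    seq_len(nrow(el)) != i &
                    (el$end - el$start) == (el$end[i] - el$start[i]))
    same[vapply(same, function(j) {
      hamming_identity(fixture$element_seqs[[el$element_id[i]]],
                       fixture$element_seqs[[el$element_id[j]]]) >=
        multimap_identity
    }, logical(1))]
  })

  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  records <- list()
  truth <- stats::setNames(rep(0L, nrow(el)), el$element_id)
  rid <- 0L
  for (i in seq_len(nrow(el))) {
    n <- abundances[el$element_id[i]]
    if (is.na(n) || n == 0) next
    truth[i] <- as.integer(n)
    span <- el$end[i] - el$start[i] + 1L
    stopifnot(span >= read_len)
    for (r in seq_len(n)) {
      rid <- rid + 1L
      off <- sample(span - read_len + 1L, 1) - 1L
      pos <- el$start[i] + off
      seq <- substr(genome[[el$chrom[i]]], pos, pos + read_len - 1L)
      name <- sprintf("read_%d", rid)
      records[[length(records) + 1]] <- sam_line(name, 0L, el$chrom[i], pos,
                                                 read_len, seq)
      for (j in partners[[i]]) {
        records[[length(records) + 1]] <- sam_line(name, 256L, el$chrom[j],
                                                   el$start[j] + off, read_len,
                                                   "*")
      }
    }
  }
  if (n_background > 0) {
    # place background reads in the leading gap before the first element
    first <- min(el$start)
    stopifnot(first > read_len)
    for (r in seq_len(n_background)) {
      rid <- rid + 1L
      pos <- sample(first - read_len, 1)
      seq <- substr(genome[[1]], pos, pos + read_len - 1L)
      records[[length(records) + 1]] <- sam_line(sprintf("read_%d", rid), 0L,
                                                 names(genome)[1], pos,
                                                 read_len, seq)
    }
  }
  sam <- c(lines, unlist(records))
  out <- list(sam = sam, truth = truth)
  if (!is.null(path)) {
    writeLines(sam, path)
    out$path <- path
  }
  out
}

sam_line <- function(name, flag, chrom, pos, read_len, seq) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*", name, flag, chrom, pos,
          if (flag == 256L) 0L else 60L, read_len, seq)
}
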