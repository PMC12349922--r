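# Independent brute-force oracles. These deliberately share no code with
# the package: the DP is written out in full, the genetic code is typed in
# by hand, tree overlaps come from parent-pointer ancestor chains, and
# coverage from per-base boolean masks.

# --- Smith-Waterman with affine gaps (Gotoh), full traceback ------------
# Convention: a gap of length L costs gap_open + L * gap_ext.
sw_oracle <- function(a, b, match = 2, mismatch = -3, gap_open = 5, gap_ext = 2) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      s <- if (va[i - 1] == vb[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
    }
  }
  if (best <= 0) {
    return(list(score = 0, matches = 0, cols = 0, a_span = 0, b_span = 0))
  }
  # traceback
  i <- bi; j <- bj; state <- "H"
  matches <- 0; cols <- 0; a_used <- 0; b_used <- 0
  while (TRUE) {
    if (state == "H") {
      if (H[i, j] == 0) break
      s <- if (va[i - 1] == vb[j - 1]) match else mismatch
      if (i > 1 && j > 1 && H[i, j] == H[i - 1, j - 1] + s) {
        cols <- cols + 1; a_used <- a_used + 1; b_used <- b_used + 1
        if (va[i - 1] == vb[j - 1]) matches <- matches + 1
        i <- i - 1; j <- j - 1
      } else if (H[i, j] == E[i, j]) {
        state <- "E"
      } else if (H[i, j] == F[i, j]) {
        state <- "F"
      } else stop("oracle traceback failure")
    } else if (state == "E") {
      cols <- cols + 1; b_used <- b_used + 1
      if (E[i, j] == H[i, j - 1] - gap_open - gap_ext) {
        j <- j - 1; state <- "H"
      } else {
        j <- j - 1; state <- "E"
      }
    } else {
      cols <- cols + 1; a_used <- a_used + 1
      if (F[i, j] == H[i - 1, j] - gap_open - gap_ext) {
        i <- i - 1; state <- "H"
      } else {
        i <- i - 1; state <- "F"
      }
    }
  }
  list(score = best, matches = matches, cols = cols,
       a_span = a_used, b_span = b_used)
}

# --- six-frame ORF scan with a hand-typed genetic code ------------------
.oracle_codons <- local({
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",  # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  codons <- paste0(g$b1, g$b2, g$b3)  # third base varies fastest
  stats::setNames(aa, codons)
})

oracle_translate <- function(s) {
  n <- nchar(s) %/% 3
  if (n == 0) return("")
  cod <- substring(s, seq(1, by = 3, length.out = n), seq(3, by = 3, length.out = n))
  aa <- .oracle_codons[cod]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
}

orf_oracle <- function(seq, min_aa = 100L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  rc <- oracle_revcomp(seq)
  best <- NULL
  for (fr in list(c(1, 0), c(1, 1), c(1, 2), c(-1, 0), c(-1, 1), c(-1, 2))) {
    dir <- fr[1]; off <- fr[2]
    s <- if (dir > 0) seq else rc
    prot <- oracle_translate(substr(s, off + 1, n))
    chars <- strsplit(prot, "")[[1]]
    i <- 1
    while (i <= length(chars)) {
      if (chars[i] == "M") {
        stop_at <- NA
        for (j in i:length(chars)) if (chars[j] == "*") { stop_at <- j; break }
        if (!is.na(stop_at)) {
          len <- stop_at - i
          if (is.null(best) || len > best$aa_len) {
            cs <- off + (i - 1) * 3 + 1
            ce <- cs + len * 3 - 1
            best <- list(
              frame = dir * (off + 1),
              nt_start = if (dir > 0) cs else n - ce + 1,
              nt_end = if (dir > 0) ce else n - cs + 1,
              protein = paste(chars[i:(stop_at - 1)], collapse = ""),
              aa_len = len
            )
          }
          i <- stop_at + 1
          next
        }
      }
      i <- i + 1
    }
  }
  if (is.null(best) || best$aa_len < min_aa) return(NULL)
  best$aa_len <- NULL
  best
}

# --- per-base boolean-mask coverage oracle ------------------------------
coverage_oracle <- function(hits, genome_sizes) {
  masks <- lapply(genome_sizes, function(n) logical(n))
  fam_cov <- list()
  for (f in unique(hits$family_id)) {
    fm <- lapply(genome_sizes, function(n) logical(n))
    h <- hits[hits$family_id == f, ]
    for (i in seq_len(nrow(h))) {
      idx <- h$start[i]:h$end[i]
      fm[[h$chrom[i]]][idx] <- TRUE
      masks[[h$chrom[i]]][idx] <- TRUE
    }
    fam_cov[[f]] <- sum(vapply(fm, sum, numeric(1)))
  }
  list(per_family = fam_cov,
       total = sum(vapply(masks, sum, numeric(1))))
}

# --- tree oracles -------------------------------------------------------
# ancestor chain (root..node) from parent pointers, independent of DFS
oracle_ancestors <- function(tree, v) {
  chain <- v
  while (!is.na(tree$parent[chain[1]])) chain <- c(tree$parent[chain[1]], chain)
  chain
}

# brute-force classification: argmax over (query, marker) shared-ancestor
# counts with the deeper-marker-then-label tie-break
oracle_classify <- function(tree, marker_pattern, min_overlap = 2L) {
  leaves <- which(lengths(tree$children) == 0L)
  lab <- tree$label[leaves]
  is_marker <- nzchar(lab) & !grepl("^[0-9.eE+-]+$", lab) &
    grepl(marker_pattern, lab)
  markers <- leaves[is_marker]
  queries <- leaves[!is_marker]
  manc <- lapply(markers, oracle_ancestors, tree = tree)
  mdep <- lengths(manc)
  mlab <- tree$label[markers]
  # ancestor-set membership matrix: nodes x markers
  amat <- matrix(FALSE, nrow = tree$n, ncol = length(markers))
  for (k in seq_along(markers)) amat[manc[[k]], k] <- TRUE
  rows <- lapply(queries, function(q) {
    qa <- oracle_ancestors(tree, q)
    # shared-ancestor count per marker (root-anchored chains, so this is
    # exactly the MRCA depth + 1)
    ov <- as.integer(colSums(amat[qa, , drop = FALSE]))
    ord <- order(-ov, -mdep, mlab)
    b <- ord[1]
    if (ov[b] < min_overlap) {
      data.frame(query_label = tree$label[q], clade = "unclassified",
                 overlap = ov[b], winning_marker = "", stringsAsFactors = FALSE)
    } else {
      data.frame(query_label = tree$label[q], clade = sub("^.*#", "", mlab[b]),
                 overlap = ov[b], winning_marker = mlab[b],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$query_label), ]
}
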