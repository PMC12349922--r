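CLADE_VOCAB <- c("Ale", "Tork", "Ikeros", "TAR", "Ivana", "SIRE",
                 "Galadriel", "Reina", "CRM", "Tekay", "Athila")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
  }
  paste(v, collapse = "")
}

hamming_id <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  mean(va == vb)
}

# random binary tree over the given leaf labels, with branch lengths
random_newick <- function(leaf_labels) {
  parts <- as.list(leaf_labels)
  while (length(parts) > 1) {
    i <- sample(length(parts), 2)
    parts <- c(parts[-i],
               sprintf("(%s:%.3f,%s:%.3f)", parts[[i[1]]], runif(1, 0.01, 1),
                       parts[[i[2]]], runif(1, 0.01, 1)))
  }
  paste0(parts[[1]], ";")
}

# random tree mixing marker and query leaves, markers tagged from the vocab
random_marker_newick <- function(n_leaves, marker_frac = 0.5) {
  n_mark <- max(1L, round(n_leaves * marker_frac))
  labels <- c(sprintf("M%d#%s", seq_len(n_mark),
                      sample(CLADE_VOCAB, n_mark, replace = TRUE)),
              sprintf("Q%d", seq_len(n_leaves - n_mark)))
  random_newick(sample(labels))
}

# connected components of the >= threshold identity graph (equal-length,
# substitution-only sequences, so identity is plain hamming identity)
hamming_components <- function(seqs, threshold = 0.8) {
  n <- length(seqs)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in seq_len(n)) {
        if (is.na(comp[w]) && hamming_id(seqs[[v]], seqs[[w]]) >= threshold) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  split(names(seqs), comp)
}
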