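Package: ltrfam
Title: Characterization of Plant LTR Retrotransposon Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes intact long terminal repeat retrotransposons
    (LTR-RTs) predicted by LTR_retriever-style tools. Clusters elements
    into families from their 5'-LTR sequences with greedy incremental
    clustering at an identity threshold, summarizes per-family copy
    number and merged genome coverage, extracts reverse-transcriptase
    domains from the longest open reading frames, assigns elements to
    REXdb-style clades by a depth-first path-overlap algorithm on a
    phylogenetic tree, quantifies per-locus expression from RNA-seq
    alignments with EM reassignment of multimapping fragments (FPKM),
    and merges everything into a single family-level report including
    insertion-time estimates from LTR divergence. A deterministic
    synthetic-fixture generator produces every input format the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
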