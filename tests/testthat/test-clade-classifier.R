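test_that("newick parsing handles basic, support-value and quoted dialects", {
  t1 <- parse_newick("(A,B);")
  leaves <- which(lengths(t1$children) == 0)
  expect_equal(sort(t1$label[leaves]), c("A", "B"))
  expect_equal(t1$n, 3)

  t2 <- parse_newick("((A:0.1,B:0.2)0.95:0.3,C);")
  internal <- which(lengths(t2$children) > 0 & !is.na(t2$parent))
  expect_equal(t2$label[internal], "0.95")
  expect_equal(t2$branch_length[internal], 0.3)
  expect_equal(sum(lengths(t2$children) == 0), 3)
  a <- which(t2$label == "A")
  expect_equal(t2$branch_length[a], 0.1)

  t3 <- parse_newick("('a leaf, quoted':1,B);")
  expect_true("a leaf, quoted" %in% t3$label)

  expect_error(parse_newick("((A,B);"), "character")
  expect_error(parse_newick("(A,B)"), "missing terminating ';'")
})

test_that("parse/serialize round-trips topology against the ape oracle", {
  skip_if_not_installed("ape")
  set.seed(71)
  for (i in 1:25) {
    nwk <- random_newick(sprintf("L%d", seq_len(sample(4:60, 1))))
    mine <- serialize_newick(parse_newick(nwk))
    ref1 <- ape::read.tree(text = nwk)
    ref2 <- ape::read.tree(text = mine)
    expect_true(ape::all.equal.phylo(ref1, ref2, use.edge.length = FALSE))
    expect_setequal(ref1$tip.label, ref2$tip.label)
  }
})

test_that("marker paths are root-anchored and match parent-pointer walk-ups", {
  tr <- parse_newick("((M1#Ale,Q1),(M2#Tekay,Q2));")
  paths <- collect_label_paths(tr)
  expect_equal(sort(names(paths)), c("M1#Ale", "M2#Tekay"))
  p <- paths[["M1#Ale"]]
  expect_equal(length(p), 3)
  expect_equal(p[1], tr$root)
  expect_equal(tr$label[p[3]], "M1#Ale")
  expect_equal(p, oracle_ancestors(tr, p[length(p)]))

  # marker directly under the root
  tr2 <- parse_newick("(M1#Ale,(Q1,Q2));")
  expect_equal(length(collect_label_paths(tr2)[["M1#Ale"]]), 2)

  expect_error(collect_label_paths(parse_newick("(A,B);")), "no marker")

  set.seed(72)
  for (i in 1:10) {
    tr3 <- parse_newick(random_marker_newick(sample(20:200, 1)))
    paths3 <- collect_label_paths(tr3)
    for (lab in names(paths3)) {
      leaf <- paths3[[lab]][length(paths3[[lab]])]
      expect_equal(paths3[[lab]], oracle_ancestors(tr3, leaf))
    }
  }
})

test_that("overlap classification follows the prefix rule and tie-breaks", {
  tr <- parse_newick("((M1#Ale,Q1),(M2#Tekay,Q2));")
  res <- classify_tree(tr)
  expect_equal(res$query_label, c("Q1", "Q2"))
  expect_equal(res$clade, c("Ale", "Tekay"))
  expect_equal(res$overlap, c(2L, 2L))

  # a marker classified as a query resolves to itself
  paths <- collect_label_paths(tr)
  self <- classify_node(paths[["M1#Ale"]], paths, query_label = "M1#Ale")
  expect_equal(self$clade, "Ale")
  expect_equal(self$overlap, length(paths[["M1#Ale"]]))

  # star topology: root-only overlap is unclassified
  star <- classify_tree("(M1#Ale,M2#Tekay,Q1);")
  expect_equal(star$clade, "unclassified")
  expect_equal(star$overlap, 1L)

  # all-marker tree yields an empty assignment table
  expect_equal(nrow(classify_tree("(M1#Ale,M2#Tekay);")), 0)
})

test_that("classification equals the brute-force MRCA oracle on random trees", {
  set.seed(73)
  pat <- default_marker_pattern()
  for (i in 1:30) {
    tr <- parse_newick(random_marker_newick(sample(10:150, 1)))
    got <- classify_tree(tr, marker_pattern = pat)
    got <- got[order(got$query_label), ]
    rownames(got) <- NULL
    orc <- oracle_classify(tr, pat)
    rownames(orc) <- NULL
    expect_equal(got, orc)
  }
})

test_that("queries planted in monophyletic clades are always recovered", {
  fix <- make_marker_tree(c("Ale", "SIRE", "Tekay"), queries_per_clade = 4,
                          seed = 9)
  res <- classify_tree(fix$newick)
  res <- res[res$query_label %in% fix$truth$query_label, ]
  expect_equal(nrow(res), nrow(fix$truth))
  expect_equal(res$clade[match(fix$truth$query_label, res$query_label)],
               fix$truth$clade)
})

test_that("classification output is byte-deterministic CSV", {
  fix <- make_marker_tree(c("Ale", "CRM"), queries_per_clade = 3, seed = 4)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  classify_tree(fix$newick, csv = f1)
  classify_tree(fix$newick, csv = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("deep caterpillar trees traverse without recursion failure", {
  n <- 10000
  nwk <- paste0(strrep("(", n), "M1#Ale",
                paste(sprintf(",Q%d)", seq_len(n)), collapse = ""), ";")
  tr <- parse_newick(nwk)
  expect_equal(tr$n, 2 * n + 1)
  paths <- collect_label_paths(tr)
  expect_equal(length(paths[["M1#Ale"]]), n + 1)
  res <- classify_tree(tr)
  expect_equal(nrow(res), n)
  # the query nested deepest alongside the marker shares the longest path
  expect_equal(max(res$overlap), n)
})
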