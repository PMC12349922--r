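sam_from_lines <- function(lines) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, f)
  read_sam_alignments(f)
}

two_element_annot <- function() {
  data.frame(element_id = c("E1", "E2"), chrom = "chr1",
             start = c(1001L, 5001L), end = c(2000L, 6000L), strand = "+",
             ltr5_start = NA_integer_, ltr5_end = NA_integer_,
             ltr3_start = NA_integer_, ltr3_end = NA_integer_,
             ltr_identity = NA_real_, superfamily = "unknown",
             insertion_time_years = NA_real_, family_id = NA_character_,
             clade = NA_character_, stringsAsFactors = FALSE)
}

rec <- function(name, pos, flag = 0, cigar = "100M", chrom = "chr1") {
  paste(name, flag, chrom, pos, if (flag == 256) 0 else 60, cigar, "*", 0, 0,
        if (flag == 256) "*" else strrep("A", 100), "*", sep = "\t")
}

hdr <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000")

test_that("compatibility follows the 50% aligned-span rule", {
  el <- two_element_annot()
  sam <- sam_from_lines(c(hdr,
    rec("inside", 1200),          # fully inside E1
    rec("edge30", 931),           # 30 bp inside E1 -> not compatible
    rec("edge50", 951),           # exactly 50 bp inside -> compatible
    rec("nowhere", 3000)))        # between elements
  comp <- assign_fragments(sam, el)
  expect_equal(comp$pairs$read_id, c("edge50", "inside"))
  expect_equal(comp$pairs$element_id, c("E1", "E1"))
  # incompatible fragments still count toward the mapped total
  expect_equal(comp$total_mapped_fragments, 4)
})

test_that("multimapper records make fragments multiply compatible", {
  el <- two_element_annot()
  sam <- sam_from_lines(c(hdr,
    rec("mm", 1200),
    rec("mm", 5200, flag = 256)))
  comp <- assign_fragments(sam, el)
  expect_equal(comp$pairs$element_id[comp$pairs$read_id == "mm"], c("E1", "E2"))
  expect_equal(comp$total_mapped_fragments, 1)
  expect_equal(unname(comp$unique_counts), c(0, 0))
})

test_that("EM equals unique counting when nothing is ambiguous", {
  pairs <- data.frame(read_id = sprintf("r%d", 1:10),
                      element_id = rep(c("E1", "E2"), c(7, 3)),
                      stringsAsFactors = FALSE)
  counts <- em_reassign(pairs, c(E1 = 1000, E2 = 1000))
  expect_equal(unname(counts[c("E1", "E2")]), c(7, 3))
  expect_equal(attr(counts, "iterations"), 1L)
})

test_that("EM drains ambiguous mass toward the only supported element", {
  pairs <- rbind(
    data.frame(read_id = sprintf("u%d", 1:10), element_id = "E1"),
    data.frame(read_id = rep(sprintf("a%d", 1:10), each = 2),
               element_id = rep(c("E1", "E2"), 10))
  )
  counts <- em_reassign(pairs, c(E1 = 1000, E2 = 1000), max_iter = 500)
  expect_equal(unname(counts["E1"]), 20, tolerance = 1e-3)
  expect_lt(unname(counts["E2"]), 0.01)
  # conservation at every iteration
  expect_true(all(abs(attr(counts, "sum_trace") - 20) < 1e-9))
})

test_that("EM splits symmetric ambiguity evenly", {
  pairs <- rbind(
    data.frame(read_id = sprintf("u%d", 1:5), element_id = "E1"),
    data.frame(read_id = sprintf("v%d", 1:5), element_id = "E2"),
    data.frame(read_id = rep(sprintf("a%d", 1:10), each = 2),
               element_id = rep(c("E1", "E2"), 10))
  )
  counts <- em_reassign(pairs, c(E1 = 1000, E2 = 1000))
  expect_equal(unname(counts["E1"]), unname(counts["E2"]))
  expect_equal(sum(counts), 20)
})

test_that("FPKM obeys its closed formula and scale properties", {
  tab <- compute_fpkm(c(E1 = 10), c(E1 = 1000), 1e6)
  expect_equal(tab$fpkm, 10)
  expect_true(tab$expressed)

  tab0 <- compute_fpkm(c(E1 = 0), c(E1 = 1000), 1e6)
  expect_equal(tab0$fpkm, 0)
  expect_false(tab0$expressed)

  t1 <- compute_fpkm(c(a = 3, b = 8), c(a = 500, b = 2000), 1e6)
  t2 <- compute_fpkm(c(a = 3, b = 8), c(a = 500, b = 2000), 2e6)
  expect_equal(t1$fpkm / t2$fpkm, c(2, 2))

  expect_error(compute_fpkm(c(E1 = 1), c(E1 = 0), 1e6), "zero-length")
  expect_error(compute_fpkm(c(E1 = 1), c(E1 = 100), 0))
})

test_that("without multimappers the pipeline equals naive unique counting", {
  fx <- make_toy_genome(3, 4, sub_rate = 0.08, seed = 19)
  el <- fx$elements
  ab <- setNames(sample(0:8, nrow(el), replace = TRUE), el$element_id)
  sim <- simulate_reads(fx, ab, seed = 20)
  sam <- sam_from_lines(sim$sam)
  expect_false(any(sam$alignments$is_secondary))  # 8% divergence: no multimap
  tab <- quantify_expression(sam, el)
  expect_equal(setNames(tab$raw_fragments, tab$element_id)[names(ab)],
               setNames(as.numeric(ab), names(ab)))
  expect_equal(tab$raw_fragments, tab$unique_fragments)
})
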