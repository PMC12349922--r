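test_that("pass.list rows map to elements with percent normalization", {
  f <- withr::local_tempfile()
  writeLines(c(
    "#LTR_loc\tCategory\tMotif\tTSD\t5_TSD\t3_TSD\tInternal\tIdentity\tStrand\tSuperFamily\tTE_type\tInsertion_Time",
    "chr1:1000..5999\tpass\tmotif:TGCA\tTSD:ATATA\tNA\tNA\tIN:1400..5599\t0.98\t+\tCopia\tLTR\t379000",
    "chr2:50..800\tpass\tmotif:TGCA\tTSD:NA\tNA\tNA\tIN:250..600\t98.0\t-\tGypsy\tLTR\tNA"
  ), f)
  el <- read_pass_list(f)
  expect_equal(nrow(el), 2)
  expect_equal(el$element_id, c("LTRRT_1", "LTRRT_2"))
  expect_equal(el$chrom[1], "chr1")
  expect_equal(el$start[1], 1000)
  expect_equal(el$end[1], 5999)
  expect_equal(el$ltr_identity, c(0.98, 0.98))  # percent form normalized
  expect_equal(el$ltr5_start[1], 1000)
  expect_equal(el$ltr5_end[1], 1399)
  expect_equal(el$ltr3_start[1], 5600)
  expect_equal(el$superfamily, c("Copia", "Gypsy"))
  expect_equal(el$insertion_time_years[1], 379000)
  expect_true(is.na(el$insertion_time_years[2]))
})

test_that("pass.list comments are skipped, ids are sequential, errors name lines", {
  f <- withr::local_tempfile()
  rows <- sprintf("chr1:%d..%d\tpass\tm\tT\tN\tN\tIN:%d..%d\t0.9\t+\tCopia\tLTR\t100",
                  (1:12) * 1000, (1:12) * 1000 + 500,
                  (1:12) * 1000 + 100, (1:12) * 1000 + 400)
  writeLines(c("# header comment", rows[1:6], "# mid comment", rows[7:12]), f)
  el <- read_pass_list(f)
  expect_equal(nrow(el), 12)
  expect_equal(el$element_id, sprintf("LTRRT_%d", 1:12))

  writeLines(c(rows[1], "not-a-locus\tx\tx"), f)
  expect_error(read_pass_list(f), "malformed locus token.*line 2")

  writeLines(character(0), f)
  expect_equal(nrow(read_pass_list(f)), 0)
})

test_that("gff3 elements reconstruct LTR intervals and agree with pass.list", {
  f <- withr::local_tempfile()
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\trepeat_region\t1000\t5999\t.\t+\t.\tID=LTRRT_1",
    "chr1\tx\tlong_terminal_repeat\t1000\t1399\t.\t+\t.\tParent=LTRRT_1",
    "chr1\tx\tlong_terminal_repeat\t5600\t5999\t.\t+\t.\tParent=LTRRT_1"
  ), f)
  el <- read_gff3_ltr(f)
  expect_equal(nrow(el), 1)
  expect_equal(el$ltr5_start, 1000)
  expect_equal(el$ltr5_end, 1399)
  expect_equal(el$ltr3_start, 5600)
  expect_equal(el$ltr3_end, 5999)

  fx <- make_toy_genome(2, 3, seed = 11, dir = withr::local_tempdir())
  a <- read_pass_list(fx$paths$pass_list)
  b <- read_gff3_ltr(fx$paths$gff3)
  expect_equal(a[, c("chrom", "start", "end")], b[, c("chrom", "start", "end")])
})

test_that("gff3 regions lacking an ID are skipped with a count", {
  f <- withr::local_tempfile()
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\trepeat_region\t100\t500\t.\t+\t.\tID=LTRRT_1",
    "chr1\tx\trepeat_region\t600\t900\t.\t+\t.\tName=anon",
    "chr1\tx\trepeat_region\t1000\t1500\t.\t+\t.\tID=LTRRT_3"
  ), f)
  expect_warning(el <- read_gff3_ltr(f), "lacking an ID")
  expect_equal(nrow(el), 2)
  expect_equal(attr(el, "skipped"), 1)
})

test_that("fasta read/write round-trips, uppercases and rejects duplicates", {
  f <- withr::local_tempfile()
  writeLines(c(">a", "acgt"), f)
  expect_equal(read_fasta(f), c(a = "ACGT"))

  set.seed(42)
  recs <- setNames(replicate(100, random_dna(sample(20:200, 1))),
                   sprintf("seq_%03d", 1:100))
  write_fasta(recs, f)
  expect_identical(read_fasta(f), recs)

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate FASTA id: a")
})

test_that("repeatmasker .out dialect: C strand, #class strip, row errors", {
  f <- withr::local_tempfile()
  hdr <- c("   SW  perc perc perc  query    position in query", "  score  div. del. ins.  sequence  begin end", "")
  row <- function(chrom, s, e, strand, fam) {
    sprintf("  1000  5.0  0.0  0.0  %s  %d  %d  (0)  %s  %s  LTR  1  100  (0)  1",
            chrom, s, e, strand, fam)
  }
  writeLines(c(hdr, row("chr1", 100, 199, "+", "fam1#LTR/Copia"),
               row("chr1", 300, 399, "C", "fam2"),
               row("chr2", 10, 50, "+", "fam1#LTR/Copia"),
               row("chr2", 60, 90, "C", "fam3#LTR"),
               row("chr2", 95, 99, "+", "fam2")), f)
  hits <- read_repeatmasker_out(f)
  expect_equal(nrow(hits), 5)
  expect_equal(hits$strand, c("+", "-", "+", "-", "+"))
  expect_equal(hits$family_id, c("fam1", "fam2", "fam1", "fam3", "fam2"))
  expect_equal(hits$start[1], 100)
  expect_equal(hits$end[1], 199)

  writeLines(c(hdr, "  1000  5.0  chr1"), f)
  expect_error(read_repeatmasker_out(f), "line 4.*fields")
})

test_that("SAM spans follow CIGAR reference-consumption rules", {
  f <- withr::local_tempfile()
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:10000",
    paste("r1", 0, "chr1", 101, 60, "50M", "*", 0, 0, strrep("A", 50), "*", sep = "\t"),
    paste("r2", 0, "chr1", 1, 60, "10M5D10M", "*", 0, 0, strrep("A", 20), "*", sep = "\t"),
    paste("r3", 0, "chr1", 100, 60, "5S20M", "*", 0, 0, strrep("A", 25), "*", sep = "\t"),
    paste("r3", 256, "chr1", 900, 0, "5S20M", "*", 0, 0, "*", "*", sep = "\t"),
    paste("r4", 4, "*", 0, 0, "*", "*", 0, 0, strrep("A", 30), "*", sep = "\t"),
    # paired: two primary mates, one fragment
    paste("r5", 99, "chr1", 200, 60, "30M", "=", 400, 230, strrep("A", 30), "*", sep = "\t"),
    paste("r5", 147, "chr1", 400, 60, "30M", "=", 200, -230, strrep("A", 30), "*", sep = "\t")
  )
  writeLines(sam, f)
  res <- read_sam_alignments(f)
  a <- res$alignments
  expect_equal(res$seq_lengths, c(chr1 = 10000L))
  sp <- function(id) a$span[[which(a$read_id == id & !a$is_secondary)[1]]]
  expect_equal(c(IRanges::start(sp("r1")), IRanges::end(sp("r1"))), c(101, 150))
  expect_equal(c(IRanges::start(sp("r2")), IRanges::end(sp("r2"))), c(1, 25))
  expect_equal(c(IRanges::start(sp("r3")), IRanges::end(sp("r3"))), c(100, 119))
  expect_true(a$is_secondary[a$read_id == "r3" & a$start == 900])
  expect_false(a$is_mapped[a$read_id == "r4"])
  # r1, r2, r3, r5 mapped; r5 pair counts once
  expect_equal(res$total_mapped_fragments, 4)

  writeLines(c("@SQ\tSN:chr1\tLN:100",
               paste("bad", 0, "chr1", 1, 60, "10M", "*", 0, 0, "ACGT", "*", sep = "\t")), f)
  expect_error(read_sam_alignments(f), "CIGAR/sequence length mismatch.*bad")
})
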