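mk_clusters <- function(sizes, cov = NULL) {
  n <- length(sizes)
  data.frame(family_id = sprintf("FAM_%d", seq_len(n)),
             representative_id = sprintf("r%d", seq_len(n)),
             n_members = sizes, copy_number = NA_integer_,
             coverage_bp = if (is.null(cov)) NA_integer_ else cov,
             member_ids = I(lapply(seq_len(n), function(i) sprintf("r%d", i))),
             stringsAsFactors = FALSE)
}

test_that("cumulative curve fractions accumulate to exactly one", {
  curve <- cumulative_cluster_curve(mk_clusters(c(5, 3, 2)))
  expect_equal(curve$cumulative_fraction, c(0.5, 0.8, 1.0))
  expect_equal(curve$rank, 1:3)

  single <- cumulative_cluster_curve(mk_clusters(7))
  expect_equal(single$cumulative_fraction, 1.0)

  set.seed(91)
  sizes <- sample(1:100, 100, replace = TRUE)
  c2 <- cumulative_cluster_curve(mk_clusters(sizes))
  expect_true(all(diff(c2$cumulative_fraction) >= 0))
  expect_identical(c2$cumulative_fraction[100], 1.0)
  # descending sort makes the curve concave: increments non-increasing
  expect_true(all(diff(diff(c2$cumulative_fraction)) <= 1e-12))

  expect_error(cumulative_cluster_curve(mk_clusters(c(0, 0))), "zero")
})

test_that("top-N-for-fraction matches a linear-scan oracle", {
  expect_equal(top_n_for_fraction(cumulative_cluster_curve(mk_clusters(c(5, 3, 2))), 0.5), 1)
  expect_equal(top_n_for_fraction(cumulative_cluster_curve(mk_clusters(rep(1, 10))), 0.5), 5)

  set.seed(92)
  sizes <- round(1000 / seq_len(80)^1.2)  # Zipf-like
  curve <- cumulative_cluster_curve(mk_clusters(sizes))
  expect_equal(top_n_for_fraction(curve, 1.0), 80)
  for (f in c(0.25, 0.5, 0.9)) {
    sorted <- sort(sizes, decreasing = TRUE)
    k <- 0; acc <- 0
    while (acc < f * sum(sorted)) { k <- k + 1; acc <- acc + sorted[k] }
    expect_equal(top_n_for_fraction(curve, f), k)
  }
})

test_that("JC-corrected insertion times follow the closed form", {
  expect_equal(insertion_time_mya(1.0), 0)
  expect_equal(insertion_time_mya(0.99),
               -0.75 * log(1 - (4 / 3) * 0.01) / (2 * 1.3e-8) / 1e6)
  expect_equal(insertion_time_mya(0.99), 0.38720, tolerance = 1e-4)
  # halving mu doubles the age
  expect_equal(insertion_time_mya(0.95, 6.5e-9), 2 * insertion_time_mya(0.95))
  # strictly monotone in divergence
  grid <- insertion_time_mya(seq(0.999, 0.5, by = -0.01))
  expect_true(all(diff(grid) > 0))
  expect_error(insertion_time_mya(0.2), "undefined")
})

test_that("master table is a lossless left join with family summaries", {
  fx <- make_toy_genome(3, 5, seed = 33)
  el <- fx$elements
  ltr5 <- extract_ltr5_sequences(el, fx$genome)
  cl <- greedy_cluster(ltr5)
  lib <- build_library(cl, ltr5)
  s <- summarize_hits(naive_mask(fx$genome, lib$library),
                      setNames(nchar(fx$genome), names(fx$genome)))

  m <- merge_master_table(el, clusters = cl, summaries = s)
  expect_equal(nrow(m$master), nrow(el))
  expect_setequal(m$master$element_id, el$element_id)
  # stages not run stay NA without dropping rows
  expect_true(all(is.na(m$master$fpkm)))
  expect_true(all(is.na(m$master$clade)))
  expect_false(any(is.na(m$master$family_id)))

  # per-family medians equal a brute-force group-by
  for (f in m$families$family_id) {
    ids <- m$master$element_id[m$master$family_id == f]
    expect_equal(m$families$insertion_time_median_mya[m$families$family_id == f],
                 median(m$master$insertion_time_mya[m$master$element_id %in% ids]))
  }
  expect_equal(sum(m$families$n_intact), nrow(el))
  expect_true(any(m$families$dominant))

  el_dup <- rbind(el, el[1, ])
  expect_error(merge_master_table(el_dup), "duplicate element_id")
})

test_that("insertion time falls back from the table to LTR identity", {
  el <- make_toy_genome(1, 3, seed = 44)$elements
  el$insertion_time_years[2] <- NA
  m <- merge_master_table(el)$master
  expect_equal(m$insertion_time_mya[2], insertion_time_mya(el$ltr_identity[2]))
  # rows with a stated insertion time keep it
  expect_equal(m$insertion_time_mya[1], el$insertion_time_years[1] / 1e6)
})

test_that("mean cluster size is intact count over cluster count", {
  expect_equal(mean_cluster_size(10, 4), 2.5)
  expect_error(mean_cluster_size(10, 0), "positive")
})
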