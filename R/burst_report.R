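#' Cumulative cluster-contribution curve
#'
#' Sorts clusters by the chosen metric descending (ties by family id) and
#' reports the cumulative fraction of the total at each rank; the final
#' value is exactly 1. With \code{metric = "coverage_bp"} this is the
#' curve behind "a few families dominate the genome" plots (log-x
#' cumulative frequency); with \code{"members"} it counts intact
#' elements instead.
#'
#' @param clusters Cluster data frame ([greedy_cluster()] output, with
#'   \code{coverage_bp} filled in when using that metric).
#' @param metric \code{"members"} or \code{"coverage_bp"}.
#' @return Data frame: \code{rank}, \code{family_id}, \code{metric_value},
#'   \code{cumulative_fraction}.
#' @export
cumulative_cluster_curve <- function(clusters, metric = c("members", "coverage_bp")) {
  metric <- match.arg(metric)
  stopifnot(nrow(clusters) > 0)
  vals <- if (metric == "members") clusters$n_members else clusters$coverage_bp
  vals <- as.numeric(vals)
  if (all(is.na(vals)) || sum(vals, na.rm = TRUE) == 0) {
    stop("all metric values are zero or missing", call. = FALSE)
  }
  vals[is.na(vals)] <- 0
  ord <- order(-vals, clusters$family_id)
  vals <- vals[ord]
  cum <- cumsum(vals) / sum(vals)
  cum[length(cum)] <- 1  # guard against floating-point residue
  data.frame(rank = seq_along(vals), family_id = clusters$family_id[ord],
             metric_value = vals, cumulative_fraction = cum,
             stringsAsFactors = FALSE)
}

#' Number of top clusters holding a fraction of the total
#'
#' @param curve Output of [cumulative_cluster_curve()].
#' @param f Target fraction (default 0.5).
#' @return Smallest rank whose cumulative fraction reaches \code{f}.
#' @export
top_n_for_fraction <- function(curve, f = 0.5) {
  stopifnot(f > 0, f <= 1)
  which(curve$cumulative_fraction >= f)[1]
}

#' Insertion time from LTR identity (Jukes-Cantor corrected)
#'
#' The two LTRs of an element are identical on insertion and diverge
#' neutrally afterwards, so the inter-LTR distance dates the insertion:
#' with raw divergence d = 1 - identity, the JC-corrected distance is
#' K = -3/4 ln(1 - 4d/3) and T = K / (2 mu), with mu the per-site
#' per-year substitution rate (default 1.3e-8, the rate commonly used
#' for plant LTR dating).
#'
#' @param ltr_identity Identity fraction between the element's two LTRs;
#'   vectorized. Values with d >= 0.75 are outside the JC domain and
#'   raise an error.
#' @param mu_per_site_per_year Substitution rate (default 1.3e-8).
#' @return Insertion time(s) in million years.
#' @export
insertion_time_mya <- function(ltr_identity, mu_per_site_per_year = 1.3e-8) {
  stopifnot(all(ltr_identity >= 0 & ltr_identity <= 1, na.rm = TRUE))
  d <- 1 - ltr_identity
  if (any(d >= 0.75, na.rm = TRUE)) {
    stop("divergence >= 0.75: Jukes-Cantor correction undefined", call. = FALSE)
  }
  k <- -0.75 * log(1 - (4 / 3) * d)
  k / (2 * mu_per_site_per_year) / 1e6
}

#' Merge all pipeline stages into one master table
#'
#' Left-joins every stage onto the intact-element table by element id and
#' then family id: family membership from clustering, copy number and
#' coverage from masking summaries, clade from tree classification,
#' fragment counts and FPKM from quantification. Missing stages leave
#' their columns NA rather than dropping rows, so the master table always
#' has one row per intact element. Insertion times come from the input
#' table when present, else from LTR identity via
#' [insertion_time_mya()].
#'
#' Also returns a per-family burst summary: copy number, coverage,
#' intact-element count, median and interquartile range of insertion
#' times, and a \code{dominant} flag marking the top families that
#' together hold \code{dominant_fraction} of the chosen metric.
#'
#' @param elements Element data frame ([read_pass_list()]).
#' @param clusters Optional [greedy_cluster()] output.
#' @param summaries Optional [summarize_hits()] output.
#' @param assignments Optional [classify_tree()] output (query labels are
#'   element ids).
#' @param expression Optional [quantify_expression()] /
#'   [compute_fpkm()] table.
#' @param mu_per_site_per_year Substitution rate for insertion-time
#'   fallback.
#' @param dominant_fraction Fraction for the dominant-family cut
#'   (default 0.5).
#' @param dominant_metric Metric for the dominant-family ranking
#'   (default \code{"coverage_bp"}, falling back to \code{"members"}
#'   when no coverage is available).
#' @return List with \code{master} (one row per element) and
#'   \code{families} (per-family burst summary).
#' @export
merge_master_table <- function(elements, clusters = NULL, summaries = NULL,
                               assignments = NULL, expression = NULL,
                               mu_per_site_per_year = 1.3e-8,
                               dominant_fraction = 0.5,
                               dominant_metric = c("coverage_bp", "members")) {
  dominant_metric <- match.arg(dominant_metric)
  if (anyDuplicated(elements$element_id)) {
    stop(sprintf("duplicate element_id: %s",
                 elements$element_id[duplicated(elements$element_id)][1]),
         call. = FALSE)
  }
  master <- elements[, c("element_id", "chrom", "start", "end", "strand",
                         "ltr_identity", "superfamily", "insertion_time_years")]

  master$family_id <- NA_character_
  if (!is.null(clusters)) {
    map <- data.frame(
      element_id = unlist(clusters$member_ids, use.names = FALSE),
      family_id = rep(clusters$family_id, lengths(clusters$member_ids)),
      stringsAsFactors = FALSE
    )
    master$family_id <- map$family_id[match(master$element_id, map$element_id)]
  }

  master$copy_number <- NA_integer_
  master$coverage_bp <- NA_integer_
  if (!is.null(summaries)) {
    fam <- summaries$families
    i <- match(master$family_id, fam$family_id)
    master$copy_number <- fam$copy_number[i]
    master$coverage_bp <- fam$coverage_bp[i]
  }

  master$clade <- NA_character_
  if (!is.null(assignments)) {
    i <- match(master$element_id, assignments$query_label)
    master$clade <- assignments$clade[i]
  }

  master$raw_fragments <- NA_real_
  master$fpkm <- NA_real_
  if (!is.null(expression)) {
    i <- match(master$element_id, expression$element_id)
    master$raw_fragments <- expression$raw_fragments[i]
    master$fpkm <- expression$fpkm[i]
  }

  master$insertion_time_mya <- master$insertion_time_years / 1e6
  need <- is.na(master$insertion_time_mya) & !is.na(master$ltr_identity)
  if (any(need)) {
    master$insertion_time_mya[need] <-
      insertion_time_mya(master$ltr_identity[need], mu_per_site_per_year)
  }
  master$insertion_time_years <- NULL

  families <- NULL
  if (!is.null(clusters)) {
    fam_ids <- clusters$family_id
    idx <- split(seq_len(nrow(master)), master$family_id)
    med <- function(f, fun) {
      x <- master$insertion_time_mya[idx[[f]]]
      if (is.null(idx[[f]]) || all(is.na(x))) NA_real_ else fun(x)
    }
    families <- data.frame(
      family_id = fam_ids,
      n_intact = lengths(idx)[fam_ids],
      copy_number = if (!is.null(summaries)) {
        summaries$families$copy_number[match(fam_ids, summaries$families$family_id)]
      } else NA_integer_,
      coverage_bp = if (!is.null(summaries)) {
        summaries$families$coverage_bp[match(fam_ids, summaries$families$family_id)]
      } else NA_integer_,
      insertion_time_median_mya =
        vapply(fam_ids, med, numeric(1), fun = function(x) stats::median(x, na.rm = TRUE)),
      insertion_time_iqr_mya =
        vapply(fam_ids, med, numeric(1), fun = function(x) stats::IQR(x, na.rm = TRUE)),
      stringsAsFactors = FALSE
    )
    families$n_intact[is.na(families$n_intact)] <- 0L

    curve_input <- clusters
    metric <- dominant_metric
    if (metric == "coverage_bp") {
      if (!is.null(summaries)) {
        curve_input$coverage_bp <- summaries$families$coverage_bp[
          match(curve_input$family_id, summaries$families$family_id)]
      }
      if (all(is.na(curve_input$coverage_bp))) metric <- "members"
    }
    curve <- cumulative_cluster_curve(curve_input, metric = metric)
    n_dom <- top_n_for_fraction(curve, dominant_fraction)
    families$dominant <- families$family_id %in% curve$family_id[seq_len(n_dom)]
    rownames(families) <- NULL
  }
  rownames(master) <- NULL
  list(master = master, families = families)
}
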