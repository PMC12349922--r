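#' Pipeline run configuration
#'
#' Collects input paths and thresholds for [run_all()]. Only the genome
#' and pass.list are mandatory; stages whose inputs are absent are
#' skipped with a log line. A configuration round-trips through a plain
#' JSON file via [read_run_config()] / [write_run_config()].
#'
#' @param genome,pass_list Required input paths (FASTA; pass.list).
#' @param gff3,markers,tree,sam Optional input paths (pass.list.gff3,
#'   clade-tagged marker protein FASTA, Newick tree, sorted SAM).
#' @param out_dir Output directory.
#' @param c,aL Clustering thresholds (see [greedy_cluster()]).
#' @param marker_pattern Marker regex (see [classify_tree()]).
#' @param min_overlap Minimum path overlap for a clade call.
#' @param expressed_min Expressed-element fragment threshold.
#' @param mu Substitution rate for insertion-time estimates.
#' @param min_orf_aa Minimum ORF length (aa).
#' @param seed Integer seed (fixtures and any stochastic step).
#' @param threads Declared thread count; all reductions are
#'   order-independent so results never depend on it.
#' @return A \code{run_config} list.
#' @export
run_config <- function(genome, pass_list, gff3 = NULL, markers = NULL,
                       tree = NULL, sam = NULL, out_dir = "ltrfam_out",
                       c = 0.8, aL = 0.8,
                       marker_pattern = default_marker_pattern(),
                       min_overlap = 2L, expressed_min = 1, mu = 1.3e-8,
                       min_orf_aa = 100L, seed = 1L, threads = 1L) {
  cfg <- list(genome = genome, pass_list = pass_list, gff3 = gff3,
              markers = markers, tree = tree, sam = sam, out_dir = out_dir,
              c = c, aL = aL, marker_pattern = marker_pattern,
              min_overlap = min_overlap, expressed_min = expressed_min,
              mu = mu, min_orf_aa = min_orf_aa, seed = seed, threads = threads)
  class(cfg) <- "run_config"
  for (p in c("genome", "pass_list", "gff3", "markers", "tree", "sam")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop(sprintf("input '%s' does not exist: %s", p, cfg[[p]]), call. = FALSE)
    }
  }
  cfg
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config)[!vapply(config, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

log_stage <- function(...) message(sprintf("[ltrfam %s] ", format(Sys.time(), "%H:%M:%S")),
                                   sprintf(...))

#' Run the full characterization pipeline
#'
#' Executes all stages in dependency order: 5'-LTR extraction and family
#' clustering; library construction; genome masking and family
#' copy-number/coverage summaries; ORF and RT-domain extraction (when
#' markers are supplied); clade classification (when a tree is supplied);
#' expression quantification (when a SAM file is supplied); and the
#' merged master table with burst summaries. Each output is a plain CSV
#' or FASTA in \code{out_dir}; a \code{manifest.json} records parameters,
#' input checksums and per-stage status.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main in-memory results
#'   (\code{elements}, \code{clusters}, \code{summary},
#'   \code{assignments}, \code{expression}, \code{master},
#'   \code{families}, \code{curve}) plus \code{out_dir}.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "ltrfam", version = as.character(utils::packageVersion("ltrfam")),
    parameters = unclass(config)[c("c", "aL", "marker_pattern", "min_overlap",
                                   "expressed_min", "mu", "min_orf_aa",
                                   "seed", "threads")],
    inputs = list(), stages = list()
  )
  for (p in c("genome", "pass_list", "gff3", "markers", "tree", "sam")) {
    if (!is.null(config[[p]])) {
      manifest$inputs[[p]] <- list(path = config[[p]],
                                   md5 = unname(tools::md5sum(config[[p]])))
    }
  }
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, fun) {
    log_stage("stage %s", name)
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      flush_manifest()
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  genome <- run_stage("load_genome", function() read_fasta(config$genome))
  elements <- run_stage("load_elements", function() read_pass_list(config$pass_list))

  cluster_res <- run_stage("cluster", function() {
    ltr5 <- extract_ltr5_sequences(elements, genome)
    clusters <- greedy_cluster(ltr5, c = config$c, aL = config$aL)
    lib <- build_library(clusters, ltr5)
    write_fasta(lib$library, file.path(config$out_dir, "ltr_library.fa"))
    utils::write.table(lib$mapping,
                       file.path(config$out_dir, "element_families.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(clusters = clusters, library = lib$library, mapping = lib$mapping)
  })

  summary_res <- run_stage("mask_and_summarize", function() {
    hits <- naive_mask(genome, cluster_res$library)
    s <- summarize_hits(hits, stats::setNames(nchar(genome), names(genome)))
    utils::write.csv(s$families, file.path(config$out_dir, "family_coverage.csv"),
                     row.names = FALSE, quote = FALSE)
    s
  })

  if (!is.null(config$markers)) {
    run_stage("rt_domains", function() {
      markers <- read_fasta(config$markers)
      orfs <- find_orfs(extract_element_sequences(elements, genome),
                        min_aa = config$min_orf_aa)
      hits <- extract_rt_domains(orfs, markers)
      if (nrow(hits)) {
        write_fasta(stats::setNames(hits$domain_protein, hits$element_id),
                    file.path(config$out_dir, "rt_domains.faa"))
      }
      utils::write.csv(hits[, setdiff(names(hits), "domain_protein")],
                       file.path(config$out_dir, "rt_domain_hits.csv"),
                       row.names = FALSE, quote = FALSE)
      hits
    })
  } else log_stage("stage rt_domains skipped (no marker FASTA)")

  assignments <- NULL
  if (!is.null(config$tree)) {
    assignments <- run_stage("classify", function() {
      classify_tree(paste(readLines(config$tree, warn = FALSE), collapse = ""),
                    marker_pattern = config$marker_pattern,
                    min_overlap = config$min_overlap,
                    csv = file.path(config$out_dir, "clade_assignments.csv"))
    })
  } else log_stage("stage classify skipped (no tree)")

  expression <- NULL
  if (!is.null(config$sam)) {
    expression <- run_stage("quantify", function() {
      el <- if (!is.null(config$gff3)) read_gff3_ltr(config$gff3) else elements
      tab <- quantify_expression(config$sam, el,
                                 expressed_min = config$expressed_min)
      utils::write.csv(tab, file.path(config$out_dir, "expression.csv"),
                       row.names = FALSE, quote = FALSE)
      tab
    })
  } else log_stage("stage quantify skipped (no SAM)")

  report <- run_stage("report", function() {
    m <- merge_master_table(elements, clusters = cluster_res$clusters,
                            summaries = summary_res, assignments = assignments,
                            expression = expression,
                            mu_per_site_per_year = config$mu)
    curve_input <- cluster_res$clusters
    curve_input$coverage_bp <- summary_res$families$coverage_bp[
      match(curve_input$family_id, summary_res$families$family_id)]
    curve <- cumulative_cluster_curve(curve_input, metric = "coverage_bp")
    utils::write.csv(m$master, file.path(config$out_dir, "master.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(m$families, file.path(config$out_dir, "family_burst.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(curve, file.path(config$out_dir, "cumulative_curve.csv"),
                     row.names = FALSE, quote = FALSE)
    c(m, list(curve = curve))
  })

  flush_manifest()
  log_stage("done: %s", config$out_dir)
  invisible(list(elements = elements, clusters = cluster_res$clusters,
                 summary = summary_res, assignments = assignments,
                 expression = expression, master = report$master,
                 families = report$families, curve = report$curve,
                 out_dir = config$out_dir))
}

#' Extract full element sequences from the genome
#'
#' @param elements Element table.
#' @param genome Named character vector of chromosome sequences.
#' @return Named character vector keyed by element id.
#' @export
extract_element_sequences <- function(elements, genome) {
  vapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    substr(genome[[e$chrom]], e$start, e$end)
  }, character(1)) |> stats::setNames(elements$element_id)
}
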