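#' Detect complex structural variants in a BAM file
#'
#' Runs the full caller: insert-profile estimation, abnormal-alignment
#' signal extraction, signal clustering into weighted nodes, signal-graph
#' assembly, maximal-subgraph pattern growth, and call generation.
#'
#' @param bam Coordinate-sorted, indexed BAM of paired-end reads.
#' @param params A [csv_params()].
#' @param region Optional `"contig"` or `"contig:start-end"` restriction.
#' @param profile Optional precomputed [insert_profile()].
#' @return A list of class `csv_callset`: `calls` (list of `csv_call`),
#'   `graph`, `subgraphs`, `profile`, `params`, `stats` (per-stage
#'   counts).
#' @export
detect_csvs <- function(bam, params = csv_params(), region = NULL,
                        profile = NULL) {
  if (is.null(profile)) {
    profile <- estimate_insert_profile(bam, min_sample = params$min_sample,
                                       region = region)
  }
  signals <- extract_signals(bam, region, profile, params)
  cov <- alignment_coverage(bam, region)
  cov_fn <- coverage_lookup(cov)

  bk_nodes <- cluster_breakpoint_signals(signals, cov_fn, params)
  disc <- cluster_discordant_signals(signals, profile, params, cov_fn)
  splits <- split_junction_links(bk_nodes)
  nodes <- rbind(bk_nodes[, c("kind", "contig", "start", "end", "weight",
                              "read_ids", "uid")],
                 disc$nodes[, c("kind", "contig", "start", "end", "weight",
                                "read_ids", "uid")])
  graph <- build_graph(nodes, disc$pairings, splits, params)

  min_dist <- params$min_dist %||% max(2 * profile$mean_insert, 1000)
  gp <- growth_params(min_freq = params$min_freq, min_dist = min_dist)
  subgraphs <- find_maximal_subgraphs(graph, gp)
  calls <- calls_from_graph(graph, subgraphs,
                            min_link_types = params$min_link_types)
  structure(list(calls = calls, graph = graph, subgraphs = subgraphs,
                 profile = profile, params = params,
                 stats = c(n_signals = nrow(signals),
                           n_nodes = nrow(graph$nodes),
                           n_epe = nrow(graph$epe),
                           n_subgraphs = length(subgraphs),
                           n_calls = length(calls))),
            class = "csv_callset")
}

#' @export
print.csv_callset <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("CSV callset: %d calls (from %d signals, %d nodes, ",
                     "%d paired edges, %d subgraphs)\n"),
              s["n_calls"], s["n_signals"], s["n_nodes"], s["n_epe"],
              s["n_subgraphs"]))
  if (length(x$calls)) print(utils::head(calls_table(x$calls), 10))
  invisible(x)
}

#' Simulate a complete benchmark dataset
#'
#' Reference, implanted CSVs on two haplotypes, paired-end reads, a
#' truth-guided (or externally aligned) BAM, and the truth table — all
#' deterministic in `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_fastq Also materialize FASTQ files.
#' @param aligner_cmd Command template for `align_mode = "external_aligner"`,
#'   with placeholders `{ref}`, `{fq1}`, `{fq2}`, `{out}` (must produce a
#'   sorted indexed `<out>.bam`).
#' @return `list(bam, truth, truth_path, reference_path, implant, reads,
#'   config)`.
#' @export
simulate_csv_dataset <- function(config, out_dir,
                                 write_fastq = FALSE, aligner_cmd = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref_path <- file.path(out_dir, "reference.fa")
  ref <- make_reference(config, ref_path)
  implant <- implant_csvs(ref, config)
  need_fq <- write_fastq || config$align_mode == "external_aligner"
  reads <- simulate_reads(implant, config,
                          fastq_prefix = if (need_fq)
                            file.path(out_dir, "reads") else NULL,
                          reference = if (need_fq) ref else NULL)
  bam_prefix <- file.path(out_dir, "aln")
  if (config$align_mode == "external_aligner") {
    if (is.null(aligner_cmd)) {
      stop("external_aligner mode requires `aligner_cmd`")
    }
    cmd <- aligner_cmd
    subs <- c(ref = ref_path, fq1 = reads$fastq[1], fq2 = reads$fastq[2],
              out = bam_prefix)
    for (nm in names(subs)) {
      cmd <- gsub(sprintf("{%s}", nm), subs[[nm]], cmd, fixed = TRUE)
    }
    status <- system(cmd)
    if (status != 0) stop("external aligner failed with status ", status)
    bam <- paste0(bam_prefix, ".bam")
  } else {
    bam <- truth_guided_align(reads$fragments, implant, bam_prefix, config)
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  write_truth_tsv(implant$truth, truth_path)
  list(bam = bam, truth = implant$truth, truth_path = truth_path,
       reference_path = ref_path, implant = implant, reads = reads,
       config = config)
}

#' Simulate, call and score one benchmark replicate
#'
#' Convenience wrapper used by the worked examples and the acceptance
#' protocol: generates a dataset, runs [detect_csvs()], and scores the
#' callset under both match criteria.
#'
#' @param config A [sim_config()].
#' @param params A [csv_params()].
#' @param out_dir Scratch directory (a temporary one by default, removed
#'   afterwards).
#' @param keep Keep the dataset directory.
#' @return `list(unique_interval = match_report, all_breakpoint =
#'   match_report, callset, dataset)`.
#' @export
run_benchmark_replicate <- function(config, params = csv_params(),
                                    out_dir = NULL, keep = !is.null(out_dir)) {
  if (is.null(out_dir)) out_dir <- tempfile("simrep")
  ds <- simulate_csv_dataset(config, out_dir)
  cs <- detect_csvs(ds$bam, params)
  tab <- calls_table(cs$calls)
  ui <- score(tab, ds$truth, criterion = "unique_interval", slop = 500)
  ab <- score(breakpoint_intervals(cs$calls), ds$truth,
              criterion = "all_breakpoint", slop = 500, recall_only = TRUE)
  if (!keep) unlink(out_dir, recursive = TRUE)
  list(unique_interval = ui, all_breakpoint = ab, callset = cs,
       dataset = if (keep) ds else NULL)
}
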