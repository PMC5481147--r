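#' Default pipeline configuration
#'
#' Every heuristic constant used by the pipeline surfaces here.
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
resolve_config <- function(...) {
  cfg <- list(
    mode = "normal",
    quality_threshold = NULL,     # override the mode's threshold
    tau_seed = 0.5,               # multiplicity seeding depth window
    tau_prop = 0.3,               # multiplicity propagation tolerance
    min_anchor_length = 1000,     # bridging anchors must be at least this long;
                                  # shorter single-copy islands (e.g. between
                                  # repeat copies) are resolved as path interior
    match = 3L, mismatch = -6L, gap_open = -5L, gap_extend = -2L,
    min_identity = 0.6,           # long-read alignment identity cut-off
    band = 75L,                   # banded-alignment corridor half-width
    path_delta = 0.5,             # path-search length window
    path_budget = 10000L,         # path-search node budget
    path_accept_identity = 0.7,   # consensus-vs-path acceptance
    seq_bridge_penalty = 0.5,     # quality factor for sequence bridges
    low_depth_frac = 0.5,         # contaminant filter threshold
    quiet = FALSE,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Resolve an assembly graph with long reads
#'
#' Orchestrates graph selection, contaminant filtering, multiplicity
#' inference, long-read alignment, bridging, quality-ordered bridge
#' application, mode-dependent merging, overlap trimming, circularisation
#' and optional rotation.  All stage artifacts are written to `out_dir`;
#' outputs are deterministic for identical inputs and configuration.
#'
#' @param graph an [assembly_graph], or path to a GFA file.
#' @param candidates optional named list of candidate graphs (by k) or a
#'   directory of `k<value>.gfa` files; when given, the best-scoring
#'   candidate is selected and `graph` may be NULL.
#' @param long_reads named character vector of read sequences, or a
#'   FASTA/FASTQ path, or NULL for short-read-only mode.
#' @param contig_paths list of data.frames (id, strand), or a contig-paths
#'   file, or NULL.
#' @param start_genes named character vector or FASTA path of start genes,
#'   or NULL.
#' @param truth optional `synthetic_truth` (or truth JSON path) enabling
#'   evaluation.
#' @param out_dir output directory (created); NULL skips artifact files.
#' @param config a [resolve_config()] list.
#' @return list: `graph` (final), `replicons`, `sequences`, `bridges`,
#'   `applied`, `mmap`, `report` (eval_report or NULL), `log` (character).
#' @export
run_resolve <- function(graph = NULL, candidates = NULL, long_reads = NULL,
                        contig_paths = NULL, start_genes = NULL, truth = NULL,
                        out_dir = NULL, config = resolve_config()) {
  t0 <- Sys.time()
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (!isTRUE(config$quiet)) message("[resolve] ", msg)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  art <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)
  scoring <- scoring_scheme(config$match, config$mismatch, config$gap_open,
                            config$gap_extend)
  mode <- assembly_mode(config$mode, config$quality_threshold)
  say("mode %s (quality threshold %g)", mode$name, mode$quality_threshold)

  # ---- inputs ----
  if (is.character(candidates)) candidates <- read_graph_candidates(candidates)
  if (!is.null(candidates)) {
    sel <- select_best_graph(candidates)
    graph <- sel$graph
    say("selected k=%d from %d candidates", sel$k, nrow(sel$report))
    if (!is.null(out_dir))
      write.table(sel$report, art("graph_selection.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  } else if (is.character(graph)) {
    graph <- read_gfa(graph)
  }
  if (is.null(graph)) stop("either a graph or candidate graphs must be given")
  as_path <- function(x) is.character(x) && length(x) == 1 && file.exists(x)
  if (as_path(long_reads)) long_reads <- read_seqs(long_reads)
  if (as_path(contig_paths)) contig_paths <- read_contig_paths(contig_paths)
  if (as_path(start_genes)) start_genes <- read_seqs(start_genes)
  if (as_path(truth)) truth <- read_truth(truth)
  say("input graph: %d segments, %d dead ends", nrow(graph$segments),
      dead_end_count(graph))

  # ---- prep ----
  graph <- filter_low_depth(graph, config$low_depth_frac)
  say("after low-depth filter: %d segments", nrow(graph$segments))

  # ---- multiplicity ----
  mmap <- infer_multiplicity(graph, config$tau_seed, config$tau_prop)
  if (!is.null(out_dir)) write_multiplicity_tsv(mmap, graph, art("multiplicity.tsv"))
  anchors <- single_copy_segments(mmap, graph, config$min_anchor_length)
  say("%d single-copy anchor segments", length(anchors))

  # ---- bridges ----
  bridges <- list()
  if (mode$use_path_bridges && !is.null(contig_paths)) {
    pb <- path_bridges(graph, contig_paths, mmap)
    say("%d path bridges", length(pb))
    bridges <- c(bridges, pb)
  }
  if (!is.null(long_reads) && length(long_reads) && length(anchors)) {
    contigs <- setNames(graph$segments$sequence, graph$segments$id)[anchors]
    aln <- align_long_reads(long_reads, contigs, scoring,
                            min_identity = config$min_identity,
                            band = config$band)
    say("%d long-read alignments from %d reads", nrow(aln), length(long_reads))
    if (!is.null(out_dir) && nrow(aln))
      write_sam(aln, long_reads, contigs, art("alignments.sam"))
    lb <- long_read_bridges(graph, aln, long_reads, mmap, scoring,
                            delta = config$path_delta,
                            budget = config$path_budget,
                            accept_identity = config$path_accept_identity)
    say("%d long-read bridges", length(lb))
    bridges <- c(bridges, lb)
  }
  bridges <- score_bridges(bridges, graph,
                           seq_bridge_penalty = config$seq_bridge_penalty)
  if (!is.null(out_dir)) write_bridge_tsv(bridges, art("bridges.tsv"))

  # ---- apply + finalise ----
  ap <- apply_bridges(graph, bridges, mode$quality_threshold, mmap,
                      require_multiplicity = mode$name == "conservative")
  say("applied %d of %d bridges", sum(ap$applied), length(bridges))
  fin <- finalise_assembly(ap$graph, mmap, mode, ap$residual, ap$bridge_ids,
                           start_genes, scoring)
  reps <- fin$replicons
  say("final assembly: %d contigs, %d circular", nrow(reps), sum(reps$circular))
  if (!is.null(out_dir)) {
    write_gfa(fin$graph, art("assembly.gfa"))
    write_graph_fasta(fin$graph, art("assembly.fasta"),
                      circular_ids = reps$id[reps$circular],
                      comment = "unpolished")
    write.table(reps, art("replicons.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # ---- evaluation ----
  report <- NULL
  if (!is.null(truth)) {
    report <- evaluate_assembly(fin$sequences, truth,
                                circular_ids = reps$id[reps$circular])
    say("evaluation: %d misassemblies (%d extensive), NGA50 %d, %d/%d replicons completed",
        report$misassemblies, report$extensive, report$nga50,
        report$completed_replicons, nrow(truth$replicons))
    if (!is.null(out_dir)) write_eval_report(report, art("evaluation.tsv"))
  }
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) writeLines(log, art("run.log"))
  list(graph = fin$graph, replicons = reps, sequences = fin$sequences,
       bridges = bridges, applied = ap$applied, mmap = mmap,
       report = report, log = log)
}
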