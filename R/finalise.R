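#' Assembly modes
#'
#' Conservative, normal and bold modes differ in the minimum bridge
#' quality (25, 10 and 1), in whether read-pair contig-path bridges are
#' used at all (not in conservative mode), and in the final merge rule:
#' conservative merges only single-copy anchors and bridge segments,
#' normal additionally merges segments whose post-bridging multiplicity is
#' one, and bold merges every unbranching path.
#'
#' @param name one of "conservative", "normal", "bold".
#' @param quality_threshold optional override of the mode's threshold.
#' @return list of class `assembly_mode`.
#' @export
assembly_mode <- function(name = c("normal", "conservative", "bold"),
                          quality_threshold = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    conservative = list(quality_threshold = 25, use_path_bridges = FALSE,
                        merge_rule = "single_copy_and_bridges_only"),
    normal = list(quality_threshold = 10, use_path_bridges = TRUE,
                  merge_rule = "multiplicity_one_after_bridging"),
    bold = list(quality_threshold = 1, use_path_bridges = TRUE,
                merge_rule = "all_unbranching"))
  if (!is.null(quality_threshold)) def$quality_threshold <- quality_threshold
  structure(c(list(name = name), def), class = "assembly_mode")
}

#' Mode-dependent merging
#'
#' Delegates to [merge_unbranching_paths()] with the mode's eligibility
#' predicate, using post-bridging residual multiplicity for the normal-mode
#' rule.
#'
#' @param graph an [assembly_graph] after bridge application.
#' @param mmap the original `multiplicity_map`.
#' @param mode an [assembly_mode()].
#' @param residual named integer vector of post-bridging multiplicities.
#' @param bridge_ids ids of bridge segments created by [apply_bridges()].
#' @return merged graph.
#' @export
mode_merge <- function(graph, mmap, mode, residual = mmap$assignment,
                       bridge_ids = character(0)) {
  k_orig <- mmap$assignment
  pred <- switch(mode$merge_rule,
    single_copy_and_bridges_only = function(id) {
      id %in% bridge_ids || isTRUE(k_orig[[id]] == 1L)
    },
    multiplicity_one_after_bridging = function(id) {
      id %in% bridge_ids || isTRUE(residual[[id]] == 1L) ||
        isTRUE(k_orig[[id]] == 1L)
    },
    all_unbranching = function(id) TRUE,
    stop("unknown merge rule"))
  merge_unbranching_paths(graph, pred)
}

#' Detect circular replicons
#'
#' Segments whose only links are the self end-to-start link are complete
#' circular replicons; everything else is linear.
#'
#' @param graph an [assembly_graph] (after merging).
#' @return data.frame: id, length, depth, circular.
#' @export
detect_replicons <- function(graph) {
  segs <- graph$segments
  circ <- vapply(segs$id, function(id) {
    l <- graph$links[graph$links$from_id == id | graph$links$to_id == id, ,
                     drop = FALSE]
    nrow(l) > 0 && all(l$from_id == id & l$to_id == id &
                       l$from_strand == l$to_strand)
  }, logical(1))
  data.frame(id = segs$id, length = nchar(segs$sequence), depth = segs$depth,
             circular = unname(circ), stringsAsFactors = FALSE)
}

#' Rotate a circular sequence to begin at a start gene
#'
#' Searches a start-gene database (e.g. dnaA/repA alleles) against the
#' doubled replicon sequence on both strands with the package's seeded
#' aligner.  The best hit with identity >= `min_identity` over >= `min_cov`
#' of the gene length defines the new origin; the sequence is rotated
#' and/or reverse-complemented so the gene starts at position 0 on the
#' forward strand.  With no acceptable hit the sequence is returned
#' unchanged.
#'
#' @param sequence circular replicon sequence (overlap-free).
#' @param genes named character vector of start-gene sequences.
#' @param scoring a [scoring_scheme()].
#' @param min_identity minimum hit identity (default 0.8).
#' @param min_cov minimum fraction of the gene covered (default 0.9).
#' @return list(sequence, rotated (logical), start_gene (name or NA),
#'   strand).
#' @export
rotate_to_start_gene <- function(sequence, genes,
                                 scoring = scoring_scheme(),
                                 min_identity = 0.8, min_cov = 0.9) {
  L <- nchar(sequence)
  best <- NULL
  for (strand in c("+", "-")) {
    target <- if (strand == "+") sequence else revcomp(sequence)
    doubled <- paste0(target, target)
    tindex <- kmer_index(doubled, max_occ = 64L)
    for (gn in names(genes)) {
      al <- seeded_align(genes[[gn]], doubled, scoring, band = 100L,
                         tindex = tindex)
      if (is.null(al)) next
      cov <- (al$a_interval[2] - al$a_interval[1]) / nchar(genes[[gn]])
      if (cov < min_cov || al$identity < min_identity) next
      pos <- al$b_interval[1] %% L
      if (is.null(best) || al$score > best$score ||
          (al$score == best$score && pos < best$pos)) {
        best <- list(score = al$score, pos = pos, strand = strand, gene = gn)
      }
    }
  }
  if (is.null(best)) {
    return(list(sequence = sequence, rotated = FALSE, start_gene = NA_character_,
                strand = NA_character_))
  }
  target <- if (best$strand == "+") sequence else revcomp(sequence)
  out <- if (best$pos == 0) target else
    paste0(substr(target, best$pos + 1L, L), substr(target, 1L, best$pos))
  list(sequence = out, rotated = TRUE, start_gene = best$gene,
       strand = best$strand)
}

#' Finalise an assembly graph into replicons
#'
#' Runs mode-dependent merging, overlap trimming, circular-replicon
#' detection and optional start-gene rotation.
#'
#' @inheritParams mode_merge
#' @param start_genes optional named character vector of start genes.
#' @param scoring a [scoring_scheme()].
#' @return list: `graph` (final), `replicons` (data.frame id, length,
#'   depth, circular, rotated, start_gene), `sequences` (named character
#'   vector of final, possibly rotated, sequences).
#' @export
finalise_assembly <- function(graph, mmap, mode,
                              residual = mmap$assignment,
                              bridge_ids = character(0),
                              start_genes = NULL,
                              scoring = scoring_scheme()) {
  graph <- mode_merge(graph, mmap, mode, residual, bridge_ids)
  graph <- trim_overlaps(graph)
  reps <- detect_replicons(graph)
  reps$rotated <- FALSE
  reps$start_gene <- NA_character_
  seqs <- setNames(graph$segments$sequence, graph$segments$id)
  if (!is.null(start_genes) && length(start_genes)) {
    for (i in which(reps$circular)) {
      rot <- rotate_to_start_gene(seqs[[reps$id[i]]], start_genes, scoring)
      seqs[[reps$id[i]]] <- rot$sequence
      reps$rotated[i] <- rot$rotated
      reps$start_gene[i] <- rot$start_gene
      j <- match(reps$id[i], graph$segments$id)
      graph$segments$sequence[j] <- rot$sequence
    }
  }
  list(graph = graph, replicons = reps, sequences = seqs)
}
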