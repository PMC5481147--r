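#' Candidate k-mer ladder
#'
#' Ten k values spanning 20--95% of the short-read length, capped at 127,
#' linearly spaced then rounded to the nearest odd (ties upward) and
#' de-duplicated.
#'
#' @param read_length short-read length in bp (>= 30).
#' @return increasing odd integer vector (usually length 10).
#' @export
kmer_ladder <- function(read_length) {
  if (read_length < 30) stop("read_length too small")
  lo <- 0.20 * read_length
  hi <- min(round(0.95 * read_length), 127)
  raw <- seq(lo, hi, length.out = 10)
  odd <- as.integer(2 * floor(raw / 2) + 1)  # nearest odd, ties up
  odd[odd > 127L] <- 127L
  ks <- unique(odd)
  if (length(ks) < 2) stop("read_length too small to yield >= 2 distinct odd k values")
  ks
}

#' Score a k-mer assembly graph
#'
#' `score = 1 / (c * (d + 1)^2)` for `c` contigs and `d` dead ends: both
#' fragmentation and dead ends are penalised, dead ends quadratically
#' because they defeat downstream multiplicity and bridging steps.
#'
#' @param c positive contig count.
#' @param d non-negative dead-end count.
#' @return list with `contig_count`, `dead_ends`, `score`.
#' @export
graph_score <- function(c, d) {
  stopifnot(c >= 1, d >= 0)
  list(contig_count = as.integer(c), dead_ends = as.integer(d),
       score = 1 / (c * (d + 1)^2))
}

#' Select the best graph from a candidate ladder
#'
#' @param candidates named list of [assembly_graph] objects; names are the
#'   k values.
#' @return list with `k`, `graph`, and a `report` data.frame
#'   (k, contigs, dead_ends, score per candidate).
#' @export
select_best_graph <- function(candidates) {
  if (!length(candidates)) stop("no candidate graphs")
  ks <- as.integer(names(candidates))
  rep <- data.frame(k = ks,
                    contigs = vapply(candidates, function(g) nrow(g$segments), 0L),
                    dead_ends = vapply(candidates, dead_end_count, 0L))
  rep$score <- 1 / (rep$contigs * (rep$dead_ends + 1)^2)
  # ties broken toward larger k
  best <- order(-rep$score, -rep$k)[1]
  list(k = rep$k[best], graph = candidates[[best]], report = rep)
}

#' Read candidate graphs from a directory
#'
#' Files must be named `k<value>.gfa` (e.g. `k55.gfa`).
#'
#' @param dir directory path.
#' @return named list of graphs keyed by k.
#' @export
read_graph_candidates <- function(dir) {
  files <- list.files(dir, pattern = "^k[0-9]+\\.gfa$", full.names = TRUE)
  if (!length(files)) stop("no k<value>.gfa candidates in ", dir)
  ks <- as.integer(sub("^k([0-9]+)\\.gfa$", "\\1", basename(files)))
  out <- lapply(files, read_gfa)
  names(out) <- ks
  out[order(ks)]
}

#' Remove likely contaminant segments
#'
#' Iteratively removes segments whose depth is below half the
#' length-weighted median graph depth, skipping any removal that would
#' create a new dead end.  Candidates are processed deepest-first; removal
#' iterates to a fixed point.  The median is computed once, on the input
#' graph.
#'
#' @param graph an [assembly_graph].
#' @param frac depth fraction of the median below which a segment is a
#'   removal candidate (default 0.5).
#' @return filtered graph.
#' @export
filter_low_depth <- function(graph, frac = 0.5) {
  if (nrow(graph$segments) == 0) return(graph)
  D <- median_depth(graph)
  repeat {
    segs <- graph$segments
    cand <- segs$id[segs$depth < frac * D]
    if (!length(cand)) return(graph)
    cand <- cand[order(-segs$depth[match(cand, segs$id)])]  # deepest first
    removed <- FALSE
    for (id in cand) {
      if (!creates_dead_end(graph, id)) {
        graph <- remove_segments(graph, id)
        removed <- TRUE
        break  # re-derive candidates against the edited graph
      }
    }
    if (!removed) return(graph)
  }
}

# would removing `id` leave some other segment end with no links?
creates_dead_end <- function(graph, id) {
  touching <- graph$links[graph$links$from_id == id | graph$links$to_id == id, ,
                          drop = FALSE]
  if (!nrow(touching)) return(FALSE)
  # neighbour oriented ends that currently reach `id`
  nb <- touching[touching$from_id != id, c("from_id", "from_strand"), drop = FALSE]
  nb <- unique(nb)
  if (!nrow(nb)) return(FALSE)  # only self-links
  for (i in seq_len(nrow(nb))) {
    l <- out_links(graph, nb$from_id[i], nb$from_strand[i])
    if (all(l$to_id == id)) return(TRUE)
  }
  FALSE
}
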