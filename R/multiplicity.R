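#' Infer segment multiplicity from depth and connectivity
#'
#' Copy numbers are determined in two phases.  Seeding assigns multiplicity
#' one to every segment whose depth lies within `tau_seed` of the
#' length-weighted median graph depth D and which has at most one link at
#' either end.  A greedy propagation then walks segment ends where all but
#' one incident segment is known and flow balance (copies entering a
#' junction equal copies leaving) forces a unique positive value in close
#' depth agreement; the assignment with the best depth agreement is applied
#' first.  When propagation stalls, a restart seeds multiplicity one into
#' the longest unassigned segment: preferring segments near or below median
#' depth, then structurally single-copy segments (at most one link per end,
#' which covers high-copy-number plasmids whose depth reflects cell copy
#' number rather than within-genome multiplicity), and finally falling back
#' to `round(depth/D)`.
#'
#' @param graph an [assembly_graph].
#' @param tau_seed relative depth window for seeding (default 0.5).
#' @param tau_prop relative depth tolerance for propagation (default 0.3).
#' @return object of class `multiplicity_map`: list with `assignment`
#'   (named integer vector), `origin` (named character:
#'   seed/propagated/restart-seed), `median_depth`.
#' @export
infer_multiplicity <- function(graph, tau_seed = 0.5, tau_prop = 0.3) {
  mm <- seed_multiplicity(graph, tau_seed)
  propagate_multiplicity(graph, mm, tau_seed = tau_seed, tau_prop = tau_prop)
}

#' Seed single-copy multiplicity
#'
#' @inheritParams infer_multiplicity
#' @return partial `multiplicity_map` (unassigned segments are absent from
#'   `assignment`).
#' @export
seed_multiplicity <- function(graph, tau_seed = 0.5) {
  D <- median_depth(graph)
  segs <- graph$segments
  ids <- character(); vals <- integer()
  for (i in seq_len(nrow(segs))) {
    id <- segs$id[i]
    d <- segs$depth[i]
    if (d < (1 - tau_seed) * D || d > (1 + tau_seed) * D) next
    if (nrow(out_links(graph, id, "+")) > 1) next
    if (nrow(out_links(graph, id, "-")) > 1) next
    ids <- c(ids, id); vals <- c(vals, 1L)
  }
  structure(list(assignment = setNames(vals, ids),
                 origin = setNames(rep("seed", length(ids)), ids),
                 median_depth = D),
            class = "multiplicity_map")
}

#' Propagate multiplicity to completion
#'
#' @param graph an [assembly_graph].
#' @param mmap partial map from [seed_multiplicity()].
#' @inheritParams infer_multiplicity
#' @return complete `multiplicity_map`.
#' @export
propagate_multiplicity <- function(graph, mmap, tau_seed = 0.5, tau_prop = 0.3) {
  D <- mmap$median_depth
  segs <- graph$segments
  depth <- setNames(segs$depth, segs$id)
  len <- segment_lengths(graph)
  k <- mmap$assignment
  origin <- mmap$origin

  # all oriented ends with at least one link
  ends <- unique(graph$links[, c("from_id", "from_strand")])

  one_link_per_end <- function(id) {
    nrow(out_links(graph, id, "+")) <= 1 && nrow(out_links(graph, id, "-")) <= 1
  }

  repeat {
    # gather candidate forced assignments across all junctions
    cand <- NULL  # (id, value, agreement)
    for (i in seq_len(nrow(ends))) {
      eid <- ends$from_id[i]; estr <- ends$from_strand[i]
      nbrs <- out_links(graph, eid, estr)
      nbr_ids <- nbrs$to_id
      all_ids <- c(eid, nbr_ids)
      unknown <- unique(all_ids[!(all_ids %in% names(k))])
      if (length(unknown) != 1) next
      u <- unknown
      # the junction is clean when each neighbour end links only back to eid,
      # so the neighbour's full multiplicity flows through this junction
      clean <- all(vapply(seq_len(nrow(nbrs)), function(j) {
        back <- in_links(graph, nbrs$to_id[j], nbrs$to_strand[j])
        nrow(back) >= 1 && all(back$from_id == eid)
      }, logical(1)))
      if (!clean) next
      if (u == eid) {
        val <- sum(k[nbr_ids])
      } else {
        others <- nbr_ids[nbr_ids != u]
        if (anyDuplicated(nbr_ids[nbr_ids == u])) next
        val <- k[[eid]] - if (length(others)) sum(k[others]) else 0L
      }
      if (is.na(val) || val < 1) next
      agree <- abs(depth[[u]] / D - val)
      if (agree > tau_prop * val) next
      cand <- rbind(cand, data.frame(id = u, val = as.integer(val),
                                     agree = agree / val,
                                     stringsAsFactors = FALSE))
    }
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(cand$agree, cand$id), , drop = FALSE]
      k[cand$id[1]] <- cand$val[1]
      origin[cand$id[1]] <- "propagated"
      next
    }
    un <- setdiff(segs$id, names(k))
    if (!length(un)) break
    # restart: seed the longest suitable unassigned segment
    un <- un[order(-len[un], un)]
    pick <- un[depth[un] <= (1 + tau_seed) * D]
    if (length(pick)) {
      k[pick[1]] <- 1L
    } else {
      pick <- un[vapply(un, one_link_per_end, logical(1))]
      if (length(pick)) {
        k[pick[1]] <- 1L
      } else {
        pick <- un
        k[pick[1]] <- max(1L, as.integer(round(depth[[pick[1]]] / D)))
      }
    }
    origin[pick[1]] <- "restart-seed"
  }
  structure(list(assignment = k, origin = origin, median_depth = D),
            class = "multiplicity_map")
}

#' @export
print.multiplicity_map <- function(x, ...) {
  cat("multiplicity_map:", length(x$assignment), "segments, D =",
      signif(x$median_depth, 4), "\n")
  tab <- table(x$assignment)
  cat("  k:", paste(names(tab), "x", tab, collapse = ", "), "\n")
  invisible(x)
}

#' Single-copy segments
#'
#' @param mmap a complete `multiplicity_map`.
#' @param graph the graph the map was computed on.
#' @param min_length minimum segment length in bp (default 0).
#' @return character vector of segment ids with multiplicity 1 and length
#'   at least `min_length`.
#' @export
single_copy_segments <- function(mmap, graph, min_length = 0) {
  ids <- names(mmap$assignment)[mmap$assignment == 1L]
  len <- segment_lengths(graph)
  sort(ids[len[ids] >= min_length])
}

#' Write a per-segment multiplicity table
#'
#' Columns: id, length, depth, depth ratio to the graph median, assigned
#' multiplicity, origin.
#'
#' @param mmap a `multiplicity_map`.
#' @param graph the graph.
#' @param path output TSV path.
#' @export
write_multiplicity_tsv <- function(mmap, graph, path) {
  segs <- graph$segments
  df <- data.frame(id = segs$id, length = nchar(segs$sequence),
                   depth = segs$depth,
                   depth_ratio = segs$depth / mmap$median_depth,
                   multiplicity = mmap$assignment[segs$id],
                   origin = mmap$origin[segs$id])
  df <- df[order(-df$length, df$id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
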