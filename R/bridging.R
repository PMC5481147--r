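new_bridge <- function(start_id, start_strand, end_id, end_strand, path,
                       sequence, kind, support, consensus_identity = 1,
                       aln_factor = 1) {
  structure(list(start_id = start_id, start_strand = start_strand,
                 end_id = end_id, end_strand = end_strand,
                 path = path,              # data.frame(id, strand) or NULL
                 sequence = sequence,      # interior sequence (may be "")
                 kind = kind,              # path_bridge / long_read_graph_bridge /
                                           # long_read_sequence_bridge
                 support = support,
                 consensus_identity = consensus_identity,
                 aln_factor = aln_factor,  # mean(read identity * capped length)
                 quality = NA_real_),
            class = "bridge")
}

#' @export
print.bridge <- function(x, ...) {
  cat(sprintf("bridge %s%s -> %s%s [%s] support=%d quality=%s\n",
              x$start_id, x$start_strand, x$end_id, x$end_strand, x$kind,
              x$support,
              if (is.na(x$quality)) "unscored" else sprintf("%.1f", x$quality)))
  invisible(x)
}

# overlap between consecutive oriented path members, looked up in the graph;
# NA when no link exists
path_link_overlaps <- function(graph, ids, strands) {
  if (length(ids) < 2) return(integer(0))
  vapply(seq_len(length(ids) - 1), function(i) {
    l <- out_links(graph, ids[i], strands[i])
    l <- l[l$to_id == ids[i + 1] & l$to_strand == strands[i + 1], , drop = FALSE]
    if (nrow(l)) l$overlap[1] else NA_integer_
  }, 0L)
}

#' Bridges from read-pair contig paths
#'
#' For every pair of single-copy segments adjacent (up to interposed repeat
#' segments) within a contig path, emits a `path_bridge` whose interior is
#' the sub-path between them.  Identical bridges found in several paths
#' accumulate support.
#'
#' @param graph an [assembly_graph].
#' @param contig_paths list of data.frames (id, strand), as produced by
#'   [read_contig_paths()] or [build_kmer_graph()].
#' @param mmap a `multiplicity_map`.
#' @return list of `bridge` objects.
#' @export
path_bridges <- function(graph, contig_paths, mmap) {
  sc <- names(mmap$assignment)[mmap$assignment == 1L]
  acc <- list()
  for (p in contig_paths) {
    if (!all(p$id %in% graph$segments$id)) {
      warning("contig path references unknown segment; skipped")
      next
    }
    anchors <- which(p$id %in% sc)
    if (length(anchors) < 2) next
    for (ai in seq_len(length(anchors) - 1)) {
      i <- anchors[ai]; j <- anchors[ai + 1]
      interior <- if (j > i + 1) p[(i + 1):(j - 1), , drop = FALSE] else NULL
      key <- paste(p$id[i], p$strand[i], p$id[j], p$strand[j],
                   if (is.null(interior)) "" else paste(interior$id, interior$strand, collapse = " "))
      if (!is.null(acc[[key]])) {
        acc[[key]]$support <- acc[[key]]$support + 1L
      } else {
        full_ids <- p$id[i:j]; full_strands <- p$strand[i:j]
        ovs <- path_link_overlaps(graph, full_ids, full_strands)
        if (anyNA(ovs)) next  # path not realisable in this graph
        seq_int <- if (is.null(interior)) "" else
          oriented_concat(graph, interior$id, interior$strand,
                          path_link_overlaps(graph, interior$id, interior$strand))
        acc[[key]] <- new_bridge(p$id[i], p$strand[i], p$id[j], p$strand[j],
                                 path = interior, sequence = seq_int,
                                 kind = "path_bridge", support = 1L)
      }
    }
  }
  unname(acc)
}

#' Best graph path matching a target sequence
#'
#' Best-first search over oriented paths from `from` to `to`.  Candidates
#' are pruned when their interior length exceeds the window
#' `[(1-delta), (1+delta)]` times the target length (plus an overlap/indel
#' slack) or when node expansions exceed `budget`.  Surviving candidate
#' paths are scored by banded end-gap-free alignment of their interior
#' sequence (anchor overlaps trimmed) against the target; the best-scoring
#' path with identity at least `accept_identity` is returned.
#'
#' @param graph an [assembly_graph].
#' @param from,to oriented anchors, as `list(id=, strand=)`.
#' @param target_seq consensus gap sequence (may be "").
#' @param scoring a [scoring_scheme()].
#' @param delta relative length-window half-width.
#' @param budget node-expansion budget.
#' @param accept_identity minimum identity of target vs path sequence.
#' @return list(path = data.frame(id, strand) [possibly 0-row],
#'   identity, score) or NULL.
#' @export
find_graph_path <- function(graph, from, to, target_seq,
                            scoring = scoring_scheme(), delta = 0.5,
                            budget = 10000L, accept_identity = 0.7) {
  tl <- nchar(target_seq)
  slack <- 2L * graph$k_overlap + 20L
  lo <- (1 - delta) * tl - slack
  hi <- (1 + delta) * tl + slack
  lens <- segment_lengths(graph)

  # interior length of a path (anchor overlaps and internal overlaps removed)
  interior_len <- function(ids, strands) {
    if (!length(ids)) return(0L)
    ov_in <- path_link_overlaps(graph, c(from$id, ids), c(from$strand, strands))
    ov_out <- path_link_overlaps(graph, c(ids[length(ids)], to$id),
                                 c(strands[length(ids)], to$strand))
    sum(lens[ids]) - sum(ov_in) - sum(ov_out)
  }

  candidates <- list()
  # direct connection
  direct <- out_links(graph, from$id, from$strand)
  if (any(direct$to_id == to$id & direct$to_strand == to$strand) &&
      0 >= lo && 0 <= hi) {
    candidates[[1]] <- list(ids = character(0), strands = character(0))
  }
  # best-first over partial paths ordered by interior length so far
  queue <- list(list(ids = character(0), strands = character(0), len = 0))
  expansions <- 0L
  while (length(queue) && expansions < budget) {
    ord <- order(vapply(queue, `[[`, 0, "len"))
    st <- queue[[ord[1]]]
    queue <- queue[ord[-1]]
    tail_id <- if (length(st$ids)) st$ids[length(st$ids)] else from$id
    tail_strand <- if (length(st$ids)) st$strands[length(st$ids)] else from$strand
    nxt <- out_links(graph, tail_id, tail_strand)
    for (i in seq_len(nrow(nxt))) {
      expansions <- expansions + 1L
      nid <- nxt$to_id[i]; nstr <- nxt$to_strand[i]
      if (nid == to$id && nstr == to$strand) next  # handled as candidate close
      new_ids <- c(st$ids, nid); new_strands <- c(st$strands, nstr)
      nlen <- st$len + lens[[nid]] - nxt$overlap[i]
      if (nlen - 2 * graph$k_overlap > hi) next  # prune: already too long
      # can it close onto `to`?
      closes <- out_links(graph, nid, nstr)
      if (any(closes$to_id == to$id & closes$to_strand == to$strand)) {
        il <- interior_len(new_ids, new_strands)
        if (il >= lo && il <= hi)
          candidates[[length(candidates) + 1L]] <-
            list(ids = new_ids, strands = new_strands)
      }
      queue[[length(queue) + 1L]] <- list(ids = new_ids, strands = new_strands,
                                          len = nlen)
      if (length(candidates) >= 50L) { queue <- list(); break }
    }
  }
  if (!length(candidates)) return(NULL)

  best <- NULL
  for (cd in candidates) {
    seq_int <- path_interior_sequence(graph, from, to, cd$ids, cd$strands)
    if (!nchar(seq_int) && tl == 0) {
      sc <- list(identity = 1, score = 0)
    } else if (!nchar(seq_int) || tl == 0) {
      # pure-gap comparison: identity 0 unless both tiny
      if (max(nchar(seq_int), tl) <= slack) sc <- list(identity = 1, score = 0)
      else next
    } else {
      d <- nchar(seq_int) - tl
      raw <- .semiglobal_banded_cpp(target_seq, seq_int, scoring$match,
                                    scoring$mismatch, scoring$gap_open,
                                    scoring$gap_extend,
                                    min(0, d) - 150L, max(0, d) + 150L)
      if (!isTRUE(raw$found)) next
      # identity over the shorter sequence's aligned fraction, penalising
      # unaligned target/path ends
      cols <- raw$columns + (tl - (raw$a_end - raw$a_start))
      sc <- list(identity = raw$matches / max(cols, 1), score = raw$score)
    }
    if (is.null(best) || sc$score > best$score ||
        (sc$score == best$score && sc$identity > best$identity)) {
      best <- list(path = if (length(cd$ids))
                     data.frame(id = cd$ids, strand = cd$strands,
                                stringsAsFactors = FALSE)
                   else data.frame(id = character(0), strand = character(0)),
                   identity = sc$identity, score = sc$score)
    }
  }
  if (is.null(best) || best$identity < accept_identity) return(NULL)
  best
}

# interior sequence between anchors: concatenated path with internal overlaps
# collapsed and anchor-side overlaps trimmed
path_interior_sequence <- function(graph, from, to, ids, strands) {
  if (!length(ids)) return("")
  ov_first <- path_link_overlaps(graph, c(from$id, ids[1]),
                                 c(from$strand, strands[1]))
  ov_last <- path_link_overlaps(graph, c(ids[length(ids)], to$id),
                                c(strands[length(ids)], to$strand))
  internal <- path_link_overlaps(graph, ids, strands)
  s <- oriented_concat(graph, ids, strands, internal)
  n <- nchar(s)
  if (ov_first + ov_last >= n) return("")
  substr(s, ov_first + 1L, n - ov_last)
}

#' Bridges from long-read alignments
#'
#' Reads aligning to two or more single-copy contigs are grouped by the
#' oriented contig pair they span; per group, the read gap fragments are
#' collapsed to a consensus, and the graph is searched for a path matching
#' the consensus ([find_graph_path()]).  Success yields a
#' `long_read_graph_bridge` whose sequence comes from the graph (short-read
#' base quality); failure yields a `long_read_sequence_bridge` carrying the
#' consensus itself.
#'
#' @param graph an [assembly_graph].
#' @param alignments data.frame from [align_long_reads()].
#' @param reads named character vector of read sequences.
#' @param mmap a `multiplicity_map`.
#' @param scoring a [scoring_scheme()].
#' @param ... passed to [find_graph_path()].
#' @return list of `bridge` objects.
#' @export
long_read_bridges <- function(graph, alignments, reads, mmap,
                              scoring = scoring_scheme(), ...) {
  if (!nrow(alignments)) return(list())
  sc <- names(mmap$assignment)[mmap$assignment == 1L]
  alignments <- alignments[alignments$contig %in% sc, , drop = FALSE]
  groups <- list()
  for (rn in unique(alignments$read)) {
    al <- alignments[alignments$read == rn, , drop = FALSE]
    if (nrow(al) < 2) next
    al <- al[order(al$read_start), , drop = FALSE]
    for (i in seq_len(nrow(al) - 1)) {
      a <- al[i, ]; b <- al[i + 1, ]
      # the read must leave a's far end and enter b's near end
      a_exits <- (a$strand == "+" && a$reaches_contig_end) ||
                 (a$strand == "-" && a$reaches_contig_start)
      b_enters <- (b$strand == "+" && b$reaches_contig_start) ||
                  (b$strand == "-" && b$reaches_contig_end)
      if (!a_exits || !b_enters) next
      gap <- if (b$read_start > a$read_end)
        substr(reads[[rn]], a$read_end + 1L, b$read_start) else ""
      key <- paste(a$contig, a$strand, b$contig, b$strand)
      tkey <- paste(b$contig, flip_strand(b$strand),
                    a$contig, flip_strand(a$strand))
      if (tkey < key) { key <- tkey; gap <- if (nzchar(gap)) revcomp(gap) else "" }
      aln_q <- mean(c(a$identity * min(1, (a$read_end - a$read_start) / 1000),
                      b$identity * min(1, (b$read_end - b$read_start) / 1000)))
      groups[[key]] <- c(groups[[key]], list(list(gap = gap, aln_q = aln_q)))
    }
  }
  bridges <- list()
  for (key in names(groups)) {
    g <- groups[[key]]
    parts <- strsplit(key, " ")[[1]]
    from <- list(id = parts[1], strand = parts[2])
    to <- list(id = parts[3], strand = parts[4])
    gaps <- vapply(g, `[[`, "", "gap")
    cons <- consensus_sequence(gaps, scoring)
    hit <- find_graph_path(graph, from, to, cons, scoring, ...)
    aln_factor <- mean(vapply(g, `[[`, 0, "aln_q"))
    if (!is.null(hit)) {
      seq_int <- if (nrow(hit$path))
        oriented_concat(graph, hit$path$id, hit$path$strand,
                        path_link_overlaps(graph, hit$path$id, hit$path$strand))
      else ""
      b <- new_bridge(from$id, from$strand, to$id, to$strand,
                      path = if (nrow(hit$path)) hit$path else NULL,
                      sequence = seq_int, kind = "long_read_graph_bridge",
                      support = length(g), consensus_identity = hit$identity,
                      aln_factor = aln_factor)
    } else {
      b <- new_bridge(from$id, from$strand, to$id, to$strand, path = NULL,
                      sequence = cons, kind = "long_read_sequence_bridge",
                      support = length(g), consensus_identity = 1,
                      aln_factor = aln_factor)
    }
    bridges[[length(bridges) + 1L]] <- b
  }
  bridges
}

#' Heuristic bridge quality in [0, 100]
#'
#' The quality is 100 times a product of bounded monotone factors:
#' read support `1 - 2^-support`; consensus-to-path identity (graph
#' bridges; sequence bridges take a fixed penalty factor); anchor contig
#' length `min(1, min_len/10000)`; supporting-alignment quality
#' (identity times capped length); and anchor depth agreement
#' `min(d)/max(d)`.  Path bridges take support over path occurrences and
#' unit consensus/alignment factors.
#'
#' @param bridge a `bridge`.
#' @param graph an [assembly_graph].
#' @param seq_bridge_penalty consensus factor for sequence bridges.
#' @return quality in `[0, 100]`.
#' @export
bridge_quality <- function(bridge, graph, seq_bridge_penalty = 0.5) {
  lens <- segment_lengths(graph)
  depth <- setNames(graph$segments$depth, graph$segments$id)
  f_support <- 1 - 2^(-bridge$support)
  f_consensus <- switch(bridge$kind,
    path_bridge = 1,
    long_read_graph_bridge = bridge$consensus_identity,
    long_read_sequence_bridge = seq_bridge_penalty)
  f_contig_len <- min(1, min(lens[[bridge$start_id]], lens[[bridge$end_id]]) / 10000)
  f_aln <- if (bridge$kind == "path_bridge") 1 else bridge$aln_factor
  d1 <- depth[[bridge$start_id]]; d2 <- depth[[bridge$end_id]]
  f_depth <- min(d1, d2) / max(d1, d2)
  100 * f_support * f_consensus * f_contig_len * f_aln * f_depth
}

score_bridges <- function(bridges, graph, ...) {
  lapply(bridges, function(b) { b$quality <- bridge_quality(b, graph, ...); b })
}

#' Apply bridges in decreasing quality order
#'
#' Bridges below `threshold` are discarded.  The rest are applied
#' best-first; a bridge is skipped when either of its single-copy anchor
#' ends was already consumed by an applied bridge (the contradiction rule).
#' Application removes the competing links at both anchor ends, installs a
#' bridge segment carrying the bridge sequence (or restores the direct
#' link for an empty interior), and decrements the remaining multiplicity
#' of path members (floored at 0).  Afterwards, path members with no
#' remaining multiplicity are removed when that creates no new dead end.
#'
#' @param graph an [assembly_graph].
#' @param bridges list of scored `bridge` objects.
#' @param threshold minimum quality.
#' @param mmap a `multiplicity_map`.
#' @param require_multiplicity skip bridges whose path members lack
#'   remaining multiplicity (conservative mode).
#' @return list: `graph` (modified), `applied` (logical per input bridge),
#'   `residual` (named integer vector of remaining multiplicities),
#'   `bridge_ids` (ids of created bridge segments).
#' @export
apply_bridges <- function(graph, bridges, threshold, mmap,
                          require_multiplicity = FALSE) {
  applied <- logical(length(bridges))
  if (!length(bridges)) {
    return(list(graph = graph, applied = applied,
                residual = mmap$assignment, bridge_ids = character(0)))
  }
  qual <- vapply(bridges, function(b) b$quality, 0)
  ord <- order(-qual,
               vapply(bridges, function(b) paste(b$start_id, b$end_id), ""))
  residual <- mmap$assignment
  consumed <- character(0)   # "<id> <physical end L/R>"
  exit_end <- function(id, strand) paste(id, ifelse(strand == "+", "R", "L"))
  entry_end <- function(id, strand) paste(id, ifelse(strand == "+", "L", "R"))
  bridge_ids <- character(0)
  path_member_ids <- character(0)

  for (oi in ord) {
    b <- bridges[[oi]]
    if (is.na(b$quality) || b$quality < threshold) next
    e1 <- exit_end(b$start_id, b$start_strand)
    e2 <- entry_end(b$end_id, b$end_strand)
    if (e1 %in% consumed || e2 %in% consumed) next
    if (identical(e1, e2)) next
    if (!(b$start_id %in% graph$segments$id) ||
        !(b$end_id %in% graph$segments$id)) next
    has_path <- !is.null(b$path) && nrow(b$path) > 0
    if (require_multiplicity && has_path) {
      uses <- table(b$path$id)
      if (any(residual[names(uses)] < uses)) next
    }
    # look up anchor-side overlaps before links are removed
    if (has_path) {
      ov_first <- path_link_overlaps(graph, c(b$start_id, b$path$id[1]),
                                     c(b$start_strand, b$path$strand[1]))
      ov_last <- path_link_overlaps(graph,
                                    c(b$path$id[nrow(b$path)], b$end_id),
                                    c(b$path$strand[nrow(b$path)], b$end_strand))
      if (anyNA(c(ov_first, ov_last))) next  # path no longer realisable
    }
    direct <- out_links(graph, b$start_id, b$start_strand)
    direct <- direct[direct$to_id == b$end_id &
                     direct$to_strand == b$end_strand, , drop = FALSE]
    # remove all links at both anchor ends
    rm1 <- graph$links$from_id == b$start_id &
           graph$links$from_strand == b$start_strand
    rm2 <- graph$links$to_id == b$end_id & graph$links$to_strand == b$end_strand
    drop <- rm1 | rm2
    dropped <- graph$links[drop, , drop = FALSE]
    dropkeys <- unique(c(link_key(dropped), link_key(twin_of(dropped))))
    graph$links <- graph$links[!(link_key(graph$links) %in% dropkeys), ,
                               drop = FALSE]
    if (nzchar(b$sequence)) {
      bid <- new_segment_id(graph, "bridge_")
      dep <- mean(c(graph$segments$depth[match(b$start_id, graph$segments$id)],
                    graph$segments$depth[match(b$end_id, graph$segments$id)]))
      mem <- if (has_path) paste0(b$path$id, b$path$strand, collapse = ",") else bid
      graph$segments <- rbind(graph$segments, data.frame(
        id = bid, sequence = b$sequence, depth = dep, members = mem,
        stringsAsFactors = FALSE))
      ov_in <- if (has_path) ov_first else 0L
      ov_out <- if (has_path) ov_last else 0L
      graph$links <- add_twin_links(rbind(graph$links, data.frame(
        from_id = c(b$start_id, bid), from_strand = c(b$start_strand, "+"),
        to_id = c(bid, b$end_id), to_strand = c("+", b$end_strand),
        overlap = c(ov_in, ov_out), stringsAsFactors = FALSE)))
      bridge_ids <- c(bridge_ids, bid)
    } else {
      # empty interior: restore/install the direct connection
      ov <- if (nrow(direct)) direct$overlap[1] else 0L
      graph$links <- add_twin_links(rbind(graph$links, data.frame(
        from_id = b$start_id, from_strand = b$start_strand,
        to_id = b$end_id, to_strand = b$end_strand, overlap = ov,
        stringsAsFactors = FALSE)))
    }
    if (has_path) {
      for (pid in b$path$id)
        residual[pid] <- max(0L, residual[pid] - 1L)
      path_member_ids <- unique(c(path_member_ids, b$path$id))
    }
    consumed <- c(consumed, e1, e2)
    applied[oi] <- TRUE
  }
  # retire path members that are used up, where safe
  for (pid in intersect(path_member_ids, graph$segments$id)) {
    if (residual[pid] == 0L && !creates_dead_end(graph, pid))
      graph <- remove_segments(graph, pid)
  }
  list(graph = graph, applied = applied, residual = residual,
       bridge_ids = bridge_ids)
}

#' Write a bridge table
#'
#' @param bridges list of `bridge` objects (scored).
#' @param path output TSV path.
#' @export
write_bridge_tsv <- function(bridges, path) {
  df <- do.call(rbind, lapply(bridges, function(b) data.frame(
    start = paste0(b$start_id, b$start_strand),
    end = paste0(b$end_id, b$end_strand),
    kind = b$kind, support = b$support,
    quality = round(b$quality, 2),
    path = if (!is.null(b$path) && nrow(b$path))
      paste0(b$path$id, b$path$strand, collapse = ",") else "",
    stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(start = character(), end = character(),
                                    kind = character(), support = integer(),
                                    quality = numeric(), path = character())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
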