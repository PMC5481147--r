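#' Bidirected assembly graph
#'
#' An assembly graph holds contig segments (id, sequence, depth) and oriented
#' links between segment ends, each with a non-negative end overlap in bp.
#' Every link is stored together with its reverse-complement twin, so the
#' link table is closed under twin reversal.  A self-link from a segment's
#' end to its own start marks a circular replicon.
#'
#' @param segments data.frame with columns `id` (character, unique),
#'   `sequence` (character, non-empty A/C/G/T) and `depth` (positive).
#'   An optional `members` column records merge provenance.
#' @param links data.frame with columns `from_id`, `from_strand`, `to_id`,
#'   `to_strand`, `overlap`; may be empty.  Missing twin links are added.
#' @param k_overlap uniform graph overlap in bp (0 allowed).
#' @return object of class `assembly_graph`.
#' @export
assembly_graph <- function(segments, links = empty_links(), k_overlap = 0L) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence", "depth") %in% names(segments)))
    stop("segments needs columns id, sequence, depth")
  segments$id <- as.character(segments$id)
  if (anyDuplicated(segments$id)) stop("duplicate segment ids")
  if (any(nchar(segments$sequence) < 1L)) stop("empty segment sequence")
  if (any(segments$depth <= 0)) stop("segment depth must be positive")
  if (is.null(segments$members)) segments$members <- segments$id
  links <- normalise_links(links)
  unknown <- setdiff(c(links$from_id, links$to_id), segments$id)
  if (length(unknown))
    stop("link references unknown segment(s): ", paste(unknown, collapse = ", "))
  links <- add_twin_links(links)
  seglen <- setNames(nchar(segments$sequence), segments$id)
  bad <- links$overlap >= pmin(seglen[links$from_id], seglen[links$to_id])
  if (any(bad))
    stop("link overlap not smaller than segment length (",
         paste(unique(links$from_id[bad]), collapse = ", "), ")")
  g <- list(segments = segments[, c("id", "sequence", "depth", "members")],
            links = links, k_overlap = as.integer(k_overlap))
  class(g) <- "assembly_graph"
  g
}

empty_links <- function() {
  data.frame(from_id = character(), from_strand = character(),
             to_id = character(), to_strand = character(),
             overlap = integer(), stringsAsFactors = FALSE)
}

normalise_links <- function(links) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (nrow(links) == 0) return(empty_links())
  need <- c("from_id", "from_strand", "to_id", "to_strand", "overlap")
  if (!all(need %in% names(links))) stop("links needs columns ", paste(need, collapse = ", "))
  links$from_id <- as.character(links$from_id)
  links$to_id <- as.character(links$to_id)
  links$overlap <- as.integer(links$overlap)
  if (any(links$overlap < 0)) stop("negative link overlap")
  if (!all(c(links$from_strand, links$to_strand) %in% c("+", "-")))
    stop("strands must be '+' or '-'")
  links[, need]
}

link_key <- function(links) {
  paste(links$from_id, links$from_strand, links$to_id, links$to_strand, links$overlap)
}

twin_of <- function(links) {
  data.frame(from_id = links$to_id, from_strand = flip_strand(links$to_strand),
             to_id = links$from_id, to_strand = flip_strand(links$from_strand),
             overlap = links$overlap, stringsAsFactors = FALSE)
}

add_twin_links <- function(links) {
  all <- rbind(links, twin_of(links))
  all <- all[!duplicated(link_key(all)), , drop = FALSE]
  all <- all[order(all$from_id, all$from_strand, all$to_id, all$to_strand), , drop = FALSE]
  rownames(all) <- NULL
  all
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat("assembly_graph:", nrow(x$segments), "segments,",
      nrow(x$links) / 2, "links (plus twins),",
      sum(nchar(x$segments$sequence)), "bp,",
      dead_end_count(x), "dead ends\n")
  invisible(x)
}

segment_lengths <- function(graph) {
  setNames(nchar(graph$segments$sequence), graph$segments$id)
}

segment_seq <- function(graph, id, strand = "+") {
  s <- graph$segments$sequence[match(id, graph$segments$id)]
  if (strand == "-") revcomp(s) else s
}

# links leaving oriented segment (id, strand)
out_links <- function(graph, id, strand) {
  graph$links[graph$links$from_id == id & graph$links$from_strand == strand, ,
              drop = FALSE]
}

# links entering oriented segment (id, strand) == twins of out_links of flip
in_links <- function(graph, id, strand) {
  graph$links[graph$links$to_id == id & graph$links$to_strand == strand, ,
              drop = FALSE]
}

#' Count dead ends
#'
#' A dead end is a segment end (each segment has two) with no incident link.
#'
#' @param graph an [assembly_graph].
#' @return non-negative integer.
#' @export
dead_end_count <- function(graph) {
  if (nrow(graph$segments) == 0) return(0L)
  fw <- paste(graph$links$from_id, graph$links$from_strand)
  n <- 0L
  for (id in graph$segments$id) {
    if (!(paste(id, "+") %in% fw)) n <- n + 1L  # right end open
    if (!(paste(id, "-") %in% fw)) n <- n + 1L  # left end open
  }
  n
}

#' Length-weighted median depth of a graph
#'
#' Each base votes with its segment's depth, making the median robust to
#' many short high-copy segments.
#'
#' @param graph an [assembly_graph].
#' @return positive real.
#' @export
median_depth <- function(graph) {
  len <- nchar(graph$segments$sequence)
  d <- graph$segments$depth
  o <- order(d)
  d <- d[o]; len <- len[o]
  cum <- cumsum(as.numeric(len))
  d[which(cum >= sum(as.numeric(len)) / 2)[1]]
}

#' Remove segments (and their links) from a graph
#'
#' @param graph an [assembly_graph].
#' @param ids character vector of segment ids.
#' @return modified graph.
#' @export
remove_segments <- function(graph, ids) {
  keep <- !(graph$segments$id %in% ids)
  segs <- graph$segments[keep, , drop = FALSE]
  links <- graph$links[!(graph$links$from_id %in% ids) &
                       !(graph$links$to_id %in% ids), , drop = FALSE]
  rownames(segs) <- rownames(links) <- NULL
  graph$segments <- segs
  graph$links <- links
  graph
}

# ---- GFA1 I/O ---------------------------------------------------------------

#' Read a GFA1 assembly graph
#'
#' Understands S and L lines.  Segment depth is taken from a `DP:f:` tag,
#' else `dp:f:`, else `KC:i:` divided by sequence length, else 1.0.  Link
#' CIGARs must be pure match (`<N>M`, or `*`/`0M` for no overlap).  Missing
#' twin links are added on read.
#'
#' @param path GFA file path.
#' @return an [assembly_graph].
#' @export
read_gfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seg_id <- character(); seg_seq <- character(); seg_depth <- numeric()
  lk <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") {
      if (length(f) < 3 || !nzchar(f[3]) || f[3] == "*")
        stop("malformed S line at line ", i)
      tags <- if (length(f) > 3) f[-(1:3)] else character()
      depth <- NA_real_
      dp <- grep("^DP:f:", tags, value = TRUE)
      dplo <- grep("^dp:f:", tags, value = TRUE)
      kc <- grep("^KC:i:", tags, value = TRUE)
      if (length(dp)) depth <- as.numeric(sub("^DP:f:", "", dp[1]))
      else if (length(dplo)) depth <- as.numeric(sub("^dp:f:", "", dplo[1]))
      else if (length(kc)) depth <- as.numeric(sub("^KC:i:", "", kc[1])) / nchar(f[3])
      else depth <- 1.0
      if (is.na(depth)) stop("malformed depth tag at line ", i)
      seg_id <- c(seg_id, f[2]); seg_seq <- c(seg_seq, toupper(f[3]))
      seg_depth <- c(seg_depth, depth)
    } else if (f[1] == "L") {
      if (length(f) < 6) stop("malformed L line at line ", i)
      cig <- f[6]
      if (cig == "*") ov <- 0L
      else if (grepl("^[0-9]+M$", cig)) ov <- as.integer(sub("M$", "", cig))
      else stop("non-pure-match CIGAR '", cig, "' at line ", i)
      if (!all(c(f[3], f[5]) %in% c("+", "-")))
        stop("malformed strand at line ", i)
      lk[[length(lk) + 1L]] <- data.frame(
        from_id = f[2], from_strand = f[3], to_id = f[4], to_strand = f[5],
        overlap = ov, stringsAsFactors = FALSE)
    }
    # other record types ignored
  }
  links <- if (length(lk)) do.call(rbind, lk) else empty_links()
  unknown <- setdiff(c(links$from_id, links$to_id), seg_id)
  if (length(unknown))
    stop("L line references unknown segment(s): ", paste(unknown, collapse = ", "))
  k_overlap <- if (nrow(links)) max(links$overlap) else 0L
  assembly_graph(
    data.frame(id = seg_id, sequence = seg_seq, depth = seg_depth,
               stringsAsFactors = FALSE),
    links, k_overlap = k_overlap)
}

#' Write a graph as GFA1
#'
#' Deterministic: segments sorted by descending length then id; one L line
#' per twin pair.  S lines carry `LN:i:` and `DP:f:` tags.
#'
#' @param graph an [assembly_graph].
#' @param path output path.
#' @export
write_gfa <- function(graph, path) {
  segs <- graph$segments
  o <- order(-nchar(segs$sequence), segs$id)
  segs <- segs[o, , drop = FALSE]
  s_lines <- sprintf("S\t%s\t%s\tLN:i:%d\tDP:f:%s",
                     segs$id, segs$sequence, nchar(segs$sequence),
                     formatC(segs$depth, format = "f", digits = 4))
  links <- graph$links
  l_lines <- character()
  if (nrow(links)) {
    key <- link_key(links)
    tkey <- link_key(twin_of(links))
    keep <- key <= tkey  # canonical member of each twin pair (self-twins kept once)
    links <- links[keep, , drop = FALSE]
    links <- links[order(links$from_id, links$from_strand, links$to_id,
                         links$to_strand), , drop = FALSE]
    l_lines <- sprintf("L\t%s\t%s\t%s\t%s\t%dM",
                       links$from_id, links$from_strand,
                       links$to_id, links$to_strand, links$overlap)
  }
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}

#' Export graph segments as FASTA
#'
#' Headers carry id, length and depth; optional `circular=true` flags.
#'
#' @param graph an [assembly_graph].
#' @param path output path.
#' @param circular_ids ids of segments to flag as circular.
#' @param comment extra header comment appended to every record.
#' @export
write_graph_fasta <- function(graph, path, circular_ids = character(),
                              comment = NULL) {
  segs <- graph$segments
  o <- order(-nchar(segs$sequence), segs$id)
  segs <- segs[o, , drop = FALSE]
  hdr <- sprintf("%s length=%d depth=%.4fx circular=%s", segs$id,
                 nchar(segs$sequence), segs$depth,
                 ifelse(segs$id %in% circular_ids, "true", "false"))
  if (!is.null(comment)) hdr <- paste(hdr, comment)
  write_fasta(setNames(segs$sequence, hdr), path)
}

# structural equality for tests and round-trip checks
graph_identical <- function(a, b, tol = 1e-6) {
  sa <- a$segments[order(a$segments$id), c("id", "sequence", "depth")]
  sb <- b$segments[order(b$segments$id), c("id", "sequence", "depth")]
  if (!identical(sa$id, sb$id) || !identical(sa$sequence, sb$sequence)) return(FALSE)
  if (any(abs(sa$depth - sb$depth) > tol)) return(FALSE)
  setequal(link_key(a$links), link_key(b$links))
}

# ---- structural edits -------------------------------------------------------

oriented_concat <- function(graph, path_ids, path_strands, overlaps) {
  # overlap-aware concatenation of an oriented path; overlaps[i] joins i to i+1
  seqs <- mapply(segment_seq, id = path_ids, strand = path_strands,
                 MoreArgs = list(graph = graph), USE.NAMES = FALSE)
  if (length(seqs) == 1) return(seqs)
  out <- seqs[1]
  for (i in 2:length(seqs)) {
    ov <- overlaps[i - 1]
    out <- paste0(out, substr(seqs[i], ov + 1L, nchar(seqs[i])))
  }
  out
}

new_segment_id <- function(graph, prefix) {
  n <- 1L
  repeat {
    id <- sprintf("%s%d", prefix, n)
    if (!(id %in% graph$segments$id)) return(id)
    n <- n + 1L
  }
}

#' Merge unbranching paths
#'
#' Every maximal path whose internal junctions have exactly one in-link and
#' one out-link, and all of whose members satisfy `mergeable`, becomes a
#' single segment: the overlap-aware concatenation of the member sequences,
#' with depth the length-weighted mean of member depths.  Links at the path
#' ends are preserved; a fully circular mergeable cycle becomes one segment
#' with a self-link.  Merged segments receive fresh ids and record their
#' oriented members in the `members` column.
#'
#' @param graph an [assembly_graph].
#' @param mergeable predicate `function(segment_id) -> logical`; default
#'   accepts every segment.
#' @return modified graph.
#' @export
merge_unbranching_paths <- function(graph, mergeable = function(id) TRUE) {
  ok <- vapply(graph$segments$id, mergeable, logical(1))
  names(ok) <- graph$segments$id

  n_out <- table(paste(graph$links$from_id, graph$links$from_strand))
  out1 <- function(id, strand) {
    l <- out_links(graph, id, strand)
    if (nrow(l) != 1) NULL else l
  }
  # edge (id,strand) -> next is contractible if unique out, unique in at
  # target, both mergeable, distinct segments
  step <- function(id, strand) {
    l <- out1(id, strand)
    if (is.null(l)) return(NULL)
    tin <- in_links(graph, l$to_id, l$to_strand)
    if (nrow(tin) != 1) return(NULL)
    if (!isTRUE(ok[[id]]) || !isTRUE(ok[[l$to_id]])) return(NULL)
    l
  }

  used <- character()
  chains <- list()
  for (sid in graph$segments$id) {
    if (sid %in% used || !isTRUE(ok[[sid]])) next
    ids <- sid; strands <- "+"; ovs <- integer(); circular <- FALSE
    # forward
    repeat {
      tail_n <- length(ids)
      l <- step(ids[tail_n], strands[tail_n])
      if (is.null(l)) break
      if (l$to_id == ids[1] && l$to_strand == strands[1]) {
        circular <- TRUE; close_ov <- l$overlap; break
      }
      if (l$to_id %in% ids) break
      ids <- c(ids, l$to_id); strands <- c(strands, l$to_strand)
      ovs <- c(ovs, l$overlap)
    }
    # backward (skip if circular: chain already closed)
    if (!circular) {
      repeat {
        # in-edge of head == out-edge of flipped head, reversed
        l <- NULL
        fl <- out_links(graph, ids[1], flip_strand(strands[1]))
        if (nrow(fl) == 1) {
          # candidate predecessor is flip of fl's target
          pid <- fl$to_id; pstr <- flip_strand(fl$to_strand)
          # contractibility of edge (pid,pstr) -> head
          cand <- step(pid, pstr)
          if (!is.null(cand) && cand$to_id == ids[1] && cand$to_strand == strands[1])
            l <- list(id = pid, strand = pstr, overlap = cand$overlap)
        }
        if (is.null(l)) break
        if (l$id %in% ids) break
        ids <- c(l$id, ids); strands <- c(l$strand, strands)
        ovs <- c(l$overlap, ovs)
      }
    }
    if (length(ids) > 1) {
      chains[[length(chains) + 1L]] <- list(ids = ids, strands = strands,
                                            ovs = ovs, circular = circular,
                                            close_ov = if (circular) close_ov else NA_integer_)
      used <- c(used, ids)
    }
  }
  if (!length(chains)) return(graph)

  segs <- graph$segments
  links <- graph$links
  lens <- segment_lengths(graph)
  for (ch in chains) {
    newid <- new_segment_id(graph, "m")
    graph$segments <- rbind(graph$segments,
      data.frame(id = newid, sequence = "N", depth = 1, members = "",
                 stringsAsFactors = FALSE))  # reserve id
    seqc <- oriented_concat(graph, ch$ids, ch$strands, ch$ovs)
    w <- as.numeric(lens[ch$ids])
    dep <- sum(segs$depth[match(ch$ids, segs$id)] * w) / sum(w)
    mem <- paste0(ch$ids, ch$strands, collapse = ",")
    head_id <- ch$ids[1]; head_str <- ch$strands[1]
    tail_id <- ch$ids[length(ch$ids)]; tail_str <- ch$strands[length(ch$ids)]
    # drop exactly the chain edges (and their twins)
    n <- length(ch$ids)
    chain_edges <- data.frame(
      from_id = ch$ids[-n], from_strand = ch$strands[-n],
      to_id = ch$ids[-1], to_strand = ch$strands[-1],
      overlap = ch$ovs, stringsAsFactors = FALSE)
    if (ch$circular)
      chain_edges <- rbind(chain_edges, data.frame(
        from_id = ch$ids[n], from_strand = ch$strands[n],
        to_id = ch$ids[1], to_strand = ch$strands[1],
        overlap = ch$close_ov, stringsAsFactors = FALSE))
    dropkeys <- c(link_key(chain_edges), link_key(twin_of(chain_edges)))
    links <- links[!(link_key(links) %in% dropkeys), , drop = FALSE]
    # remap external links
    remap <- function() {
      # "to" endpoints entering the chain head -> (new, +) / leaving flip -> handled by from
      sel_to_head <- links$to_id == head_id & links$to_strand == head_str
      links$to_id[sel_to_head] <<- newid; links$to_strand[sel_to_head] <<- "+"
      sel_from_headflip <- links$from_id == head_id & links$from_strand == flip_strand(head_str)
      links$from_id[sel_from_headflip] <<- newid; links$from_strand[sel_from_headflip] <<- "-"
      sel_from_tail <- links$from_id == tail_id & links$from_strand == tail_str
      links$from_id[sel_from_tail] <<- newid; links$from_strand[sel_from_tail] <<- "+"
      sel_to_tailflip <- links$to_id == tail_id & links$to_strand == flip_strand(tail_str)
      links$to_id[sel_to_tailflip] <<- newid; links$to_strand[sel_to_tailflip] <<- "-"
    }
    remap()
    if (ch$circular) {
      links <- rbind(links, data.frame(
        from_id = newid, from_strand = "+", to_id = newid, to_strand = "+",
        overlap = ch$close_ov, stringsAsFactors = FALSE))
    }
    i <- match(newid, graph$segments$id)
    graph$segments$sequence[i] <- seqc
    graph$segments$depth[i] <- dep
    graph$segments$members[i] <- mem
  }
  graph$segments <- graph$segments[!(graph$segments$id %in% used), , drop = FALSE]
  rownames(graph$segments) <- NULL
  graph$links <- add_twin_links(links)
  graph
}

#' Remove link overlaps by trimming segment ends
#'
#' Assigns each physical segment end a trim amount so every junction's two
#' trims sum to its overlap (each shared overlap sequence is kept exactly
#' once), trims the sequences, and sets all link overlaps to zero.  Trim
#' assignment 2-colours each junction-graph component with `{0, overlap}`;
#' a non-bipartite component falls back to `overlap/2` per end (exact for
#' even overlaps, as produced by odd-k de Bruijn graphs).
#'
#' @param graph an [assembly_graph].
#' @return graph with all overlaps 0.
#' @export
trim_overlaps <- function(graph) {
  links <- graph$links
  if (!nrow(links) || all(links$overlap == 0)) {
    graph$k_overlap <- 0L
    graph$links$overlap <- integer(nrow(graph$links))
    return(graph)
  }
  # physical ends: "<id> L" (start of + strand) and "<id> R" (end of +)
  end_of <- function(id, strand) paste(id, ifelse(strand == "+", "R", "L"))
  start_of <- function(id, strand) paste(id, ifelse(strand == "+", "L", "R"))
  # one junction per twin pair
  key <- link_key(links); tkey <- link_key(twin_of(links))
  jx <- links[key <= tkey, , drop = FALSE]
  jx <- jx[jx$overlap > 0, , drop = FALSE]
  e1 <- end_of(jx$from_id, jx$from_strand)
  e2 <- start_of(jx$to_id, jx$to_strand)
  ends <- unique(c(e1, e2))
  trim <- setNames(rep(NA_real_, length(ends)), ends)
  seglen <- segment_lengths(graph)
  end_seg <- sub(" [LR]$", "", ends)
  # total trim a segment would receive, treating unassigned ends as 0
  seg_total <- function(tr, id) {
    v <- tr[end_seg == id]
    sum(v[!is.na(v)])
  }
  # adjacency of ends through junctions
  jx_of_end <- split(rep(seq_len(nrow(jx)), 2), c(e1, e2))
  for (root in ends) {
    if (!is.na(trim[root])) next
    local <- setNames(rep(NA_real_, length(ends)), ends)
    local[root] <- 0
    queue <- root
    comp <- root
    conflict <- FALSE
    while (length(queue)) {
      e <- queue[1]; queue <- queue[-1]
      for (ji in jx_of_end[[e]]) {
        other <- if (e1[ji] == e) e2[ji] else e1[ji]
        # self-junction (palindromic / circular single end)
        if (other == e) {
          if (abs(2 * local[e] - jx$overlap[ji]) > 0) conflict <- TRUE
          next
        }
        want <- jx$overlap[ji] - local[e]
        if (is.na(local[other])) {
          local[other] <- want
          queue <- c(queue, other); comp <- c(comp, other)
        } else if (local[other] != want) conflict <- TRUE
      }
    }
    ovs <- unique(jx$overlap[e1 %in% comp | e2 %in% comp])
    uniform_even <- length(ovs) == 1 && ovs %% 2 == 0
    variants <- list()
    if (!conflict) {
      variants <- list(local[comp])
      if (length(ovs) == 1) variants[[2]] <- ovs - local[comp]  # flipped colouring
    }
    if (uniform_even)
      variants[[length(variants) + 1L]] <- setNames(rep(ovs / 2, length(comp)), comp)
    if (!length(variants))
      stop("cannot assign consistent end trims in component containing ",
           comp[1])
    # pick the first variant that empties no segment
    chosen <- NULL
    for (v in variants) {
      tr <- trim; tr[comp] <- v
      bad <- any(vapply(unique(end_seg[match(comp, ends)]),
                        function(id) seg_total(tr, id) >= seglen[[id]],
                        logical(1)))
      if (!bad) { chosen <- v; break }
    }
    if (is.null(chosen)) chosen <- variants[[1]]  # error surfaces below
    trim[comp] <- chosen
  }
  if (any(trim < 0, na.rm = TRUE))
    stop("negative trim demanded; inconsistent overlaps")
  segs <- graph$segments
  for (i in seq_len(nrow(segs))) {
    tl <- trim[paste(segs$id[i], "L")]; tr <- trim[paste(segs$id[i], "R")]
    tl <- if (is.na(tl)) 0 else tl
    tr <- if (is.na(tr)) 0 else tr
    len <- nchar(segs$sequence[i])
    if (tl + tr >= len)
      stop("overlap trimming would empty segment ", segs$id[i])
    segs$sequence[i] <- substr(segs$sequence[i], tl + 1L, len - tr)
  }
  graph$segments <- segs
  graph$links$overlap <- integer(nrow(graph$links))
  graph$k_overlap <- 0L
  graph
}
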