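#' Alignment scoring scheme
#'
#' Affine-gap convention: a gap of length g costs `gap_open + g * gap_extend`.
#' The defaults (+3/-6/-5/-2) are tolerant of reads around 70% identity and
#' are fully configurable.
#'
#' @param match positive match score.
#' @param mismatch mismatch score (<= 0).
#' @param gap_open gap-open score (<= 0).
#' @param gap_extend per-base gap-extension score (<= 0).
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 3L, mismatch = -6L, gap_open = -5L,
                           gap_extend = -2L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

finish_alignment <- function(raw, a, b) {
  if (!isTRUE(raw$found)) return(NULL)
  structure(list(score = raw$score, cigar = raw$cigar,
                 a_interval = c(raw$a_start, raw$a_end),
                 b_interval = c(raw$b_start, raw$b_end),
                 identity = if (raw$columns > 0) raw$matches / raw$columns else 0,
                 matches = raw$matches, columns = raw$columns),
            class = "semiglobal_alignment")
}

#' Optimal semi-global alignment by full dynamic programming
#'
#' End-gap-free alignment: leading and trailing gaps on both sequences are
#' free, so an alignment can only terminate at a sequence end.  Intended as
#' the exact reference at oracle scale (a few kbp).
#'
#' @param a,b non-empty DNA strings.
#' @param scoring a [scoring_scheme()].
#' @return `semiglobal_alignment` (score, CIGAR relative to `a`, 0-based
#'   half-open intervals on both sequences, identity) or NULL when no
#'   positive-scoring alignment exists.
#' @export
semiglobal_align <- function(a, b, scoring = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  raw <- .semiglobal_full_cpp(a, b, scoring$match, scoring$mismatch,
                              scoring$gap_open, scoring$gap_extend)
  finish_alignment(raw, a, b)
}

# 13-mer index of a target sequence: named list kmer -> start positions (1-based)
kmer_index <- function(seq, k = 13L, max_occ = 16L) {
  n <- nchar(seq)
  if (n < k) return(list())
  km <- substring(seq, 1:(n - k + 1), k:n)
  idx <- split(seq_len(n - k + 1), km)
  idx[lengths(idx) <= max_occ]
}

read_kmers <- function(read, k = 13L) {
  n <- nchar(read)
  if (n < k) return(character(0))
  substring(read, 1:(n - k + 1), k:n)
}

# one index over all contigs: kmer -> global positions on the padded
# concatenation; `breaks`/`starts` map global positions back to contigs
combined_kmer_index <- function(contigs, k = 13L, max_occ = 16L) {
  pad <- strrep("#", k)
  cat_seq <- paste(contigs, collapse = pad)
  starts <- cumsum(c(1L, head(nchar(contigs) + k, -1L)))
  names(starts) <- names(contigs)
  list(index = kmer_index(cat_seq, k = k, max_occ = max_occ),
       starts = starts, lens = nchar(contigs), k = k)
}

# core chain step on precollected seeds (1-based positions)
chain_seeds <- function(qpos, tpos, min_seeds = 3L, bucket = 500L,
                        max_diag_step = 100L) {
  dg <- tpos - qpos
  b <- floor(dg / bucket)
  cnt <- table(b)
  bv <- as.integer(names(cnt))
  score3 <- vapply(bv, function(x)
    sum(cnt[as.character(c(x - 1L, x, x + 1L))], na.rm = TRUE), 0)
  best_b <- bv[which.max(score3)]
  keep <- b >= best_b - 1L & b <= best_b + 1L
  qpos <- qpos[keep]; tpos <- tpos[keep]
  o <- order(qpos, -tpos)
  tp <- tpos[o]; qp <- qpos[o]
  tails <- integer(0)
  tails_i <- integer(0)
  parent <- integer(length(tp))
  for (i in seq_along(tp)) {
    j <- findInterval(tp[i] - 1L, tails) + 1L
    parent[i] <- if (j > 1) tails_i[j - 1] else 0L
    tails[j] <- tp[i]
    tails_i[j] <- i
  }
  L <- length(tails)
  if (L < min_seeds) return(NULL)
  chain <- integer(L)
  i <- tails_i[L]
  for (d in L:1) { chain[d] <- i; i <- parent[i] }
  diag <- tp[chain] - qp[chain]
  grp <- cumsum(c(0L, abs(diff(diag)) > max_diag_step))
  runs <- split(seq_along(chain), grp)
  best <- runs[[which.max(lengths(runs))]]
  if (length(best) < min_seeds) return(NULL)
  diag <- diag[best]
  list(n_seeds = length(best), dlo = min(diag), dhi = max(diag),
       q_range = range(qp[chain[best]]), t_range = range(tp[chain[best]]))
}

# seed chain between read and target: returns diagonal corridor or NULL.
# The dominant diagonal band is selected first (so seeds from distinct
# repeat copies cannot inflate the corridor), then seeds are chained by
# longest-increasing-subsequence and trimmed to the longest
# diagonal-coherent run.
seed_chain <- function(read, tindex, k = 13L, min_seeds = 3L,
                       bucket = 500L, max_diag_step = 100L, km = NULL) {
  if (is.null(km)) km <- read_kmers(read, k)
  if (!length(km)) return(NULL)
  hit <- tindex[km]
  nh <- lengths(hit)
  if (!any(nh > 0)) return(NULL)
  qpos <- rep(seq_along(km), nh)
  tpos <- unlist(hit, use.names = FALSE)
  chain_seeds(qpos, tpos, min_seeds = min_seeds, bucket = bucket,
              max_diag_step = max_diag_step)
}

#' Seeded, banded semi-global alignment
#'
#' Exact 13-mer seeds are chained by longest-increasing-subsequence over
#' diagonals; banded dynamic programming within `band` of the chain's
#' diagonal range reproduces the optimal alignment whenever the optimum
#' stays inside the corridor.  Returns NULL when no chain of at least
#' `min_seeds` seeds exists.
#'
#' @inheritParams semiglobal_align
#' @param read,target non-empty DNA strings.
#' @param band corridor half-width in bp around the chained diagonals.
#' @param min_seeds minimum seeds in the best chain.
#' @param tindex optional precomputed [kmer_index()] of `target`.
#' @return `semiglobal_alignment` or NULL.
#' @export
seeded_align <- function(read, target, scoring = scoring_scheme(), band = 75L,
                         min_seeds = 3L, tindex = NULL, km = NULL) {
  if (!nzchar(read) || !nzchar(target)) stop("empty sequence")
  if (is.null(tindex)) tindex <- kmer_index(target)
  ch <- seed_chain(read, tindex, min_seeds = min_seeds, km = km)
  if (is.null(ch)) return(NULL)
  dlo <- ch$dlo - band; dhi <- ch$dhi + band
  # clamp corridor area, centring on the chain, to bound memory
  max_w <- max(2L * band + 1L, as.integer(4e7 / (nchar(read) + 1)))
  if (dhi - dlo + 1L > max_w) {
    mid <- as.integer((ch$dlo + ch$dhi) / 2)
    dlo <- mid - max_w %/% 2L; dhi <- mid + max_w %/% 2L
  }
  raw <- .semiglobal_banded_cpp(read, target, scoring$match, scoring$mismatch,
                                scoring$gap_open, scoring$gap_extend,
                                dlo, dhi)
  finish_alignment(raw, read, target)
}

#' Align long reads to single-copy contigs
#'
#' Both strands are searched.  Per read, alignments with identity at least
#' `min_identity` are kept greedily by score, rejecting overlaps on the
#' read.  Coordinates are always reported on the forward contig strand;
#' `read_start`/`read_end` are on the original read.
#'
#' @param reads named character vector of read sequences.
#' @param contigs named character vector of contig sequences.
#' @param scoring a [scoring_scheme()].
#' @param min_identity identity cut-off (default 0.6, admitting the worst
#'   simulated accuracy tier).
#' @param band corridor half-width for [seeded_align()].
#' @param max_read_overlap tolerated overlap in bp between kept alignments
#'   on the same read.
#' @return data.frame with one row per kept alignment: read, contig, strand,
#'   read_start/read_end and contig_start/contig_end (0-based half-open),
#'   score, identity, cigar, reaches_contig_start, reaches_contig_end.
#' @export
align_long_reads <- function(reads, contigs, scoring = scoring_scheme(),
                             min_identity = 0.6, band = 75L,
                             max_read_overlap = 50L) {
  stopifnot(!is.null(names(reads)), !is.null(names(contigs)))
  cidx <- combined_kmer_index(contigs)
  clen <- nchar(contigs)
  cend <- cidx$starts + cidx$lens - 1L
  rows <- list()
  for (rn in names(reads)) {
    rfw <- reads[[rn]]
    rrc <- revcomp(rfw)
    rl <- nchar(rfw)
    cand <- list()
    for (strand in c("+", "-")) {
      rseq <- if (strand == "+") rfw else rrc
      km <- read_kmers(rseq)
      if (!length(km)) next
      hit <- cidx$index[km]
      nh <- lengths(hit)
      if (!any(nh > 0)) next
      qpos <- rep(seq_along(km), nh)
      gpos <- unlist(hit, use.names = FALSE)
      ci <- findInterval(gpos, cidx$starts)
      for (cu in unique(ci)) {
        cn <- names(contigs)[cu]
        sel <- ci == cu & gpos <= cend[cu]
        if (sum(sel) < 3L) next
        ch <- chain_seeds(qpos[sel], gpos[sel] - cidx$starts[[cu]] + 1L)
        if (is.null(ch)) next
        raw <- .semiglobal_banded_cpp(rseq, contigs[[cn]], scoring$match,
                                      scoring$mismatch, scoring$gap_open,
                                      scoring$gap_extend,
                                      ch$dlo - band, ch$dhi + band)
        al <- finish_alignment(raw, rseq, contigs[[cn]])
        if (is.null(al) || al$identity < min_identity) next
        rs <- al$a_interval[1]; re <- al$a_interval[2]
        if (strand == "-") { tmp <- rs; rs <- rl - re; re <- rl - tmp }
        cand[[length(cand) + 1L]] <- data.frame(
          read = rn, contig = cn, strand = strand,
          read_start = rs, read_end = re,
          contig_start = al$b_interval[1], contig_end = al$b_interval[2],
          score = al$score, identity = al$identity, cigar = al$cigar,
          read_length = rl,
          reaches_contig_start = al$b_interval[1] == 0L,
          reaches_contig_end = al$b_interval[2] == clen[[cn]],
          stringsAsFactors = FALSE)
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$score), , drop = FALSE]
    kept <- cand[0, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      s <- cand$read_start[i]; e <- cand$read_end[i]
      ov <- pmin(kept$read_end, e) - pmax(kept$read_start, s)
      if (!nrow(kept) || all(ov <= max_read_overlap)) kept <- rbind(kept, cand[i, ])
    }
    rows[[length(rows) + 1L]] <- kept
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consensus of spanning fragments
#'
#' Single fragment: returned unchanged.  Otherwise the fragment with the
#' highest summed pairwise alignment score becomes the backbone; all other
#' fragments are aligned to it end-gap-free and each backbone column is
#' called by majority vote over bases, deletions and insertions.
#'
#' @param fragments character vector of DNA strings (length >= 1).
#' @param scoring a [scoring_scheme()].
#' @param max_fragments at most this many fragments are used (longest-score
#'   backbone selection is quadratic).
#' @return consensus DNA string.
#' @export
consensus_sequence <- function(fragments, scoring = scoring_scheme(),
                               max_fragments = 10L) {
  if (!length(fragments)) stop("no fragments")
  fragments <- fragments[nzchar(fragments)]
  if (!length(fragments)) return("")
  if (length(fragments) == 1) return(fragments[[1]])
  if (length(fragments) > max_fragments) {
    # keep fragments closest to the median length
    med <- median(nchar(fragments))
    fragments <- fragments[order(abs(nchar(fragments) - med))][1:max_fragments]
  }
  n <- length(fragments)
  pair_band <- function(a, b) {
    d <- nchar(b) - nchar(a)
    c(min(0L, d) - 150L, max(0L, d) + 150L)
  }
  scores <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    bd <- pair_band(fragments[i], fragments[j])
    raw <- .semiglobal_banded_cpp(fragments[i], fragments[j],
                                  scoring$match, scoring$mismatch,
                                  scoring$gap_open, scoring$gap_extend,
                                  bd[1], bd[2])
    scores[i, j] <- scores[j, i] <- raw$score
  }
  bb <- which.max(rowSums(scores))
  backbone <- fragments[[bb]]
  bl <- nchar(backbone)
  bchars <- strsplit(backbone, "")[[1]]
  base_votes <- matrix(0L, nrow = 5, ncol = bl,
                       dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  base_votes[cbind(match(bchars, rownames(base_votes)), seq_len(bl))] <- 1L
  cov <- rep(1L, bl)  # backbone votes everywhere
  ins <- vector("list", bl + 1)  # insertions after backbone position i (0..bl)
  for (f in setdiff(seq_len(n), bb)) {
    frag <- fragments[[f]]
    bd <- pair_band(frag, backbone)
    raw <- .semiglobal_banded_cpp(frag, backbone, scoring$match,
                                  scoring$mismatch, scoring$gap_open,
                                  scoring$gap_extend, bd[1], bd[2])
    if (!isTRUE(raw$found)) next
    fpos <- raw$a_start; bpos <- raw$b_start
    fchars <- strsplit(frag, "")[[1]]
    for (op in cigar_ops(raw$cigar)) {
      if (op$op == "M") {
        idx <- (bpos + 1):(bpos + op$n)
        ch <- fchars[(fpos + 1):(fpos + op$n)]
        r <- match(ch, rownames(base_votes))
        okc <- !is.na(r)
        base_votes[cbind(r[okc], idx[okc])] <-
          base_votes[cbind(r[okc], idx[okc])] + 1L
        cov[idx] <- cov[idx] + 1L
        fpos <- fpos + op$n; bpos <- bpos + op$n
      } else if (op$op == "D") {  # gap in fragment over backbone bases
        idx <- (bpos + 1):(bpos + op$n)
        base_votes["-", idx] <- base_votes["-", idx] + 1L
        cov[idx] <- cov[idx] + 1L
        bpos <- bpos + op$n
      } else if (op$op == "I") {  # fragment inserts relative to backbone
        seqi <- substr(frag, fpos + 1, fpos + op$n)
        key <- bpos + 1L
        ins[[key]] <- c(ins[[key]], seqi)
        fpos <- fpos + op$n
      }
    }
  }
  out <- character(0)
  for (j in seq_len(bl)) {
    v <- base_votes[, j]
    call <- names(v)[which.max(v)]
    piece <- if (call == "-") "" else call
    # majority insertion after column j
    insv <- ins[[j + 1L]]
    if (!is.null(insv) && length(insv) * 2 > cov[j]) {
      tab <- sort(table(insv), decreasing = TRUE)
      piece <- paste0(piece, names(tab)[1])
    }
    out[j] <- piece
  }
  # leading insertions (before backbone position 1)
  lead <- ""
  if (!is.null(ins[[1]]) && length(ins[[1]]) * 2 > cov[1]) {
    tab <- sort(table(ins[[1]]), decreasing = TRUE)
    lead <- names(tab)[1]
  }
  paste0(lead, paste(out, collapse = ""))
}

cigar_ops <- function(cigar) {
  if (!nzchar(cigar)) return(list())
  ns <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDSH=X]", cigar))[[1]]
  mapply(function(n, op) list(n = n, op = op), ns, ops,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write alignments as SAM
#'
#' End-gap-free alignments are encoded with soft clips for the unaligned
#' read ends.  Reverse-strand records store the reverse-complemented read,
#' per the SAM convention.
#'
#' @param alignments data.frame from [align_long_reads()].
#' @param reads named character vector of read sequences.
#' @param contigs named character vector of contig sequences.
#' @param path output path.
#' @export
write_sam <- function(alignments, reads, contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (cn in names(contigs))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", cn, nchar(contigs[[cn]])), con)
  if (!nrow(alignments)) return(invisible(path))
  for (i in seq_len(nrow(alignments))) {
    al <- alignments[i, ]
    rseq <- reads[[al$read]]
    rl <- nchar(rseq)
    if (al$strand == "-") {
      rseq <- revcomp(rseq)
      lead <- rl - al$read_end; trail <- al$read_start
    } else {
      lead <- al$read_start; trail <- rl - al$read_end
    }
    cig <- paste0(if (lead > 0) paste0(lead, "S") else "", al$cigar,
                  if (trail > 0) paste0(trail, "S") else "")
    writeLines(paste(al$read, if (al$strand == "-") 16L else 0L, al$contig,
                     al$contig_start + 1L, 60L, cig, "*", 0L, 0L, rseq, "*",
                     sprintf("AS:i:%d", al$score),
                     sprintf("id:f:%.4f", al$identity), sep = "\t"), con)
  }
  invisible(path)
}
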