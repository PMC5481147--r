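#' Simulate a bacterial genome with planted repeats and plasmids
#'
#' Builds circular replicons: one chromosome of uniform-random sequence
#' with planted repeat families (each family one master sequence copied to
#' non-overlapping positions, with optional per-copy divergence applied as
#' substitutions), plus plasmids carried at a per-cell copy number.
#' Repeat copies are planted on the forward strand.  Fully reproducible
#' from `seed`.
#'
#' @param chromosome_length chromosome size in bp.
#' @param repeats list of `list(length=, copies=, divergence=)` with
#'   `copies >= 2` and `divergence` in `[0, 0.05]`.
#' @param plasmids list of `list(length=, cell_copy=)`.
#' @param seed integer RNG seed.
#' @return `synthetic_truth` object: list with `replicons` (data.frame
#'   name, sequence, length, cell_copy) and `repeats` (data.frame replicon,
#'   family, start (0-based), length, strand, divergence).
#' @export
simulate_genome <- function(chromosome_length, repeats = list(),
                            plasmids = list(), seed = 1L) {
  set.seed(seed)
  for (r in repeats) {
    if (r$copies < 2) stop("repeat copy number must be >= 2")
    if (is.null(r$divergence)) r$divergence <- 0
    if (r$divergence < 0 || r$divergence > 0.05) stop("divergence must be in [0, 0.05]")
  }
  chrom <- strsplit(random_dna(chromosome_length), "")[[1]]
  # choose non-overlapping placements for all repeat copies
  placements <- data.frame(replicon = character(), family = integer(),
                           start = integer(), length = integer(),
                           strand = character(), divergence = numeric(),
                           stringsAsFactors = FALSE)
  occupied <- rep(FALSE, chromosome_length)
  margin <- 100L
  occupied[1:margin] <- TRUE                                # keep origin clean
  occupied[(chromosome_length - margin):chromosome_length] <- TRUE
  for (fi in seq_along(repeats)) {
    r <- repeats[[fi]]
    div <- if (is.null(r$divergence)) 0 else r$divergence
    master <- strsplit(random_dna(r$length), "")[[1]]
    for (ci in seq_len(r$copies)) {
      ok <- FALSE
      for (try in 1:1000) {
        s <- sample.int(chromosome_length - r$length - 2L * margin, 1) + margin
        span <- (s - margin):(s + r$length + margin)
        if (!any(occupied[span])) { ok <- TRUE; break }
      }
      if (!ok) stop("cannot place repeat copies without overlap")
      copy <- master
      if (div > 0) {
        nmut <- round(div * r$length)
        if (nmut > 0) {
          pos <- sample.int(r$length, nmut)
          copy[pos] <- vapply(copy[pos], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        }
      }
      chrom[s:(s + r$length - 1L)] <- copy
      occupied[(s - margin):(s + r$length + margin)] <- TRUE
      placements <- rbind(placements, data.frame(
        replicon = "chromosome", family = fi, start = s - 1L,
        length = r$length, strand = "+", divergence = div,
        stringsAsFactors = FALSE))
    }
  }
  reps <- data.frame(name = "chromosome",
                     sequence = paste(chrom, collapse = ""),
                     length = chromosome_length, cell_copy = 1,
                     stringsAsFactors = FALSE)
  for (pi in seq_along(plasmids)) {
    p <- plasmids[[pi]]
    reps <- rbind(reps, data.frame(
      name = sprintf("plasmid%d", pi), sequence = random_dna(p$length),
      length = p$length, cell_copy = p$cell_copy, stringsAsFactors = FALSE))
  }
  structure(list(replicons = reps, repeats = placements),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", nrow(x$replicons), "replicons,",
      sum(x$replicons$length), "bp,", nrow(x$repeats), "repeat placements\n")
  invisible(x)
}

#' Write / read truth as JSON
#' @param truth a `synthetic_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(replicons = truth$replicons,
                            repeats = truth$repeats),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  reps <- as.data.frame(x$repeats, stringsAsFactors = FALSE)
  if (!nrow(reps))
    reps <- data.frame(replicon = character(), family = integer(),
                       start = integer(), length = integer(),
                       strand = character(), divergence = numeric())
  structure(list(replicons = as.data.frame(x$replicons, stringsAsFactors = FALSE),
                 repeats = reps),
            class = "synthetic_truth")
}

#' Build the exact de Bruijn (k-mer) graph of a synthetic genome
#'
#' Constructs the forward-strand de Bruijn graph of the circular replicons:
#' unitigs become segments, links carry (k-1) overlaps, and segment depth is
#' genomic copy count times replicon cell copy number, scaled by
#' `base_depth` and optionally jittered with multiplicative lognormal noise
#' `sigma`.  Also emits truth-derived contig paths: the circular walk of
#' each replicon through the graph, split at repeat segments longer than
#' `insert_size` (emulating what read-pair repeat resolution can span).
#'
#' @param truth a `synthetic_truth` from [simulate_genome()].
#' @param k odd k-mer size, smaller than the shortest replicon.
#' @param sigma multiplicative depth-noise sd (lognormal sdlog; 0 = exact).
#' @param base_depth depth scale for single-copy chromosomal sequence.
#' @param insert_size read-pair insert size in bp limiting which repeats
#'   contig paths may span.
#' @param seed RNG seed for the depth jitter.
#' @return list with `graph` (an [assembly_graph]), `contig_paths` (list of
#'   data.frames id/strand), `multiplicity` (named integer vector of true
#'   per-segment copy numbers).
#' @export
build_kmer_graph <- function(truth, k = 41L, sigma = 0, base_depth = 50,
                             insert_size = 400L, seed = 1L) {
  if (k %% 2 == 0) stop("k must be odd")
  if (k >= min(truth$replicons$length)) stop("k must be smaller than the shortest replicon")
  reps <- truth$replicons
  # enumerate k-mers per replicon (circular)
  km_all <- character(); w_depth <- numeric()
  per_rep <- list()
  for (i in seq_len(nrow(reps))) {
    s <- reps$sequence[i]; L <- nchar(s)
    circ <- paste0(s, substr(s, 1, k - 1))
    km <- substring(circ, 1:L, k:(L + k - 1))
    per_rep[[reps$name[i]]] <- km
    km_all <- c(km_all, km)
    w_depth <- c(w_depth, rep(reps$cell_copy[i], L))
  }
  kmers <- sort(unique(km_all))
  ik <- match(km_all, kmers)           # every genome position -> kmer id
  mult_count <- tabulate(ik, length(kmers))
  depth_count <- as.vector(rowsum(w_depth, ik))
  nodes <- sort(unique(c(substr(kmers, 1, k - 1), substr(kmers, 2, k))))
  pid <- match(substr(kmers, 1, k - 1), nodes)
  sid <- match(substr(kmers, 2, k), nodes)
  out_deg <- tabulate(pid, length(nodes))
  in_deg <- tabulate(sid, length(nodes))
  next_of_node <- integer(length(nodes))   # valid only where out_deg == 1
  next_of_node[pid] <- seq_along(kmers)
  node_simple <- out_deg == 1L & in_deg == 1L

  visited <- logical(length(kmers))
  unitigs <- list()
  walk_from <- function(start) {
    path <- integer(1024); n <- 0L
    cur <- start
    repeat {
      n <- n + 1L
      if (n > length(path)) length(path) <- 2L * length(path)
      path[n] <- cur
      visited[cur] <<- TRUE
      node <- sid[cur]
      if (!node_simple[node]) break
      nxt <- next_of_node[node]
      if (visited[nxt]) break  # closed a cycle (or rejoined)
      cur <- nxt
    }
    path[seq_len(n)]
  }
  # unitigs starting at junction boundaries
  starts <- which(!node_simple[pid])
  for (s0 in starts) if (!visited[s0]) unitigs[[length(unitigs) + 1L]] <- walk_from(s0)
  # leftover isolated cycles
  for (s0 in seq_along(kmers)) if (!visited[s0]) unitigs[[length(unitigs) + 1L]] <- walk_from(s0)

  useq <- vapply(unitigs, function(u) {
    paste0(kmers[u[1]], paste(substr(kmers[u[-1]], k, k), collapse = "")) }, "")
  # deterministic ordering and ids
  o <- order(-nchar(useq), useq)
  unitigs <- unitigs[o]; useq <- useq[o]
  ids <- as.character(seq_along(unitigs))
  umult <- vapply(unitigs, function(u) as.integer(round(mean(mult_count[u]))), 0L)
  udepth_exact <- vapply(unitigs, function(u) mean(depth_count[u]), 0)
  set.seed(seed)
  jitter <- if (sigma > 0) rlnorm(length(unitigs), 0, sigma) else rep(1, length(unitigs))
  udepth <- udepth_exact * base_depth * jitter

  start_node <- vapply(unitigs, function(u) pid[u[1]], 0L)
  end_node <- vapply(unitigs, function(u) sid[u[length(u)]], 0L)
  links <- empty_links()
  for (i in seq_along(unitigs)) {
    js <- which(start_node == end_node[i])
    for (j in js)
      links <- rbind(links, data.frame(
        from_id = ids[i], from_strand = "+", to_id = ids[j], to_strand = "+",
        overlap = k - 1L, stringsAsFactors = FALSE))
  }
  graph <- assembly_graph(
    data.frame(id = ids, sequence = useq, depth = udepth,
               stringsAsFactors = FALSE),
    links, k_overlap = k - 1L)

  # map each k-mer to its unitig and offset for the truth walks
  k2u <- integer(length(kmers)); k2off <- integer(length(kmers))
  for (i in seq_along(unitigs)) {
    k2u[unitigs[[i]]] <- i
    k2off[unitigs[[i]]] <- seq_along(unitigs[[i]])
  }
  contig_paths <- list()
  mult_map <- setNames(umult, ids)
  for (rn in names(per_rep)) {
    kid <- match(per_rep[[rn]], kmers)
    L <- length(kid)
    # rotate so the walk starts at a unitig boundary
    p0 <- which(k2off[kid] == 1L)[1]
    if (is.na(p0)) {
      # whole replicon is one cycle unitig
      contig_paths[[length(contig_paths) + 1L]] <-
        data.frame(id = ids[k2u[kid[1]]], strand = "+", stringsAsFactors = FALSE)
      next
    }
    walk_ids <- character(); p <- p0; consumed <- 0L
    while (consumed < L) {
      u <- k2u[kid[p]]
      walk_ids <- c(walk_ids, ids[u])
      step <- length(unitigs[[u]])
      consumed <- consumed + step
      p <- (p + step - 1L) %% L + 1L
    }
    sep <- mult_map[walk_ids] > 1L & nchar(useq)[match(walk_ids, ids)] > insert_size
    if (any(sep)) {
      # rotate so the walk starts right after a separator, then split runs
      first_sep <- which(sep)[1]
      ord <- c(seq_along(walk_ids), seq_along(walk_ids))[(first_sep + 1):(first_sep + length(walk_ids))]
      walk_ids <- walk_ids[ord]; sep <- sep[ord]
      runs <- split(walk_ids, cumsum(sep))
      for (r in runs) {
        keep <- r[!(mult_map[r] > 1L & nchar(useq)[match(r, ids)] > insert_size)]
        if (length(keep) >= 1)
          contig_paths[[length(contig_paths) + 1L]] <-
            data.frame(id = keep, strand = "+", stringsAsFactors = FALSE)
      }
    } else {
      contig_paths[[length(contig_paths) + 1L]] <-
        data.frame(id = walk_ids, strand = "+", stringsAsFactors = FALSE)
    }
  }
  list(graph = graph, contig_paths = contig_paths, multiplicity = mult_map)
}

#' Simulate error-bearing long reads
#'
#' Read starts are uniform on the circular replicons (reads may wrap),
#' replicons are sampled proportional to length times cell copy number,
#' lengths are gamma-distributed (shape 4) around `mean_len`, strands are
#' uniform, and errors are i.i.d. per base at rate `1 - identity`, split
#' mismatch:insertion:deletion = 50:25:25.
#'
#' @param truth a `synthetic_truth`.
#' @param depth long-read depth relative to single-cell genome content.
#' @param mean_len mean read length in bp.
#' @param identity per-base identity in `[0.5, 1]`.
#' @param seed RNG seed.
#' @param min_len minimum emitted read length.
#' @return named character vector of read sequences; names carry provenance
#'   (`read<i> replicon:start:strand`).
#' @export
simulate_long_reads <- function(truth, depth, mean_len, identity, seed = 1L,
                                min_len = 200L) {
  if (identity < 0.5 || identity > 1) stop("identity must be in [0.5, 1]")
  set.seed(seed)
  reps <- truth$replicons
  w <- reps$length * reps$cell_copy
  n_reads <- max(1L, round(depth * sum(w) / mean_len))
  ri <- sample.int(nrow(reps), n_reads, replace = TRUE, prob = w)
  lens <- pmax(min_len, round(rgamma(n_reads, shape = 4, scale = mean_len / 4)))
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  err <- 1 - identity
  bases <- c("A", "C", "G", "T")
  out <- character(n_reads)
  prov <- character(n_reads)
  for (i in seq_len(n_reads)) {
    L <- reps$length[ri[i]]
    len <- min(lens[i], L)  # cannot exceed one full replicon turn
    start <- sample.int(L, 1)
    doubled <- paste0(reps$sequence[ri[i]], reps$sequence[ri[i]])
    frag <- substr(doubled, start, start + len - 1L)
    if (strands[i] == "-") frag <- revcomp(frag)
    if (err > 0) {
      ch <- strsplit(frag, "")[[1]]
      epos <- which(runif(len) < err)
      if (length(epos)) {
        type <- sample(c("m", "i", "d"), length(epos), replace = TRUE,
                       prob = c(0.5, 0.25, 0.25))
        for (j in seq_along(epos)) {
          p <- epos[j]
          if (type[j] == "m") ch[p] <- sample(setdiff(bases, ch[p]), 1)
          else if (type[j] == "d") ch[p] <- ""
          else ch[p] <- paste0(ch[p], sample(bases, 1))
        }
      }
      frag <- paste(ch, collapse = "")
    }
    out[i] <- frag
    prov[i] <- sprintf("read%05d %s:%d:%s", i, reps$name[ri[i]], start - 1L,
                       strands[i])
  }
  setNames(out, prov)
}

#' Write reads as FASTQ with constant qualities
#'
#' @param reads named character vector from [simulate_long_reads()].
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", names(reads)[i]), reads[[i]], "+",
                 strrep("I", nchar(reads[[i]]))), con)
  }
  invisible(path)
}

#' Read / write contig paths
#'
#' One line per path: comma-separated oriented segment ids (e.g.
#' `1+,3+,5+`).
#'
#' @param path file path.
#' @return list of data.frames with columns id, strand.
#' @export
read_contig_paths <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    toks <- strsplit(l, ",", fixed = TRUE)[[1]]
    data.frame(id = sub("[+-]$", "", toks),
               strand = sub("^.*([+-])$", "\\1", toks),
               stringsAsFactors = FALSE)
  })
}

#' @rdname read_contig_paths
#' @param paths list of data.frames with columns id, strand.
#' @export
write_contig_paths <- function(paths, path) {
  writeLines(vapply(paths, function(p) paste0(p$id, p$strand, collapse = ","), ""),
             path)
  invisible(path)
}
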