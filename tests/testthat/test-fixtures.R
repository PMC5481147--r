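test_that("genome simulation is reproducible and honours its spec", {
  spec <- list(chromosome_length = 20000,
               repeats = list(list(length = 1000, copies = 3, divergence = 0)),
               plasmids = list(list(length = 5000, cell_copy = 5)))
  t1 <- simulate_genome(20000, spec$repeats, spec$plasmids, seed = 5)
  t2 <- simulate_genome(20000, spec$repeats, spec$plasmids, seed = 5)
  expect_identical(t1$replicons$sequence, t2$replicons$sequence)
  expect_equal(nrow(t1$repeats), 3)
  expect_equal(t1$replicons$cell_copy, c(1, 5))
  expect_equal(t1$replicons$length, c(20000, 5000))
  # divergence 0: all copies identical
  s <- t1$replicons$sequence[1]
  copies <- vapply(seq_len(nrow(t1$repeats)), function(i)
    substr(s, t1$repeats$start[i] + 1, t1$repeats$start[i] + t1$repeats$length[i]), "")
  expect_equal(length(unique(copies)), 1)
  # divergence > 0: copies differ but stay close
  t3 <- simulate_genome(20000,
                        list(list(length = 1000, copies = 2, divergence = 0.02)),
                        seed = 6)
  s3 <- t3$replicons$sequence[1]
  c3 <- vapply(1:2, function(i)
    substr(s3, t3$repeats$start[i] + 1, t3$repeats$start[i] + 1000), "")
  d <- sum(strsplit(c3[1], "")[[1]] != strsplit(c3[2], "")[[1]])
  expect_gt(d, 0)
  expect_lt(d, 100)
  expect_error(simulate_genome(3000, list(list(length = 1400, copies = 2,
                                               divergence = 0))),
               "cannot place")
  # truth JSON round-trips
  f <- tempfile(fileext = ".json")
  write_truth(t1, f)
  t1b <- read_truth(f)
  expect_equal(t1$replicons$sequence, t1b$replicons$sequence)
  expect_equal(t1$repeats$start, t1b$repeats$start)
})

test_that("the k-mer graph builder recovers planted repeat structure", {
  truth <- simulate_genome(20000,
                           list(list(length = 1000, copies = 2, divergence = 0)),
                           seed = 8)
  bk <- build_kmer_graph(truth, k = 31)
  g <- bk$graph
  # the repeat collapses to one deep segment; its multiplicity truth is 2
  rep_seg <- g$segments$id[which.max(g$segments$depth)]
  expect_equal(unname(bk$multiplicity[[rep_seg]]), 2L)
  expect_equal(g$segments$depth[g$segments$id == rep_seg], 100)  # 2 x base 50
  expect_equal(dead_end_count(g), 0)
  expect_true(all(g$links$overlap == 30))
  # a repeat-free circular genome is a single self-linked segment
  t0 <- simulate_genome(5000, seed = 9)
  g0 <- build_kmer_graph(t0, k = 31)$graph
  expect_equal(nrow(g0$segments), 1)
  expect_true(detect_replicons(g0)$circular)
  # k beyond the repeat length collapses the repeat: fewer segments
  t2 <- simulate_genome(20000,
                        list(list(length = 61, copies = 3, divergence = 0)),
                        seed = 10)
  n_small_k <- nrow(build_kmer_graph(t2, k = 31)$graph$segments)
  n_big_k <- nrow(build_kmer_graph(t2, k = 71)$graph$segments)
  expect_lt(n_big_k, n_small_k)
})

test_that("traversing the truth contig paths reconstructs each replicon", {
  truth <- simulate_genome(30000,
                           list(list(length = 700, copies = 2, divergence = 0)),
                           plasmids = list(list(length = 4000, cell_copy = 2)),
                           seed = 11)
  bk <- build_kmer_graph(truth, k = 31, insert_size = 10000)  # no splitting
  g <- bk$graph
  for (i in seq_len(nrow(truth$replicons))) {
    # find the path that traverses this replicon (it starts somewhere on it)
    rep_seq <- truth$replicons$sequence[i]
    doubled <- paste0(rep_seq, rep_seq)
    hit <- FALSE
    for (p in bk$contig_paths) {
      ovs <- gfabridge:::path_link_overlaps(g, p$id, p$strand)
      s <- gfabridge:::oriented_concat(g, p$id, p$strand, ovs)
      # the circular walk repeats its first k-1 bases at the end
      wrap <- g$k_overlap
      core <- substr(s, 1, nchar(s) - wrap)
      if (nchar(core) == nchar(rep_seq) && grepl(core, doubled, fixed = TRUE))
        hit <- TRUE
    }
    expect_true(hit, info = truth$replicons$name[i])
  }
})

test_that("depth assignment is exact at sigma zero and jittered above", {
  truth <- simulate_genome(20000,
                           list(list(length = 900, copies = 3, divergence = 0)),
                           seed = 12)
  g0 <- build_kmer_graph(truth, k = 31, sigma = 0)$graph
  # exact integer copy-count multiples of the base depth
  expect_true(all(g0$segments$depth %% 50 == 0))
  expect_true(any(g0$segments$depth == 150))  # the planted 3-copy repeat
  g1 <- build_kmer_graph(truth, k = 31, sigma = 0.1, seed = 1)$graph
  expect_false(all(g1$segments$depth %in% c(50, 150)))
  expect_true(all(abs(log(g1$segments$depth / g0$segments$depth)) < 0.5))
})

test_that("the read simulator matches its length, depth and identity dials", {
  truth <- simulate_genome(50000, seed = 13)
  reads <- simulate_long_reads(truth, depth = 8, mean_len = 5000,
                               identity = 1.0, seed = 13)
  expect_equal(length(reads), 80, tolerance = 0.2)
  expect_equal(mean(nchar(reads)), 5000, tolerance = 0.2)
  # identity 1: every read is an exact (possibly reverse-complemented)
  # substring of the circular genome
  doubled <- paste0(truth$replicons$sequence[1], truth$replicons$sequence[1])
  for (r in reads[1:20]) {
    expect_true(grepl(r, doubled, fixed = TRUE) ||
                  grepl(revcomp(r), doubled, fixed = TRUE))
  }
  # deterministic under seed
  reads2 <- simulate_long_reads(truth, depth = 8, mean_len = 5000,
                                identity = 1.0, seed = 13)
  expect_identical(reads, reads2)
  # empirical identity tracks the request within a few points
  noisy <- simulate_long_reads(truth, depth = 1, mean_len = 4000,
                               identity = 0.8, seed = 14)
  ids <- vapply(noisy[1:8], function(r) {
    al <- seeded_align(r, doubled)
    if (is.null(al)) return(NA_real_)
    al$identity
  }, 0)
  expect_true(abs(mean(ids, na.rm = TRUE) - 0.8) < 0.05)
  # FASTQ output round-trips through the reader
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads[1:5], f)
  back <- read_seqs(f)
  expect_equal(unname(back), unname(reads[1:5]))
})

test_that("contig-path files round-trip", {
  paths <- list(data.frame(id = c("1", "3", "5"), strand = c("+", "-", "+"),
                           stringsAsFactors = FALSE),
                data.frame(id = "7", strand = "+", stringsAsFactors = FALSE))
  f <- tempfile(fileext = ".txt")
  write_contig_paths(paths, f)
  back <- read_contig_paths(f)
  expect_equal(back, paths)
})
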