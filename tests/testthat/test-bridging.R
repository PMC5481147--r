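mmap_for <- function(graph, k) {
  structure(list(assignment = k,
                 origin = setNames(rep("seed", length(k)), names(k)),
                 median_depth = 1),
            class = "multiplicity_map")
}

test_that("path bridges connect single-copy pairs through repeat sub-paths", {
  g <- repeat_join_graph()
  mm <- infer_multiplicity(g)
  paths <- list(data.frame(id = c("1", "3", "5"), strand = "+"),
                data.frame(id = c("2", "3", "4"), strand = "+"))
  br <- path_bridges(g, paths, mm)
  expect_length(br, 2)
  b1 <- br[[which(vapply(br, function(b) b$start_id, "") == "1")]]
  expect_equal(b1$end_id, "5")
  expect_equal(b1$path$id, "3")
  expect_equal(b1$sequence, g$segments$sequence[g$segments$id == "3"])
  # all-repeat path yields nothing
  expect_length(path_bridges(g, list(data.frame(id = "3", strand = "+")), mm), 0)
  # directly adjacent single-copy pair: empty interior
  g2 <- assembly_graph(
    data.frame(id = c("A", "B"),
               sequence = c(random_seq(500), random_seq(500)), depth = 1),
    data.frame(from_id = "A", from_strand = "+", to_id = "B", to_strand = "+",
               overlap = 0L))
  br2 <- path_bridges(g2, list(data.frame(id = c("A", "B"), strand = "+")),
                      mmap_for(g2, c(A = 1L, B = 1L)))
  expect_length(br2, 1)
  expect_equal(br2[[1]]$sequence, "")
  # unknown segment in a path: skipped with a warning
  expect_warning(
    out <- path_bridges(g, list(data.frame(id = c("1", "zz"), strand = "+")), mm),
    "unknown segment")
  expect_length(out, 0)
})

test_that("find_graph_path picks the repeat matching the consensus", {
  set.seed(31)
  A <- random_seq(2000); B <- random_seq(2000)
  R1 <- random_seq(900); R2 <- random_seq(900)
  g <- assembly_graph(
    data.frame(id = c("A", "B", "R1", "R2"),
               sequence = c(A, B, R1, R2), depth = c(1, 1, 2, 2)),
    data.frame(from_id = c("A", "A", "R1", "R2"), from_strand = "+",
               to_id = c("R1", "R2", "B", "B"), to_strand = "+", overlap = 0L))
  target <- mutate_seq(R1, 0.95)
  hit <- find_graph_path(g, list(id = "A", strand = "+"),
                         list(id = "B", strand = "+"), target)
  expect_equal(hit$path$id, "R1")
  target2 <- mutate_seq(R2, 0.95)
  hit2 <- find_graph_path(g, list(id = "A", strand = "+"),
                          list(id = "B", strand = "+"), target2)
  expect_equal(hit2$path$id, "R2")
  # length window excludes every candidate
  expect_null(find_graph_path(g, list(id = "A", strand = "+"),
                              list(id = "B", strand = "+"),
                              random_seq(10000)))
  # empty target with a direct link: empty path
  g2 <- assembly_graph(
    data.frame(id = c("A", "B"), sequence = c(A, B), depth = 1),
    data.frame(from_id = "A", from_strand = "+", to_id = "B", to_strand = "+",
               overlap = 0L))
  hit3 <- find_graph_path(g2, list(id = "A", strand = "+"),
                          list(id = "B", strand = "+"), "")
  expect_equal(nrow(hit3$path), 0)
})

test_that("long-read bridges prefer graph paths and fall back to consensus", {
  set.seed(32)
  g <- repeat_join_graph(arm_len = 3000, rep_len = 800)
  mm <- infer_multiplicity(g)
  seqs <- setNames(g$segments$sequence, g$segments$id)
  genome_piece <- paste0(seqs[["1"]], seqs[["3"]], seqs[["5"]])
  reads <- setNames(
    vapply(1:5, function(i)
      mutate_seq(substr(genome_piece, 1500, 5300), 0.85), ""),
    paste0("r", 1:5))
  aln <- align_long_reads(reads, seqs[c("1", "2", "4", "5")])
  br <- long_read_bridges(g, aln, reads, mm)
  expect_length(br, 1)
  expect_equal(br[[1]]$kind, "long_read_graph_bridge")
  expect_equal(br[[1]]$support, 5L)
  expect_equal(br[[1]]$path$id, "3")
  expect_equal(br[[1]]$sequence, seqs[["3"]])  # graph bases, not read bases
  # dead-end gap: no graph path exists, consensus carries the bridge
  g2 <- assembly_graph(
    data.frame(id = c("A", "B"),
               sequence = c(seqs[["1"]], seqs[["5"]]), depth = 1))
  gapseq <- random_seq(700)
  genome2 <- paste0(seqs[["1"]], gapseq, seqs[["5"]])
  reads2 <- setNames(
    vapply(1:4, function(i) mutate_seq(substr(genome2, 2000, 4500), 0.85), ""),
    paste0("q", 1:4))
  aln2 <- align_long_reads(reads2, setNames(g2$segments$sequence, g2$segments$id))
  br2 <- long_read_bridges(g2, aln2, reads2,
                           mmap_for(g2, c(A = 1L, B = 1L)))
  expect_length(br2, 1)
  expect_equal(br2[[1]]$kind, "long_read_sequence_bridge")
  cons_id <- semiglobal_align(br2[[1]]$sequence, gapseq)$matches / nchar(gapseq)
  expect_gt(cons_id, 0.9)  # consensus is closer to truth than single reads
  # a single spanning read still builds a bridge with support 1
  br3 <- long_read_bridges(g, aln[aln$read == "r1", ], reads["r1"], mm)
  expect_length(br3, 1)
  expect_equal(br3[[1]]$support, 1L)
})

test_that("bridge quality follows the stated product of monotone factors", {
  set.seed(33)
  g <- assembly_graph(data.frame(
    id = c("A", "B"), sequence = c(random_seq(12000), random_seq(12000)),
    depth = c(1, 1)))
  mk <- function(support = 10L, cons = 1, alnf = 1, kind = "long_read_graph_bridge")
    structure(list(start_id = "A", start_strand = "+", end_id = "B",
                   end_strand = "+", path = NULL, sequence = "X", kind = kind,
                   support = support, consensus_identity = cons,
                   aln_factor = alnf, quality = NA_real_), class = "bridge")
  # ideal bridge approaches 100
  expect_gt(bridge_quality(mk(), g), 99.8)
  # support 1 halves the quality relative to the support -> Inf limit
  expect_equal(bridge_quality(mk(support = 1L), g) / bridge_quality(mk(support = 1000L), g),
               0.5, tolerance = 1e-6)
  # 2:1 depth disagreement halves the quality
  g2 <- g; g2$segments$depth <- c(2, 1)
  expect_equal(bridge_quality(mk(), g2) / bridge_quality(mk(), g), 0.5,
               tolerance = 1e-6)
  # monotone in every factor
  expect_lt(bridge_quality(mk(support = 2L), g), bridge_quality(mk(support = 5L), g))
  expect_lt(bridge_quality(mk(cons = 0.8), g), bridge_quality(mk(cons = 0.95), g))
  expect_lt(bridge_quality(mk(alnf = 0.5), g), bridge_quality(mk(alnf = 0.9), g))
  gshort <- g; gshort$segments$sequence[1] <- random_seq(3000)
  expect_lt(bridge_quality(mk(), gshort), bridge_quality(mk(), g))
  # sequence bridges carry the fixed consensus penalty
  expect_equal(bridge_quality(mk(kind = "long_read_sequence_bridge"), g) /
                 bridge_quality(mk(), g), 0.5, tolerance = 1e-6)
})

test_that("bridges apply best-first with the contradiction rule", {
  g <- repeat_join_graph()
  mm <- infer_multiplicity(g)
  seqs <- setNames(g$segments$sequence, g$segments$id)
  mkb <- function(from, to, q, path_ids = "3") structure(list(
    start_id = from, start_strand = "+", end_id = to, end_strand = "+",
    path = data.frame(id = path_ids, strand = "+"),
    sequence = paste(seqs[path_ids], collapse = ""),
    kind = "long_read_graph_bridge", support = 3L, consensus_identity = 1,
    aln_factor = 1, quality = q), class = "bridge")
  # the repeat-join fixture: bridging 1->5 leaves 2-3-4 connected by elimination
  ap <- apply_bridges(g, list(mkb("1", "5", 60)), threshold = 10, mmap = mm)
  expect_true(ap$applied)
  expect_equal(unname(ap$residual[["3"]]), 1L)
  ga <- ap$graph
  merged <- merge_unbranching_paths(ga)
  # two linear contigs remain: 1-bridge-5 and 2-3-4
  expect_equal(nrow(merged$segments), 2)
  expect_equal(dead_end_count(merged), 4)
  expect_lte(dead_end_count(ga), dead_end_count(g))
  # contradictory bridges: only the better one is applied
  ap2 <- apply_bridges(g, list(mkb("1", "5", 40), mkb("1", "4", 20)),
                       threshold = 10, mmap = mm)
  expect_equal(ap2$applied, c(TRUE, FALSE))
  # below threshold nothing changes
  ap3 <- apply_bridges(g, list(mkb("1", "5", 5)), threshold = 10, mmap = mm)
  expect_false(any(ap3$applied))
  expect_true(gfabridge:::graph_identical(g, ap3$graph))
})

test_that("applied bridge sets nest across the mode thresholds", {
  set.seed(34)
  for (seed in 1:2) {
    res <- list()
    truth <- study_truth(seed)
    bk <- build_kmer_graph(truth, k = 41, sigma = 0.05, seed = seed)
    reads <- simulate_long_reads(truth, depth = 4, mean_len = 10000,
                                 identity = 0.75, seed = seed)
    g <- bk$graph
    mm <- infer_multiplicity(g)
    anchors <- single_copy_segments(mm, g, 100)
    aln <- align_long_reads(reads, setNames(g$segments$sequence, g$segments$id)[anchors])
    br <- gfabridge:::score_bridges(long_read_bridges(g, aln, reads, mm), g)
    key <- function(applied) which(applied)
    a25 <- key(apply_bridges(g, br, 25, mm)$applied)
    a10 <- key(apply_bridges(g, br, 10, mm)$applied)
    a1 <- key(apply_bridges(g, br, 1, mm)$applied)
    expect_true(all(a25 %in% a10))
    expect_true(all(a10 %in% a1))
  }
})

test_that("applied graph-bridge sequences are exact substrings of the true genome", {
  for (seed in 4:5) {
    truth <- study_truth(seed)
    bk <- build_kmer_graph(truth, k = 41, sigma = 0, seed = seed)
    reads <- simulate_long_reads(truth, depth = 6, mean_len = 12000,
                                 identity = 0.9, seed = seed)
    g <- bk$graph
    mm <- infer_multiplicity(g)
    anchors <- single_copy_segments(mm, g, 100)
    aln <- align_long_reads(reads, setNames(g$segments$sequence, g$segments$id)[anchors])
    br <- long_read_bridges(g, aln, reads, mm)
    doubled <- paste0(truth$replicons$sequence[1], truth$replicons$sequence[1])
    for (b in br) {
      if (b$kind != "long_read_graph_bridge" || !nzchar(b$sequence)) next
      # a bridge may be stored in either of its two bidirected orientations
      expect_true(grepl(b$sequence, doubled, fixed = TRUE) ||
                    grepl(revcomp(b$sequence), doubled, fixed = TRUE),
                  info = sprintf("seed %d bridge %s->%s", seed, b$start_id, b$end_id))
    }
  }
})
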