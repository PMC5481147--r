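test_that("GFA parsing builds a valid graph with twin links and depth-tag precedence", {
  gfa <- tempfile(fileext = ".gfa")
  writeLines(c("H\tVN:Z:1.0",
               "S\t1\tACGTACGT\tDP:f:2.0",
               "S\t2\tCGTACGTA",
               "S\t3\tGGGGCCCC\tKC:i:16",
               "L\t1\t+\t2\t+\t3M"), gfa)
  g <- read_gfa(gfa)
  expect_equal(nrow(g$segments), 3)
  expect_equal(g$segments$depth[g$segments$id == "1"], 2.0)
  expect_equal(g$segments$depth[g$segments$id == "2"], 1.0)  # default
  expect_equal(g$segments$depth[g$segments$id == "3"], 2.0)  # KC / length
  # the written link plus its reverse-complement twin
  expect_equal(nrow(g$links), 2)
  expect_true("2 - 1 - 3" %in% gfabridge:::link_key(g$links))
  expect_equal(g$k_overlap, 3L)
})

test_that("malformed GFA lines raise errors naming the problem", {
  gfa <- tempfile(fileext = ".gfa")
  writeLines(c("S\t1\tACGT", "L\t1\t+\t9\t+\t0M"), gfa)
  expect_error(read_gfa(gfa), "unknown segment")
  writeLines(c("S\t1\tACGT", "S\t2\tACGT", "L\t1\t+\t2\t+\t2M1D"), gfa)
  expect_error(read_gfa(gfa), "CIGAR")
  writeLines(c("S\t1\t"), gfa)
  expect_error(read_gfa(gfa), "line 1")
})

test_that("write/parse round-trip is lossless", {
  set.seed(5)
  g <- repeat_join_graph()
  f <- tempfile(fileext = ".gfa")
  write_gfa(g, f)
  g2 <- read_gfa(f)
  expect_true(gfabridge:::graph_identical(g, g2))
  # an S-lines-only file has no links and all ends dead
  writeLines(c("S\ta\tACGT", "S\tb\tTTTT"), f)
  g3 <- read_gfa(f)
  expect_equal(nrow(g3$links), 0)
  expect_equal(dead_end_count(g3), 4)
})

test_that("dead ends are counted per unlinked segment end", {
  # isolated circular segment: self-link covers both ends
  circ <- assembly_graph(
    data.frame(id = "c", sequence = random_seq(100), depth = 1),
    data.frame(from_id = "c", from_strand = "+", to_id = "c", to_strand = "+",
               overlap = 0L))
  expect_equal(dead_end_count(circ), 0)
  # single linear segment
  lin <- assembly_graph(data.frame(id = "l", sequence = "ACGT", depth = 1))
  expect_equal(dead_end_count(lin), 2)
  # five-segment repeat join: arms 1,2 open on the left, 4,5 open on the right
  expect_equal(dead_end_count(repeat_join_graph()), 4)
})

test_that("merge_unbranching_paths concatenates overlap-aware and preserves depth mass", {
  set.seed(2)
  sa <- random_seq(10); sb <- random_seq(10); sc <- random_seq(10)
  mk <- function(ov) assembly_graph(
    data.frame(id = c("A", "B", "C"), sequence = c(sa, sb, sc),
               depth = c(1, 3, 2)),
    data.frame(from_id = c("A", "B"), from_strand = "+",
               to_id = c("B", "C"), to_strand = "+", overlap = ov))
  m0 <- merge_unbranching_paths(mk(0L))
  expect_equal(nrow(m0$segments), 1)
  expect_equal(m0$segments$sequence, paste0(sa, sb, sc))
  expect_equal(m0$segments$depth, 2)  # length-weighted mean
  expect_equal(m0$segments$members, "A+,B+,C+")
  # overlap-aware: two junctions at overlap 3 shrink the merge by 6
  sb2 <- paste0(substr(sa, 8, 10), random_seq(4), "")
  g3 <- assembly_graph(
    data.frame(id = c("A", "B"), sequence = c(sa, paste0(substr(sa, 8, 10), random_seq(7))),
               depth = 1),
    data.frame(from_id = "A", from_strand = "+", to_id = "B", to_strand = "+",
               overlap = 3L))
  m3 <- merge_unbranching_paths(g3)
  expect_equal(nchar(m3$segments$sequence), 17)  # 10 + 10 - 3
})

test_that("merge respects the mergeable predicate and sequence totals are conserved", {
  g <- repeat_join_graph()
  # arm segments merge into the repeat only where junctions are simple; in
  # this branching graph nothing is an unbranching chain, so no change
  m <- merge_unbranching_paths(g)
  expect_equal(sort(m$segments$id), sort(g$segments$id))
  # a simple chain with one member excluded stays unmerged
  chain <- assembly_graph(
    data.frame(id = c("A", "B", "C"),
               sequence = c(random_seq(10), random_seq(10), random_seq(10)),
               depth = 1),
    data.frame(from_id = c("A", "B"), from_strand = "+",
               to_id = c("B", "C"), to_strand = "+", overlap = 0L))
  m2 <- merge_unbranching_paths(chain, function(id) id != "B")
  expect_equal(sort(m2$segments$id), c("A", "B", "C"))
  # total sequence is conserved by a full merge
  m3 <- merge_unbranching_paths(chain)
  expect_equal(sum(nchar(m3$segments$sequence)), sum(nchar(chain$segments$sequence)))
})

test_that("a mergeable circular chain collapses to one self-linked segment", {
  set.seed(8)
  segs <- data.frame(id = c("A", "B", "C"),
                     sequence = c(random_seq(50), random_seq(60), random_seq(70)),
                     depth = 1)
  links <- data.frame(from_id = c("A", "B", "C"), from_strand = "+",
                      to_id = c("B", "C", "A"), to_strand = "+", overlap = 0L)
  g <- merge_unbranching_paths(assembly_graph(segs, links))
  expect_equal(nrow(g$segments), 1)
  expect_equal(nchar(g$segments$sequence), 180)
  reps <- detect_replicons(g)
  expect_true(reps$circular)
})

test_that("twin-link closure holds after merges and removals", {
  g <- repeat_join_graph()
  for (gg in list(g, merge_unbranching_paths(g), remove_segments(g, "1"))) {
    k <- gfabridge:::link_key(gg$links)
    tk <- gfabridge:::link_key(gfabridge:::twin_of(gg$links))
    expect_setequal(k, tk)
  }
})

test_that("trim_overlaps keeps each shared overlap exactly once", {
  set.seed(9)
  # circular single segment with self-link overlap k: length drops by k
  L <- 200; k <- 40
  s <- random_seq(L)
  circ_seq <- paste0(s, substr(s, 1, k))  # segment carries the wrap overlap
  g <- assembly_graph(
    data.frame(id = "c", sequence = circ_seq, depth = 1),
    data.frame(from_id = "c", from_strand = "+", to_id = "c", to_strand = "+",
               overlap = k), k_overlap = k)
  tr <- trim_overlaps(g)
  expect_equal(nchar(tr$segments$sequence), L)
  expect_true(all(tr$links$overlap == 0))
  # two-segment circle with overlaps k at both junctions: total drops by 2k
  sa <- random_seq(100); sb <- random_seq(120)
  a_seq <- paste0(sa, substr(sb, 1, k))
  b_seq <- paste0(sb, substr(sa, 1, k))
  g2 <- assembly_graph(
    data.frame(id = c("a", "b"), sequence = c(a_seq, b_seq), depth = 1),
    data.frame(from_id = c("a", "b"), from_strand = "+",
               to_id = c("b", "a"), to_strand = "+", overlap = k),
    k_overlap = k)
  tr2 <- trim_overlaps(g2)
  expect_equal(sum(nchar(tr2$segments$sequence)), 220)
  # zero-overlap graphs pass through unchanged
  g0 <- repeat_join_graph()
  expect_true(gfabridge:::graph_identical(g0, trim_overlaps(g0)))
})

test_that("unsatisfiable trim assignments error instead of corrupting sequence", {
  set.seed(4)
  # palindromic self-junction with an odd overlap cannot split evenly
  g <- assembly_graph(
    data.frame(id = "t", sequence = random_seq(20), depth = 1),
    data.frame(from_id = "t", from_strand = "+", to_id = "t", to_strand = "-",
               overlap = 7L))
  expect_error(trim_overlaps(g), "consistent end trims")
})
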