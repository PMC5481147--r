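# exhaustive enumeration of every end-gap-free affine alignment; tractable
# only for very short strings, and deliberately ignorant of the DP
brute_semiglobal <- function(a, b, sc) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  best <- 0
  rec <- function(i, j, score, state) {
    if (i == m || j == n) best <<- max(best, score)  # free trailing gaps
    if (i < m && j < n)
      rec(i + 1, j + 1,
          score + if (av[i + 1] == bv[j + 1]) sc$match else sc$mismatch, "M")
    if (i < m)
      rec(i + 1, j, score + sc$gap_extend +
            if (state == "I") 0 else sc$gap_open, "I")
    if (j < n)
      rec(i, j + 1, score + sc$gap_extend +
            if (state == "D") 0 else sc$gap_open, "D")
  }
  for (i0 in 0:m) rec(i0, 0, 0, "S")  # free leading gap in b
  for (j0 in 1:n) rec(0, j0, 0, "S")  # free leading gap in a
  best
}

test_that("exact aligner matches hand cases and an exhaustive enumeration oracle", {
  s <- scoring_scheme(1, -1, -2, -1)
  al <- semiglobal_align("ACGTACGT", "ACGTACGT", s)
  expect_equal(al$score, 8)
  expect_equal(al$identity, 1.0)
  # containment: trailing gap is free
  al2 <- semiglobal_align("AAAA", "AAAATTTT", s)
  expect_equal(al2$score, 4)
  expect_equal(al2$a_interval, c(0, 4))
  expect_equal(al2$b_interval[1], 0)
  set.seed(21)
  sc <- scoring_scheme(2, -3, -3, -1)
  for (i in 1:12) {
    a <- random_seq(sample(2:5, 1)); b <- random_seq(sample(2:5, 1))
    mine <- semiglobal_align(a, b, sc)
    expect_equal(if (is.null(mine)) 0 else mine$score, brute_semiglobal(a, b, sc),
                 info = paste(a, b))
  }
})

test_that("exact aligner agrees with an independent overlap-alignment implementation", {
  set.seed(22)
  sc <- scoring_scheme(3, -6, -5, -2)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 3, mismatch = -6,
                                                  baseOnly = TRUE)
  for (i in 1:100) {
    a <- random_seq(sample(20:200, 1))
    b <- random_seq(sample(20:200, 1))
    mine <- semiglobal_align(a, b, sc)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(if (is.null(mine)) 0 else mine$score, max(0, ref),
                 info = sprintf("pair %d", i))
  }
})

test_that("score is invariant under joint reverse complement", {
  set.seed(23)
  for (i in 1:10) {
    a <- random_seq(150); b <- random_seq(200)
    s1 <- semiglobal_align(a, b)$score
    s2 <- semiglobal_align(revcomp(a), revcomp(b))$score
    expect_equal(s1, s2)
  }
})

test_that("seeded alignment reproduces the exact optimum on noisy substrings", {
  set.seed(24)
  for (id in c(0.75, 0.9)) {
    for (i in 1:10) {
      tgt <- random_seq(4000)
      rd <- mutate_seq(substr(tgt, 500, 2500), id)
      ex <- semiglobal_align(rd, tgt)
      se <- seeded_align(rd, tgt)
      expect_false(is.null(se))
      expect_equal(se$score, ex$score, info = sprintf("identity %.2f rep %d", id, i))
    }
  }
  # exact substring: identity 1
  tgt <- random_seq(5000)
  rd <- substr(tgt, 1000, 3000)
  se <- seeded_align(rd, tgt)
  expect_equal(se$identity, 1.0)
  expect_equal(se$b_interval, c(999, 3000))
  # unrelated sequences: no chain, no alignment
  nulls <- vapply(1:20, function(i)
    is.null(seeded_align(random_seq(1000), random_seq(5000))), logical(1))
  expect_true(all(nulls))
})

test_that("long-read alignment spans contigs, handles strand, and filters overlaps", {
  set.seed(25)
  A <- random_seq(4000); R <- random_seq(1000); B <- random_seq(4000)
  genome <- paste0(A, R, B)
  # read spanning A -> R -> B
  rd <- substr(genome, 3001, 6000)
  contigs <- c(A = A, B = B)
  aln <- align_long_reads(c(r1 = rd), contigs)
  expect_equal(sort(aln$contig), c("A", "B"))
  a_row <- aln[aln$contig == "A", ]; b_row <- aln[aln$contig == "B", ]
  expect_true(a_row$reaches_contig_end)    # read leaves A's end
  expect_true(b_row$reaches_contig_start)  # and enters B's start
  expect_equal(b_row$read_start - a_row$read_end, 1000)  # the repeat gap
  # reverse strand: coordinates stay on the forward contig
  aln_rc <- align_long_reads(c(r1 = revcomp(rd)), contigs)
  expect_setequal(aln_rc$strand, "-")
  expect_equal(sort(aln_rc$contig_start), sort(aln$contig_start))
  # a read inside one contig yields a single alignment
  aln1 <- align_long_reads(c(r = substr(A, 1000, 2500)), contigs)
  expect_equal(nrow(aln1), 1)
  expect_equal(aln1$contig, "A")
})

test_that("consensus corrects disjoint errors and respects length spread", {
  set.seed(26)
  S <- random_seq(600)
  # three copies with disjoint single-base substitutions
  alter <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    paste(ch, collapse = "")
  }
  frs <- c(alter(S, 50), alter(S, 300), alter(S, 550))
  expect_equal(consensus_sequence(frs), S)
  # single fragment passes through
  expect_equal(consensus_sequence(S), S)
  expect_error(consensus_sequence(character(0)), "no fragments")
  # wildly different lengths: consensus length stays within the spread
  frs2 <- c(substr(S, 1, 200), S, paste0(S, random_seq(400)))
  cons <- consensus_sequence(frs2)
  expect_gte(nchar(cons), 200)
  expect_lte(nchar(cons), 1000)
})

test_that("consensus of noisy fragments beats the mean fragment identity", {
  set.seed(27)
  wins <- 0L
  for (rep in 1:10) {
    S <- random_seq(800)
    frs <- vapply(1:7, function(i) mutate_seq(S, 0.75), "")
    cons <- consensus_sequence(frs)
    idf <- function(x) {
      al <- semiglobal_align(x, S)
      if (is.null(al)) 0 else al$matches / max(nchar(S), nchar(x))
    }
    if (idf(cons) > mean(vapply(frs, idf, 0))) wins <- wins + 1L
  }
  expect_equal(wins, 10L)
})

test_that("SAM output is well-formed with soft-clipped end gaps", {
  set.seed(28)
  tgt <- random_seq(2000)
  rd <- paste0(random_seq(100), substr(tgt, 501, 1500), random_seq(50))
  aln <- align_long_reads(c(r1 = rd), c(c1 = tgt))
  f <- tempfile(fileext = ".sam")
  write_sam(aln, c(r1 = rd), c(c1 = tgt), f)
  lines <- readLines(f)
  expect_true(any(grepl("^@SQ\tSN:c1\tLN:2000$", lines)))
  rec <- strsplit(lines[!grepl("^@", lines)][1], "\t")[[1]]
  expect_equal(rec[1], "r1")
  expect_equal(rec[3], "c1")
  # CIGAR consumes the full read including clips
  ops <- gfabridge:::cigar_ops(rec[6])
  used <- sum(vapply(ops, function(o) if (o$op %in% c("M", "I", "S")) o$n else 0L, 0))
  expect_equal(used, nchar(rd))
})
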