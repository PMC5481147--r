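---
title: "Resolving bacterial assembly graphs with long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving bacterial assembly graphs with long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfabridge)
```

## The problem

A bacterial isolate sequenced on a short-read platform yields an assembly
graph: contig segments joined by links that record which contig ends can
follow which. Repeats longer than the library insert — insertion sequences
around 1 kbp, rRNA operons around 5 kbp — collapse into single segments
with several incoming and outgoing links, so the genome cannot be read off
the graph as one walk per replicon. Long reads from the same isolate span
those repeats. `gfabridge` resolves the graph by aligning long reads to
unambiguous ("single-copy") contigs and converting spanning reads into
*bridges* that commit the graph to one path through each repeat, while the
assembled bases themselves stay short-read-accurate.

## The graph model

The graph is bidirected: each segment has two ends, and a link joins an
oriented segment to another. Every link's reverse-complement twin is stored
explicitly, and all operations preserve this closure. A link may carry an
end overlap (a SPAdes-style k-mer graph has uniform `k-1` overlaps); a
self-link from a segment's end to its own start marks a completed circular
replicon. Coordinates are 0-based half-open throughout; strands are `+`/`-`.
GFA1 is the only on-disk dialect: depth is taken from `DP:f:`, falling back
to `dp:f:`, then `KC:i:` divided by length, then 1.0.

## Choosing the short-read graph

Given candidate graphs from a k-mer ladder (ten odd values spanning 20–95%
of the read length, capped at 127), each candidate with `c` contigs and `d`
dead ends scores `1/(c (d+1)^2)`. Dead ends are penalised quadratically
because every later stage relies on connectivity: a dead end breaks both
multiplicity propagation and graph-path bridging. Ties go to the larger k.
Likely contamination — segments below half the median depth — is removed
iteratively, deepest candidate first, skipping any removal that would
create a new dead end. The median depth is length-weighted (each base
votes): a cloud of short high-copy segments then cannot drag the median,
which the plain segment median would allow.

## Multiplicity

With `D` the length-weighted median depth, a segment of depth `d_x` has
multiplicity approximately `d_x / D` — but only for replicons at one copy
per cell, so depth alone is not trusted. Seeding assigns `k = 1` to
segments with depth within ±50% of `D` (`tau_seed = 0.5`) and at most one
link per end. Propagation then works junction by junction: where every
neighbour of a segment end is known and each neighbour's opposing end
connects only back to it, copy numbers must balance (copies in = copies
out), and the implied value is accepted if it agrees with depth within 30%
per copy (`tau_prop = 0.3`). Among simultaneously available assignments the
one with the closest depth agreement goes first, which makes the result
independent of iteration order. When propagation stalls, the longest
unassigned segment restarts the process with `k = 1`, preferring segments
with depth at most `1.5 D`, then segments with at most one link per end —
the latter is what assigns `k = 1` to a small plasmid at ten-fold cell copy
number, whose depth says 10 but whose genomic multiplicity is 1 — and
falling back to `round(d_x / D)`. Flow balance outranks the raw depth ratio
whenever both apply, which is how a `2D` segment can still be resolved as a
chromosomal two-copy repeat rather than a plasmid.

The two tolerances are deliberately loose: simulated depth noise of
`sigma = 0.1` (lognormal, multiplicative) leaves both windows comfortably
wide, and tightening them mainly delays assignments until the restart rule
fires.

## Semi-global alignment

Because the long reads and the contigs come from the same DNA, there are no
true structural differences between them, and local alignment would be free
to clip inconvenient disagreements. The aligner is therefore end-gap-free:
leading and trailing gaps on either sequence cost nothing, and an alignment
may only terminate at a sequence end. Scores are affine (`gap_open +
g * gap_extend` for a gap of length `g`) with defaults +3/−6/−5/−2 — chosen
so that a 70%-identity read still scores positively against its true locus —
and everything is configurable.

Two implementations share the scoring: exact full dynamic programming (the
reference, quadratic, used for consensus-versus-path scoring and as the
oracle in tests) and the production path: exact 13-mer seeds, restriction
to the dominant diagonal band (so seeds from different repeat copies cannot
widen the search), longest-increasing-subsequence chaining, trimming to the
longest diagonal-coherent run (consecutive seeds of a genuine chain drift
by a few bases; chance chains jump hundreds), and banded DP within ±75 of
the chain's diagonal range. The band default covers the indel drift of a
10 kbp read at 60% identity with a wide margin. The seeded path returns
nothing when no chain of at least 3 seeds survives — absence of an
alignment is a valid outcome, and the identity floor for keeping alignments
(0.6) admits the worst accuracy tier the read simulator produces.

## Consensus and bridging

Bridging anchors are single-copy contigs of at least 1 kbp (configurable).
Shorter single-copy islands — a few hundred bases wedged between two
copies of a repeat — make poor anchors: the quality function rightly
discounts bridges ending on them (both through the contig-length factor
and the capped alignment length), so such bridges never clear any mode
threshold and the junction would stay unresolved forever. Excluding them
from the anchor set instead lets spanning reads group across the whole
repeat cluster, and the branch-and-bound search places the island as path
interior. The 1 kbp floor matches the alignment-length scale of the
quality function.

Reads aligning to two single-copy contigs in succession carry the gap
sequence between them. Per oriented contig pair, the gap fragments are
collapsed: the fragment with the highest summed pairwise alignment score
becomes the backbone (at most 10 fragments participate; with a wide length
spread this lands on a median-length member), the rest are aligned to it
end-gap-free, and each backbone column is called by majority over bases,
deletions, and insertions. The consensus is then *not* used as assembly
sequence directly: a best-first branch-and-bound search enumerates graph
paths between the anchors, pruning when the interior length leaves
`[(1±0.5) × target length]` (plus an overlap slack) or when 10,000 node
expansions are exhausted — the budget exists because pathological repeat
tangles otherwise explode combinatorially. Candidate paths are scored by
banded alignment against the consensus; the best path with identity ≥ 0.7
wins, and the bridge takes the *graph* sequence, so base accuracy stays at
short-read levels. Only when no path qualifies (dead ends, incomplete
graph) does the consensus itself become the bridge sequence, at a fixed
quality penalty.

Bridge quality is `100 × Π f_i` with every factor in (0, 1] and monotone:
`f_support = 1 − 2^(−support)`, `f_consensus` = consensus-to-path identity
(graph bridges) or 0.5 (sequence bridges), `f_contig_len =
min(1, min(anchor lengths)/10000)`, `f_aln` = mean over supporting reads of
identity × min(1, alignment length/1000), and `f_depth` = anchor depth
ratio. Contig-path bridges (from read-pair repeat resolution) use support
over path occurrences with unit consensus and alignment factors. The
functional forms are heuristic by design; the package exposes their
constants and guarantees only boundedness and monotonicity, which the test
suite checks factor by factor.

Application is greedy by descending quality above the mode threshold
(conservative 25, normal 10, bold 1). Each single-copy contig end can be
consumed by at most one bridge — the minimal contradiction rule that makes
"best-supported wins" well-defined. Applying a bridge removes the competing
links at both anchor ends, installs the bridge segment, and decrements the
remaining multiplicity of path members (floored at zero); members used to
exhaustion are deleted when that creates no new dead end. In conservative
mode a bridge is additionally skipped when its path demands more copies of
a member than remain; in normal and bold modes the quality threshold is
the only gate. Repeats bridged on one side resolve their remaining copies
"by elimination": the leftover connections become unbranching and merge in
the final stage.

## Finalisation

Merging is mode-dependent: conservative merges only single-copy contigs and
bridge segments; normal also merges non-bridge contigs whose post-bridging
multiplicity is one; bold merges every unbranching path. End overlaps are
then removed exactly once per junction by 2-colouring the junction graph
with trims {0, overlap} per segment end (falling back to `overlap/2` per
end in a non-bipartite component — always integral for the even overlaps
that odd-k de Bruijn graphs produce). A completed circular replicon —
a segment whose only links are its own end-to-start link — has, after
trimming, exactly the replicon's length. Circular sequences are rotated to
begin at a start gene (dnaA/repA homologues supplied as FASTA) found by
the package's own aligner at ≥ 0.8 identity over ≥ 0.9 of the gene length,
flipped to the forward strand; the thresholds are configuration defaults,
as is the nucleotide-level (rather than protein-level) search. Rotation is
idempotent, and a pipeline run on an arbitrarily rotated input genome
produces byte-identical circular sequences.

## The synthetic fixtures and what they do not show

The generator emulates the study conditions end to end: a circular
chromosome of uniform-random sequence with planted repeat families
(IS-like ~1 kbp and operon-like ~5 kbp, copy numbers 2–7, optional per-copy
divergence up to 5%), plasmids at 1–10 cell copies, an exact forward-strand
de Bruijn graph standing in for the short-read assembler (unitigs, `k−1`
overlaps, depth = copy count × cell copy × 50, jittered by lognormal
`sigma`, default 0.1), truth-derived contig paths split at repeats longer
than the 400 bp insert size, and long reads with uniform circular starts,
gamma-distributed lengths (shape 4), uniform strands, and i.i.d. errors at
rate 1 − identity split 50:25:25 mismatch:insertion:deletion.

Deliberate simplifications, hence limits on what green tests prove about
real data: short reads are never simulated (the graph is error-free, so
short-read assembly artefacts — chimeric unitigs, coverage gaps, dead
ends — appear only where a test plants them); repeat copies are planted on
the forward strand and the de Bruijn graph is strand-specific, so inverted
repeats never collapse; the long-read error model is i.i.d. rather than the
burst-prone profiles of real instruments; and random sequence has none of
the compositional biases of genomes. The evaluator, likewise, anchors on
near-unique 31-mers and is adequate for near-error-free fixture contigs,
not a general-purpose replacement for reference-based assembly QC: its
misassembly definition (alignment breakpoints with ≥ 1 kbp reference
discrepancy or an orientation flip counted as extensive, smaller ones as
local, both summed) and strict NGA50 (contigs broken at every breakpoint)
mirror common practice at fixture scale. Minimum alignment-block length is
500 bp by default.

## Problem sizes and numerical choices

The test battery runs 100 kbp chromosomes (1 kbp × 3 and 5 kbp × 2 repeats,
one 10 kbp plasmid at 5×) with long-read depths 0.25–16× and identities
0.60–0.90 — sizes chosen so the full suite exercises every stage, across
20-seed batteries, in minutes on one core while keeping ≥ 40 reads at the
standard 8× depth. The read-length-versus-accuracy comparison uses a
variant genome whose second repeat family is prophage-scale (15 kbp × 2),
deliberately placed *between* the two mean read lengths compared (5 and
20 kbp): read length matters exactly when repeats approach read size, so a
genome whose repeats are all much shorter than both read lengths would
show no length effect at saturating depth. Degenerate inputs are handled explicitly: empty
consensus gaps (anchors abutting on the read) map to direct-link bridges;
alignment of unrelated sequences returns no result rather than a forced
overlap; score ties in graph selection prefer larger k; candidate ties in
multiplicity propagation break by closest depth agreement then segment id,
making every stage order-independent and deterministic under a fixed seed.
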