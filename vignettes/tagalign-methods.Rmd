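---
title: "How tagalign works: seeding, tag scoring and gap-filling alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How tagalign works: seeding, tag scoring and gap-filling alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagalign)
```

## The problem and the approach

Mapping short sequencing reads to a reference genome has to tolerate
sequencing errors and small variants (mismatches and indels) while staying
fast enough for millions of reads. tagalign is a seed-and-extend aligner:
instead of backtracking through an index to handle mismatches, it finds
*exact* matches of selected read substrings (seeds), lets those matches
vote for candidate genomic regions, and only then runs a restricted
dynamic program against the few best candidates.

Alignment of one read has two phases:

1. **Seeding and scoring.** Maximal seeds are extracted greedily from the
   read; every exact occurrence of a seed grants the seed's length, in bp,
   to the genome partition (*tag*) estimated to contain the read start.
2. **Precise alignment.** The top-scoring tags become candidate regions.
   Within each candidate, the tag's own seed matches are chained into
   fixed exact blocks, and only the gaps between blocks are aligned with a
   banded unit-cost dynamic program. The candidate with the smallest edit
   distance wins.

## The index: one FM-index for both strands

The forward sequences are concatenated, the reverse complement of the
whole concatenation is appended, and a BWT/FM-index is built over this
doubled text (plus a terminator). Because the doubled text is closed under
reverse complement, a single backward-search engine supports both search
directions:

* `match_right_to_left()` extends a suffix of the query leftward one base
  per step, maintaining the suffix-array interval (the occurrence count is
  the interval width);
* `match_left_to_right()` extends rightward by running the same backward
  search on the reverse complement of the query window, returning only the
  matched length.

Locate resolves a BWT row `p` to coordinates: positions in the forward
half map directly to strand `+`; positions in the reverse half fold back
to the forward coordinate `2G − p − len` with strand `−`, so all
downstream bookkeeping uses one coordinate system plus a strand bit. Hits
spanning the junction between concatenated sequences, or between the
forward and reverse halves, are rejected at locate time.

Numerical/representation choices: the suffix array is stored in full (no
sampling) — at the Mbp scales this package targets the memory cost is
trivial and locate stays O(1); occurrence counts are checkpointed every 64
BWT rows; the suffix array is built by comparison sort, which is entirely
adequate for random-ish references but degrades on references dominated by
very long exact repeats (e.g. megabase poly-N runs). `N` bases are encoded
as a sentinel outside the query alphabet, so no exact seed can span an N,
which prevents spurious anchors in assembly gaps.

## Seed extraction

Seeds must (1) be at least `k` bp long, (2) pairwise overlap by at most
`k − 1` bp, (3) occur exactly somewhere in the (two-strand) reference, and
(4) be maximal — extending any seed by one base either loses all exact
matches or breaks the overlap bound. The extraction loop walks the read
from its right end: probe the rightmost uncovered `k`-window left-to-right;
if the probe fails after `j < k` bases, skip the unmatched tail (any seed
containing it must fail too — this skip is what makes the greedy pass
cheap); if the window matches fully, extend it leftward maximally, emit
the seed's occurrences, and resume with the `k − 1` leftmost bases of the
window available for reuse.

`k` follows a read-length schedule: 16 below 50 bp, then 20 / 24 / 28
from 50 / 200 / 500 bp. The first breakpoint is the established default
for short reads; the growth steps are this package's choice (the
overall principle being only that longer reads can afford longer, more
specific seeds), and the whole schedule is a tunable table. Repeat
protection: at most `P = 50` occurrences per seed are scored, taken in
BWT-row order; junction-rejected rows do not count against `P`.

## Tags and the reset-free score table

Tags are consecutive, non-overlapping genome partitions of length
`L = R·c` (read length times `c = 10` by default). A seed whose match
starts at genome position `m` with `n` read bases to its left estimates
the read start at `m − n`; the tag containing that estimate is granted the
seed's length. For an indel-free read all seeds agree on the estimate; with
indels smaller than `L` the grants stay within at most two adjacent tags,
which is harmless because `t = 10` candidate tags (not just one) go to
phase 2. Strand is part of the tag key: a `+` and a `−` placement at the
same coordinate are different alignments and must not pool scores.

Scores live in an open-addressing hash table that is *never cleared*:
each record carries the serial number of the read that wrote it, and a
record whose serial is stale is treated as empty. Advancing the serial
(one integer increment) therefore invalidates the whole table between
reads — the observable behavior is identical to allocating a fresh table
per read, which the test suite checks by fuzzing against exactly that
oracle. A ranked list of the top `t` records is maintained incrementally:
since scores only grow within a read, the new top-t after any grant is a
subset of {old top-t} ∪ {the granted record}, so the list update is O(t).
Ties rank the lower tag id first, then `+` before `−`, making the whole
pipeline deterministic.

## Precise alignment: anchors plus banded offset DP

For each candidate tag, its stored seeds are chained greedily (longest
first, ties leftmost) into a consistent set of anchor blocks: collinear,
disjoint in read and genome, with diagonal offsets of adjacent anchors
differing by less than `d`. The candidate window is the anchor span plus
whatever the read needs on each side, extended by `e = 20` bp of slack.

Only the gaps between anchors are aligned. The DP is indexed by position
`i` in the read gap and by *offset* — the difference between reference and
read positions — restricted to `|offset| < d`:

```
D[i][off] = min( D[i−1][off]   + [ref[i+off] != read[i]],   # match/mismatch
                 D[i−1][off+1] + 1,                          # insertion
                 D[i][off−1]   + 1 )                         # deletion
```

with unit costs for mismatch and indel, O(d·n) time. Interior gaps run in
global mode (both ends anchored; the band must cover the length
difference). The two flanks leave the *reference* end free, so the window
slack never inflates the edit distance; the left flank is the mirror image
of the right (both sequences reversed). Boundary conditions: `D[0][off] =
off` for `off ≥ 0`, infeasible for negative offsets; traceback prefers
match, then deletion, then insertion — an arbitrary but fixed order.

Defaults: `d = e + 1 = 21`, on the reasoning that an indel larger than the
flank slack cannot be bracketed by the window anyway. If any gap's band is
infeasible the candidate is retried once with `2d`, then dropped. The
CIGAR uses `M` for match-and-mismatch (no `=`/`X`) and has no clips: reads
align end-to-end, so `M + I` ops sum to the read length and `M + D` ops to
the reference span — invariants asserted on every emitted alignment in the
tests.

Candidates are ranked by edit distance, then higher tag score, then lowest
coordinate, then `+` strand. There is no reporting threshold: a read with
at least one seed always reports its best candidate, which deliberately
favors recall over precision (the evaluator makes the trade visible).

## Mapping quality, pairing, output

MAPQ is a package-defined formula (the upstream algorithm does not define
one): with per-candidate score `s = R − edit`, a sole candidate gets 60,
tied best/runner-up scores get 0, otherwise
`min(60, floor(60·(s_best − s_runner)/max(s_best, 1)))`, where the
runner-up is the best candidate from a *different* tag.

Paired-end alignment aligns each end independently, keeps up to `t`
finalists per end, and enumerates all cross pairs on one sequence with
forward–reverse orientation and outer distance (leftmost start to
rightmost end) within `[min_insert, max_insert]` (defaults 0–1000 bp).
The pair maximizing the total score (sum of `R − edit`) wins, ties going
to the leftmost pair; the winner gets proper-pair flags and symmetric
TLEN. With no valid pair, both ends report their individual best without
the proper-pair flag.

Output is SAM 1.6 with `@HD`/`@SQ`/`@PG` headers and an `NM` tag. The
`workers` parameter chunks the input reads; each chunk is aligned with its
own tag table against the shared read-only index, so 1-worker and
N-worker runs produce identical record sets — the suite asserts equality
after sorting by read name.

## The simulator and the evaluator

`simulate_genome()` draws i.i.d. bases at a chosen GC content.
`simulate_reads()` emulates dwgsim-style Illumina reads: uniform start
positions, fair-coin strand, per-base substitutions uniform over the three
alternatives, indels opened at `indel_rate` per base (insertion or
deletion equally likely) with geometric length extension
(`indel_ext = 0.3`), and fixed read length. When `indel_rate` is not
given it defaults to a tenth of the substitution rate. The error profile
is uniform along the read — there is no quality ramp, no
platform-specific artifact model (homopolymer or flow errors), and read 1
of a pair is always the forward-strand end. Truth (sequence, strand,
1-based leftmost coordinate of the pre-error template span, error counts)
is kept in a tab-separated sidecar.

`evaluate_alignments()` counts a read correct iff it is aligned on the
true sequence and strand within a positional tolerance of the true
leftmost coordinate; recall is correct/all, precision correct/aligned.
The default tolerance of 20 bp equals the flank slack `e`: an indel inside
the read shifts the reported leftmost coordinate by at most the bracketed
indel budget, and the upstream benchmark protocol never states its own
criterion, so the package fixes one and documents it.

## What the synthetic benchmarks do and do not show

An i.i.d. genome is nearly repeat-free above the seed length, so seeds are
close to unique, candidate lists are short, and both recall and precision
run *higher* than they would on a mammalian genome, where segmental
duplications and transposon families create genuinely ambiguous
placements. The bundled experiments (a seeded 1 Mbp genome; 10,000 reads
per error-rate condition at 200 bp; 10,000 × 50 bp and 5,000 × 500 bp for
the length sweep; defaults everywhere; tolerance 20 bp) therefore validate
the *machinery* — seeding, scoring, banded gap alignment, ranking,
pairing — and track published full-scale results only as lower-bound
floors, not as point reproductions. These problem sizes are the package's
chosen desk-scale study conditions and run end-to-end in a few minutes on
one CPU.

Known limitations, by design: no affine gap penalties or quality-aware
scoring; no soft clipping (end-to-end alignment only); no secondary or
supplementary records; BAM/CRAM output is out of scope (SAM text only);
suffix-array construction is not optimized for pathological repeat
content; MAPQ is heuristic and package-specific.

## A worked example

```{r example}
ref <- simulate_genome(50000, gc = 0.5, seed = 11)
idx <- build_fm_index(ref)
sim <- simulate_reads(ref, n = 500, read_len = 100, sub_rate = 0.02,
                      indel_rate = 0.002, seed = 12)
sam <- align_reads(idx, sim$reads)
head(sam[, c("qname", "flag", "rname", "pos", "mapq", "cigar", "nm")])
evaluate_alignments(sam, sim$truth, tolerance = 20)
```
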