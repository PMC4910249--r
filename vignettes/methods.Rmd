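---
title: "Mapping reads on a compacted de Bruijn graph: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping reads on a compacted de Bruijn graph: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdbgmap)
```

## The problem

Short-read assemblies rarely end in a finished genome; what survives is an
assembly graph whose paths spell the sequence information, and a set of
contigs that record only some of those paths. Mapping reads against contigs
therefore loses reads whose true locus straddles a junction that the
assembler did not resolve. `cdbgmap` maps reads directly on the de Bruijn
graph instead: a read that crosses unitig boundaries is rewritten as a walk
of unitigs whose spelled sequence matches the read under a small Hamming
distance.

## The graph model

Given sequences over $\{A,C,G,T\}$ and an order $k \ge 2$, the de Bruijn
graph has the observed $k$-mers as nodes and an arc $d \to d'$ whenever the
$(k-1)$-suffix of $d$ equals the $(k-1)$-prefix of $d'$. A walk of $l$
single-$k$-mer nodes spells a sequence of length $k + l - 1$. Before
construction, $k$-mers with count below an abundance threshold $c$ are
discarded (`solid_kmers()`); this is the standard removal of
sequencing-error $k$-mers and is skipped ($c = 1$) when the input is a
trusted reference.

Compaction (`build_cdbg()`) merges every arc that is the unique out-arc of
its source and the unique in-arc of its target, until no such arc remains.
The resulting node sequences are the *unitigs*; each solid $k$-mer occurs in
exactly one unitig, exactly once, and no adjacent pair of unitigs remains
mergeable. Unitig ids `u1, u2, ...` are assigned by ascending unitig
sequence in the C locale, so all outputs are reproducible across sessions
and platforms.

Two constructions are under-determined by the model and fixed here by
explicit policy:

* **Isolated cycles.** A simple cycle all of whose nodes have in- and
  out-degree one has no canonical linearisation. It is broken at its
  lexicographically smallest $k$-mer and emitted as one linear unitig, which
  makes compaction terminating and deterministic. A self-looping single
  $k$-mer (e.g. `AAA`) stays a one-$k$-mer unitig.
* **Strands.** The default `strand_mode = "with_reverse_complements"` makes
  each sequence contribute the $k$-mers of both strands to an ordinary
  forward-strand graph (unitigs then occur in reverse-complement pairs).
  This keeps the graph model simple — no bidirected edges, no canonical
  $k$-mers — at the cost of a roughly doubled node set. `forward_only` is
  retained for deterministic toy examples and for simulation experiments
  where an unambiguous ground-truth path is wanted.

## Seeding: only unitig boundaries are indexed

Arcs of the compacted graph are witnessed by the $(k-1)$-mer prefix and
suffix of each unitig, called *overlaps*. The mapper indexes **only** these
overlaps (`build_overlap_index()`): they are long enough to be selective,
and — because every solid $k$-mer occurs exactly once — an overlap can be
shared by at most four unitigs starting with it and four ending with it
(one per extending base), eight in total. The index here is an exact
associative map; the original design used a minimal perfect hash, which is
a memory optimisation with identical semantics.

The documented trade-off of this choice is inherited deliberately: a read
lying wholly inside a long unitig contains no overlap and cannot be seeded
by this index. Such reads are handled by a separate containment stage
(`map_on_unitigs()`) that seeds the read's first $k$-mer (retrying at
positions $k$ and $2k$ if that $k$-mer carries an error) against a
positional index of all unitig $k$-mers and verifies full containment by
Hamming comparison.

## Greedy mapping on branching paths

`map_read_greedy()` maps a read across unitig boundaries under two
parameters with defaults taken from the reference configuration: a
cumulative mismatch budget $t$ (`max_mismatches`, default 2, inclusive) and
a per-direction anchor failure allowance $n$ (`anchor_failures`, default 2).

1. **Anchoring.** Every read position whose $(k-1)$-mer is an indexed
   overlap is an anchor. The first usable anchor (ascending order) must
   align the whole left flank of the read against the suffix of a unitig
   ending with that overlap, within $t$; symmetrically the last usable
   anchor must align the right flank against the prefix of a unitig
   starting with it. Each anchor whose candidates all fail consumes one of
   the $n$ failures; a read that cannot anchor on either side is
   `UNMAPPED_UNANCHORED`.
2. **Extension.** From the left anchor the walk grows left to right: at the
   current overlap, the at most four unitigs starting with it are aligned
   against the read (only the positions beyond the shared overlap are
   counted, truncated at the read end) and the minimum-mismatch candidate is
   accepted — greedily, with no backtracking — as long as the cumulative
   count stays within $t$; otherwise the read is `UNMAPPED_OVER_BUDGET`.
   Each accepted unitig advances the cursor by its length minus $(k-1)$, so
   the whole mapping costs a bounded number of comparisons per read
   position.
3. **Shortcut.** When one of the candidates ends exactly on a detected
   anchor whose word equals that candidate's end-overlap, it is tested
   first and accepted immediately if it keeps the budget — the other
   candidates are then not aligned at all. The wording of this optimisation
   in the original description is ambiguous; the reading adopted here is
   the one above, and it is disabled at the first and last overlap of the
   read, where extremity anchoring governs.

Ties are always broken toward the smallest unitig id, and between
orientations toward forward. By default each read is also mapped as its
reverse complement and the lower-mismatch orientation is kept.

### The position-zero boundary case

When the chosen left anchor sits at read position 0, a literal application
of the extremity rule would prepend a predecessor unitig of which the read
covers only the shared $(k-1)$-mer — an arbitrary choice among up to four
equally valid predecessors, none of which the read gives evidence for. The
package therefore starts the walk with the first extension candidate
instead. Consequently a walk of length one can emerge from the
branching-path mapper; since its alignment crosses no unitig boundary it is
by definition a containment, and `ggmap()` reclassifies it as
`MAPPED_UNITIG`. This keeps the branching-path/containment split aligned
with the definition of the two mapping situations (a branching-path mapping
spans at least two unitigs).

### Walks, not paths

The formal decision problem behind this mapper is stated on simple paths,
but reads across genomic repeats legitimately revisit unitigs, so the
implementation traverses walks, capped at one step per read base to force
termination. This is a practical-fidelity choice, not an oversight.

## The exhaustive reference mode

`map_read_exhaustive()` anchors identically and then enumerates *all*
candidate successions depth-first, pruning only when the cumulative
mismatch count exceeds $t$, and returns the minimum-mismatch walk
(ties: lexicographically smallest id sequence). It exists to quantify the
cost of greediness: the greedy mapper can commit to a locally best branch
that dead-ends (the test suite contains a minimal constructed instance).
Exhaustive mapping is sound and complete with respect to anchored walks, so
it maps a superset of the greedy-mapped reads and never with more
mismatches — both facts are asserted over hundreds of randomized instances
against an independent brute-force enumerator. A hard cap of $10^6$
expanded states turns pathological searches into an explicit error rather
than a silently truncated answer.

## The simulation harness and what a green test establishes

`random_genome()` draws i.i.d. uniform bases; `simulate_reads()` samples
fixed-length reads uniformly from the forward strand and substitutes each
position independently with the stated error rate (replacement uniform over
the three alternatives), recording the error positions. The evaluation
(`evaluate()`) builds the graph from **all** genome $k$-mers ($c = 1$, the
reference-graph setting), maps reads at rates 0, 0.1, 0.2, 0.5, 1 and 2 %,
and reports recall plus the *distance to optimum* of each mapped read: the
number of mismatches between read and spelled walk at the read's error-free
positions, binned as 0, 1, 2, 3, $\ge 4$. A read mapped at its true origin
has distance 0; because of repeats the measured value is an upper bound on
the true suboptimality.

Defaults chosen where the methodology leaves them open: 100 bp reads
(typical short-read length; the original experiment does not state one),
50 kb genomes for the evaluation experiment, and forward-only simulation so
that the origin path is unambiguous ground truth.

What the generator does *not* emulate: coverage bias, quality profiles,
indels (the whole cost model is substitution-only by design), real genomic
repeat structure, and heterozygosity. A uniform random 50 kb genome has
almost surely unique $(k-1)$-mers at $k = 21$, so the evaluation's
"100 % recall, 100 % at distance 0" outcome at rate 0 certifies the
mapper's bookkeeping, not its behaviour on repeat-rich genomes; the
saturated small-$k$ graphs used elsewhere in the tests probe the branching
behaviour instead. Greedy-vs-exhaustive gaps measured on such saturated
random graphs are much larger than on a real bacterial graph, which is
expected: branch density, not biology, drives the gap.

## Numerical and tie-breaking choices, in one place

* Mismatch budget is inclusive ($\le t$); "up to two mismatches" reads as 2
  being allowed.
* One anchor failure is charged per exhausted anchor, not per failed
  candidate; the extremity search stops at the $n$-th failure.
* Extremity unitigs must cover the whole flank; a too-short candidate
  counts as a failed candidate.
* `N` mismatches everything, including `N`; $k$-mers containing non-ACGT
  characters are skipped during counting and can never anchor.
* All ties: smallest unitig id, then forward orientation; cycle break at
  the lexicographically smallest $k$-mer; ids by C-locale sequence sort.
* Coordinates in every output are 0-based half-open.
* Duplicate read ids are suffixed `/2`, `/3`, ... on ingestion.

## Known limitations

Substitutions only — no indel alignment, hence no use on long noisy reads.
Anchoring requires at least one exact $(k-1)$-mer arc match in the read, so
highly divergent queries fail to anchor before they fail the budget. Only
the single best mapping is reported; equal-best secondary locations are
not. The in-memory exact index targets desk-scale data, not
billion-$k$-mer graphs.
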