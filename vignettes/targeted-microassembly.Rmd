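---
title: "Targeted micro-assembly around starter sequences: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted micro-assembly around starter sequences: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedasm)
```

## Scope and model

`seedasm` answers a local question about an unassembled read set: is a
given sequence fragment (a *starter*) supported by the reads, in which
variant forms, and what sequence surrounds each form? It is not a genome
assembler; it deliberately produces short, locus-scale output (hundreds to
a few thousand nucleotides) whose value is structural: variant
enumeration, coverage, and branching context.

The method assumes substitution-dominated sequencing errors (Illumina-like
data). Indels are not modelled anywhere: read placements are rigid offsets,
the distance between placed sequences counts substitutions only, and a
read whose alignment would need a gap simply fails the distance test.
Starters over the plain `{A,C,G,T}` alphabet are required; `N` in reads is
tolerated but never matches anything, so it behaves as a guaranteed
mismatch and is usually repaired or truncated by error correction.

All coordinates are 0-based and signed. The central primitive is the
overlap-aware Hamming distance `overlap_hamming(w1, i, w2)`: substitutions
counted over the overlapped positions only, with overhangs free. Because a
placement with an empty overlap would trivially have distance zero, the
mapping predicate `is_mapped()` additionally requires a minimum number of
overlapped positions; the pipeline uses `k`, which is the natural floor
since every seed-discovered placement shares a full k-mer.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` (nt) | 25 | seed length for indexing and mapping; 25 suits 70–100 nt reads. For shorter reads choose `k` so one substitution still leaves an exact seed (`k <= (L-1)/2`, e.g. 15 for 30 nt reads). |
| `d` (substitutions) | 1 | maximum distance between a starter and each sub-starter consensus. Small by design: variant enumeration grows like the number of substitution combinations, and the package caps output at `cap` sub-starters. |
| `c_min` (reads) | 2 | minimum per-position coverage of a sub-starter and minimum column support during extension; 2 is the smallest value that distinguishes support from a singleton artifact. |
| `t` (votes) | `c_min` | error-correction vote threshold. The method never specifies `t` independently; tying it to the coverage threshold keeps a single support knob. Raise both on deep data. |
| `max_iterations` | 10 | extension rounds; each round advances roughly `L - k` nt per open path. |
| `cap` | 100 | maximum sub-starters per starter, guarding against combinatorial blow-up at large `d`. |
| `frontier_cap` | 1000 | maximum simultaneously open extension fragments (pathological branching guard; logged when hit). |

## Sub-starter enumeration

Problem: among the error-corrected reads mapped to a starter `s`, find all
*maximal* subsets that (1) admit a perfect consensus, (2) whose consensus
is within `d` of `s`, and (3) cover every position of `s` at least
`c_min` times. Subsets satisfying (1) are exactly the sets of pairwise
compatible reads, where two placed reads are compatible when their
(possibly empty) overlap has zero mismatches.

The enumeration is a single sweep over reads ordered by `(offset, text,
id)` — the tie order is a package choice; any fixed total order gives
deterministic output. Each incoming read is appended to every candidate
whose members it is all compatible with; for a partially compatible
candidate, a new candidate is branched from exactly the compatible
members; an unplaceable read opens a singleton. Two prunes run as the
sweep passes position `p`: candidates whose consensus already exceeds `d`
differences with `s`, and candidates with a coverage hole before `p`
(reads are sorted by start, so no later read can mend it). Candidates
strictly included in other candidates are also dropped: a pairwise
compatible superset of a valid subset is itself valid, so included
candidates can never be maximal. With these prunes the number of live
candidates stays within the substitution-combination bound `4^d` on
error-free inputs, which the test suite asserts.

Branching from *all* compatible members (rather than from the most recent
overlapping read only) is deliberate: with variable-length reads —
truncation during error correction produces them routinely — or with
exactly touching reads, a last-read rule can miss maximal subsets. The
chosen rule is provably complete: every candidate is pairwise compatible
by construction, and inductively every maximal valid subset is built. The
test suite checks exact agreement with a power-set enumeration oracle on
500 randomized planted-variant instances (≤ 8 reads, starter ≤ 12 nt,
`d ≤ 2`, `c ≤ 2`).

Finalization re-checks all three conditions over the full span of `s`
(the sweep cannot check coverage after the last branch point), keeps
maximal candidates, deduplicates identical consensuses, trims consensuses
to the coordinate span of `s` (supporting reads may overhang), and caps
the output, preferring higher minimum coverage with lexicographic
tie-break. Condition (3) is evaluated per subset, matching the per-subset
structure of the problem statement. A starter is *read coherent* iff at
least one sub-starter survives.

Two consequences worth knowing. First, when two variant sites are farther
apart than any read, all four allele combinations are reported (two of
them potential false positives) — this is unavoidable without longer-range
information, and it is precisely the behaviour the acceptance target
checks. Second, when some but not all reads span both sites, chimeric
combinations may still qualify: a combination is excluded only when every
read covering one site also covers the other.

## Error correction

Votes are tallied once from the raw mapped pileup; corrections do not
cascade (no re-vote after a substitution), which makes the pass
idempotent. A position with its own nucleotide below `t` and not exactly
one alternative at `t` or above truncates the read before the position.
Reads shorter than `k` after truncation, and reads that no longer satisfy
the mapping predicate at their placement, are dropped. "At least `t`" is
read inclusively (`>= t`) throughout.

## Extension and the graph

Extension works at `d = 0`: reads must agree perfectly with the fragment
they extend. Beyond a fragment end, the column-wise rule is minimal and
local: a column where one nucleotide has support `>= c_min` extends the
path; a column where several do branches (each branch keeps its own
supporting reads); a column where none does terminates the path without
storing the column. Each stored extension is *enriched* with the `k-1`
terminal characters of its parent so that k-mers spanning the junction are
indexable in the next round.

Both directions are extended by rooting a second graph on the reverse
complement of the sub-starter and mirroring it back at the end; the two
one-sided graphs are joined at a single root. Convergence (bubbles closing
after a SNP, repeat copies re-entering shared sequence) is detected by
probing each new enriched extension's k-mers against an index of every
node's terminal k-mer, scanning left to right and taking the first
verified hit. A hit must overlap the existing node's text perfectly over
at least `k` positions. Three offset cases follow the rule set: offset 0
links directly; negative offsets insert an intermediate node holding the
extension's unmatched prefix; positive offsets prune the parent's
duplicated suffix before linking. Two package-specific restrictions keep
the spelled sequence content exactly consistent: positive-offset
convergence is honoured only up to `k-1` (beyond that the pruned suffix is
no longer provably identical to the duplicated characters) and never
applied to the root (whose text is the sub-starter itself); anything else
becomes a fresh node. An extension may overhang the node it converges
onto; the overhang is discarded because the converged-onto path re-derives
it when it is itself extended.

In sequence mode, a branching event stores only the longest common prefix
of the branches and stops that path. The optional SNP-merge collapses a
branching event whose branches are identical except at exactly one
position into the majority nucleotide; branches stopped by coverage at
different columns are compared over their common length, the trimmed
remainder being re-derived next round. Factorized or merged characters
carry the element-wise sum of the branch coverages — totals of the read
support for those characters.

Simplification applies three rules: strip the `k-1` enrichment prefix of
every non-root node; merge simple paths; factorize the longest common
prefix of single-parent sibling nodes into their parent (and symmetrically
suffixes), relocating branch points to the exact divergence position.
Rules two and three repeat to fixpoint; prefix factorization runs before
suffix factorization; factorization leaves at least one character in every
node (degenerate full-prefix children would otherwise vanish and change
the spelled-path multiset). The multiset of root-to-leaf strings is
invariant under simplification — asserted on 200 random graphs per test
run.

## The simulators, and what passing tests show

The generators produce: uniform shotgun reads (uniform starts, both
strands equiprobable, i.i.d. substitution errors at a given rate); a
two-haplotype starter with two biallelic sites at exact per-haplotype
depth (phase-staggered error-free tilings, so edge positions reach full
depth); and a reference carrying `n` exact copies of a unit in distinct
random flanks. All are pure functions of their parameters and a seed, with
per-read draws in fixed order.

They emulate what the method is specified against: substitution-only
errors, uniform coverage, exact repeat copies, clean biallelic sites. They
do *not* emulate indels, quality-correlated or strand-biased errors,
coverage waves, near-identical (diverged) repeat copies, or sampling noise
in the two-site case. Passing tests therefore demonstrate algorithmic
correctness under the model's own assumptions, not robustness to
real-library artifacts; on real data the practical knobs are `t`, `c_min`
and `d`, raised in step with coverage.

Problem sizes in the test and acceptance suites are desk-scale by design:
oracle equivalence on 500 instances of ≤ 8 reads, spelled-string
preservation on 200 graphs of ≤ 9 nodes, end-to-end recovery on 260–600 nt
references at 15–30× coverage, and the streaming contract on a one-million
read file of which exactly ten reads map (the retained structures stay
about five orders of magnitude smaller than the file). These sizes
exercise every code path while keeping a full run in minutes.

## Known limitations

- No indel handling anywhere (mapping, correction, extension): a
  homopolymer-error-prone technology will truncate many reads.
- Seed sensitivity: a read maps only if it shares one exact k-mer with a
  target, so at distance `d > 0` a variant can sit where it breaks every
  seed of the reads that carry it near the starter edge; choose `k` with
  the read length in mind (`k <= (L-1)/2` tolerates one substitution
  anywhere).
- Sub-starter generation is quadratic in the number of mapped reads —
  starters above 10^4 nt are warned against.
- Paired-end information is ignored; branch combinations a read cannot
  phase are all reported.
- Repeat-induced convergence can create cycles in the extension graph;
  they are tolerated (traversals guard against revisiting) but simplified
  conservatively.
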