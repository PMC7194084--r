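---
title: "Merging multi-caller structural variant predictions: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging multi-caller structural variant predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`svintegrate` treats an SV prediction as a 1-based inclusive genomic
interval `[pos1, pos2]` of one of three types (deletion, duplication,
inversion), carried by one caller, with a caller-specific support
string. Two same-type predictions on one chromosome describe the same
event when their *reciprocal overlap* — the intersection length divided
by the longer constraint of the two interval lengths,
`RO = min(o/len_a, o/len_b)` — strictly exceeds `overlap_frac`
(default 0.8, i.e. "more than 80%"). The strictness matters: a pair at
exactly 0.8 is *not* linked, and the tests pin this boundary.

Pairwise distances are 0/1 indicator distances (0 iff linked).
Single-linkage hierarchical clustering of such a matrix, cut anywhere
strictly below height 1, yields exactly the connected components of the
link graph. The default implementation therefore computes components
directly — candidate pairs from `GenomicRanges::findOverlaps()`, exact
RO on those pairs, union–find over the surviving edges — which scales
linearly in the number of overlapping pairs instead of quadratically in
records. The dense `hclust(method = "single")` formulation is retained
behind `linkage = "hclust"` purely so the two routes can be checked
against each other and against a brute-force BFS oracle; with 0/1
distances, single linkage is the only linkage under which "cluster"
means "overlap chain", which is what the merge semantics need
(complete or average linkage would split chains like A~B~C with
RO(A,C) < 0.8 arbitrarily).

A cluster supported by at least `min_methods` distinct callers
(default 2) is merged into one SV: `pos1` and `pos2` are the means of
*all* member breakpoints, rounded half-up to an integer base.
One-method clusters are discarded — agreement between algorithms is the
whole point of the exercise. The source material is ambiguous about the
discard threshold ("two or more methods" in one place, "more than two"
in another); the worked output it prints contains two-caller merges
such as `Pindel:Delly`, so ≥ 2 is the behaviour matched here, and the
threshold is exposed as `min_methods` anyway.

When one caller contributes several members to a cluster, its
coordinates all enter the breakpoint means (they are evidence) but the
caller appears once in the `methods` string and contributes the info
string of its best-supported member: the discard rule counts methods,
not records.

## Filters

Every reader applies its caller's support gates and a global size
window; both are user-overridable through `merge_params()`:

| Parameter | Default | Meaning |
|---|---|---|
| `overlap_frac` | 0.8 | strict reciprocal-overlap link threshold |
| `min_methods` | 2 | distinct callers required to keep a cluster |
| `min_size` / `max_size` | 100 bp / 10 Mb | effective-size window, all callers |
| BreakDancer `min_score` / `min_pe` | 60 / 3 | confidence score; discordant pairs |
| Pindel / SVseq2 `min_sr` | 3 | split reads |
| DELLY `min_support` | 3 | PE + SR summed |
| Lumpy `min_su` | 3 | total evidence (SU) |
| SoftSearch `min_sr` **and** `min_pe` | 3 / 3 | conjunctive: both must hold |

The *effective size* tested by the window is `|reported size|` when the
caller printed one, else the coordinate span. This is forced by real
caller behaviour: BreakDancer can print an inversion whose breakpoints
are 47 bp apart with size −105; a span-based filter would silently drop
a record the reference implementation demonstrably retains.

Only BreakDancer, Pindel and SoftSearch have gates stated by the source
material. DELLY, Lumpy and SVseq2 are only shown to have *been*
filtered (raw vs formatted counts), not how; this package applies the
same "support ≥ 3" convention — summed PE+SR for DELLY, SU for Lumpy,
split reads for SVseq2 — as its own documented choice, for consistency
with the stated rules. CNVnator, a read-depth caller, has no per-event
read count and gets only the size window.

Within one caller, overlapping same-type predictions are resolved
(`resolve_self_overlaps()`) by keeping the member with the largest
primary support value (PE, SR or SU as applicable), ties broken by
smaller `pos1`, then `pos2`. The reference behaviour is stated only as
"resolved" without a rule; greedy best-support is deterministic and
support-maximizing, and the merge step independently collapses
within-caller duplicates anyway, so this choice affects only
single-caller workflows.

## Coordinate conventions

Coordinates are 1-based inclusive everywhere except inside format
readers/writers:

* BreakDancer, CNVnator region strings, Pindel-derived events, SVseq2
  lines: used as printed (already 1-based).
* Pindel's two `BP` fields flank the event; the record is
  `[BP1 + 1, BP2 − 1]`.
* VCF (DELLY, Lumpy, SoftSearch): POS of a symbolic allele is the base
  *before* the event, END its last base; the record is
  `[POS + 1, END]`.
* Lumpy BEDPE: 0-based half-open breakpoint intervals; the event is
  `[start1 + 1, end2]`.
* BED output converts back to 0-based half-open; VCF output writes
  `POS = pos1 − 1`, `END = pos2`.

CNVnator's size column is bin-derived; the reader recomputes size as
`end − start`, which reproduces the sizes the reference output prints
(e.g. 6599 for `104101–110700`) and is one less than the inclusive
span. Records above the size window by either measure are far from the
boundary in practice; the choice is documented here once and not
revisited.

## Annotation

Gene models come from GFF3 via `rtracklayer`. Introns are derived per
transcript as the gaps between consecutive exons and deduplicated per
gene by coordinates. Optional `upstream`/`downstream` elements extend
`flank` bp (default 2000 — a conventional promoter-proximal window)
beyond each gene, strand-aware, clipped at position 1 and at the
chromosome end when sizes are supplied. An SV is annotated with *every*
element it shares ≥ 1 bp with; there is deliberately no
minimum-fraction rule for annotation, because none is stated and a
1-bp exonic breakpoint is biologically meaningful. "Genes affected by a
type" counts distinct gene IDs with at least one overlap row of that
type — any overlap, not exonic-only; with the alternative definition
the counts would differ on real data, which is why the choice is spelt
out here.

## Visualization

`window_counts()` tiles each chromosome with non-overlapping windows
(default 1 Mb) and assigns each SV to the single window containing its
midpoint. Midpoint assignment is a partition, which buys the
conservation invariant the tests assert (per-type window sums equal
input counts); counting an SV in every window it touches would be the
other defensible convention, and is not what this package does. The
circular and linear layouts consume the same `WindowCounts`, so
statistics are layout-independent. Rendering uses fixed explicit
devices (`grDevices::png`/`svg`) so identical inputs produce
byte-identical files. Colors default to: genome plot — deletions blue,
duplications red, inversions green; region plot — genes blue,
deletions red, duplications green.

## The synthetic benchmark

`simulate_truth()` + `emit_caller_outputs()` model *caller outputs*,
not sequencing: no reads, no alignment, no coverage model. The stated
world is: truth SVs placed uniformly (chromosomes weighted by length)
with log-uniform sizes in [200 bp, 100 kb]; the benchmark scenario
plants 120 deletions, 50 duplications and 30 inversions on five 20 Mb
chromosomes, reports each truth SV through ≥ 2 of five callers with
each breakpoint independently jittered by up to 5% of the SV length,
and adds 50 caller-unique false positives per caller.

The construction is *guaranteed recoverable*, and the guarantee is
arithmetic, not empirical: with `jitter_frac = j < (1 − overlap_frac)/2`
(validated at run time), two jittered copies of one truth SV of length
L overlap by at least `L(1 − 2j)` while each spans at most `L(1 + 2j)`,
so their RO is at least `(1 − 2j)/(1 + 2j)`; at j = 0.05 that is 0.818
> 0.8. Placement keeps a padded occupancy registry (30% of each
interval's length plus 100 bp on both sides) so jittered copies of
*different* truth SVs can never touch. False positives enter the same
registry; being caller-unique, they always form one-method clusters and
are discarded. Hence precision = recall = 1 is the *correct* outcome on
this fixture, and any deviation is a defect, which is what the
end-to-end acceptance test asserts. Sub-threshold records (score < 60,
support < 3, size < 100 bp, size > 10 Mb — each violating exactly one
gate) are placed without occupancy checks, because readers must remove
them before merging; the filter-audit test verifies exactly that.

What a green benchmark does **not** establish: behaviour on real data —
correlated caller errors, breakpoint uncertainty larger than 5%,
overlapping true events, translocation-contaminated call sets,
coverage-dependent support values. The simulator's independence
assumptions (independent jitter, independent reporting-caller choice,
unique false positives) are exactly the assumptions real callers
violate; the benchmark validates the *bookkeeping* of the pipeline, not
its biological error rates.

## Numerical and degenerate-input choices

* Mean breakpoints are rounded half *up* (`floor(x + 0.5)`), not
  banker's-rounded, so merged coordinates are stable integers.
* Cluster labels are first-appearance ordered; ties in self-overlap
  resolution break by (support desc, pos1, pos2) — fully deterministic.
* Readers hard-error on structurally broken input (missing columns,
  unparseable CNVnator lines — which also guards against stray files in
  call directories) but *skip-and-log* records that are merely outside
  the SV universe (translocations, breakends, interchromosomal rows).
  Every skipped record carries exactly one reason, and
  raw = kept + skipped per type is asserted in tests.
* `methods_merge()` with fewer than two call sets, unknown output
  formats, malformed region strings and unknown callers are
  configuration errors (CLI exit 2); unreadable or malformed data files
  are data errors (exit 1).
* All simulator randomness flows through `withr::with_seed()`, so the
  global RNG state is never mutated and the simulate → emit → read →
  merge → evaluate chain is byte-reproducible under a fixed seed.

## Known limitations

* Insertions, translocations and breakend notation are out of the SV
  universe (del/dup/inv only); such records are logged and skipped.
* No breakpoint-precision weighting: all members of a cluster count
  equally in the coordinate means regardless of caller resolution.
* No genotyping, liftover or multi-sample support.
* Reader dialects target the layouts exercised by the built-in
  emitters (and standard VCF 4.x); exotic historical caller versions
  may need pre-formatting.
* The SVseq2 layout supported here (per-chromosome `*.del` files of
  `start end split_reads` lines) is a simplified dialect of a caller
  whose native output format varies between releases.
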