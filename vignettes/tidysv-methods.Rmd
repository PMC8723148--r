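---
title: "Methods and design of tidysv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of tidysv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the data model, algorithms, parameter choices and
known limitations of `tidysv`, including the places where the design was
genuinely open and why the implemented option was chosen.

## The tidy linked-table model

A VCF line packs many values into the INFO and FORMAT columns; an
`SVContainer` unpacks one sample's calls into five linked tables: a
positions table (one row per SV event: both breakend coordinates,
strands, quality, type), a long filters table, one long `(id,
value_index, value)` table per INFO key, a long FORMAT table and header
metadata. Multi-valued keys occupy several rows with a 0-based
`value_index`; no cell ever stores a packed list. Every derived quantity
(BED annotations, microhomology, SV classes, merge provenance) enters the
model as just another INFO table, so it survives export to VCF/BEDPE and
is queryable with the same filtering grammar as native fields.

Coordinates are 1-based VCF-style everywhere inside the package;
conversion to 0-based half-open happens only when reading/writing BED and
BEDPE. Keeping a single internal convention avoids the classic
off-by-one errors that are fatal for breakpoint-resolution analyses such
as microhomology inference. Breakend strand follows the BEDPE community
convention: `+` retains the segment left of the position, `-` the segment
right of it, so deletions are `(+,-)`, tandem duplications `(-,+)` and
inversion junctions `(+,+)`/`(-,-)`.

## Caller dialect normalization

The four supported callers encode the same event differently.
Orientation is normalized as: Delly `CT` `3to5/5to3/3to3/5to5` →
`(+,-)/(-,+)/(+,+)/(-,-)`; Lumpy `STRANDS=±±:count` parsed directly;
Manta `INV3`/`INV5` → `(+,+)`/`(-,-)`; `SVLEN` signs are normalized to
magnitudes. Bracket-ALT breakend pairs are collapsed to one record keyed
by the lower-coordinate mate (chromosomes compared as plain strings —
no ordering is mandated anywhere, and any fixed total order works);
`MATEID`/`SECONDARY` are dropped at that point because they describe the
two-line representation, not the event, while all other INFO keys are
preserved verbatim. For intrachromosomal breakend-only events (Gridss
emits nothing else) the SV type is inferred from the strand pair, which
is what makes the four dialects converge to identical normalized tuples;
interchromosomal adjacencies stay `BND`. Gridss single breakends (ALT
with a `.` terminus) are retained with an unresolved second breakend and
are excluded from merging and classification rather than guessed at.
Missing `CIPOS`/`CIEND` become the degenerate interval `(0,0)`.

## Annotation

BED tracks are indexed as `GRanges` (interval trees / nested containment
lists) and queried with each breakend's point position. The membership
rule for a 1-based position `p` against a 0-based half-open interval
`[s, e)` is `s < p ≤ e`; both boundary cases are pinned by tests and by a
brute-force all-pairs oracle. Annotation is per breakend (keys `name1`,
`name2`) rather than per event, preserving information; classification
predicates can combine the two flags. The breakend *point* is the query
locus — CI-aware annotation (expanding the query by the caller's
confidence interval) was considered and deliberately left out to keep the
semantics unambiguous; it can be emulated by widening the BED intervals.

## Filtering grammar

Conditions are `"item op value"` strings with `op ∈ {==, !=, <, <=, >,
>=, in, not in}` over `svtype`, `svlen`, `qual`, `filter` or any INFO
key. Several conditions form a conjunction; disjunction is expressed by
filtering twice and taking `container_union()`. The grammar is
intentionally minimal (no parenthesised boolean expressions): every
condition is independently testable, and the first-match-wins rule lists
of the classification module supply the remaining expressive power. On
multi-valued keys a comparison holds if *any* value satisfies it,
matching VCF multi-value semantics; records lacking the item never match.

## Multi-caller merging

Two records are linked iff three conditions hold: (i) coordinate
agreement — proximity mode: same ordered chromosome pair and both
breakend distances ≤ `threshold`; confidence-interval mode: the
CIPOS-derived intervals around `pos1` overlap ≥ 1 bp and likewise for
`pos2` (both breakends must overlap — the stricter symmetric reading);
(ii) strand concordance at both breakends; (iii) span overlap ≥ 1 bp for
intrachromosomal records. Condition (iii) exists to keep nearby but
non-overlapping small events apart; it is waived for interchromosomal
pairs, whose span is undefined, and insertions use the reference span
`[pos1, pos1 + max(svlen, 1)]`. SV-type equality is *not* required
directly: after normalization, strand concordance already separates
deletion-like, duplication-like and inversion junctions.

Events are connected components of the link relation (union–find over
windowed candidate pairs; an O(n²) pairwise oracle with independent
connected components verifies it on random instances). Transitive
closure means a chain of pairwise-close records can span more than
`threshold` end to end; this is the intended clustering reading of
"records within a threshold are merged". Representative records are
taken verbatim from the first supporting caller in input order — no
coordinate averaging, so output coordinates always exist in some input.
Merge provenance (`mergedid`, `supportingcaller`,
`supportingcallercount`, `originalid_<caller>`) is stored as INFO and
survives VCF export.

## Microhomology

For a canonical deletion junction (strands `+,-`, positions `p1 < p2`)
the forward extension is the largest `f ≤ max_len` with
`ref[p1+1..p1+f] == ref[p2+1..p2+f]`, the backward extension the largest
`b ≤ max_len − f` with `ref[p1−b+1..p1] == ref[p2−b+1..p2]`, and
`hom_len = f + b`, `hom_seq = ref[p1−b+1..p1+f]`. This two-way,
junction-spanning form (rather than one-way extension) is the standard
microhomology definition; the backward budget `max_len − f` keeps
`hom_len ≤ max_len`. A breakend whose strand differs from its canonical
role orientation has its flanks read on the reverse complement, which
makes an inversion junction and its strand-flipped mirror give equal
lengths (a tested invariant). Comparisons are case-insensitive, `N`
never matches, windows truncate silently at contig ends, and for
intrachromosomal events `hom_len` is capped at `svlen` (trimming the
backward extension first), since homology cannot exceed the rearranged
segment. A non-empty inserted sequence at the junction (captured from
bracket ALTs into the `insseq` key) forces `hom_len = 0`: a templated
insertion interrupts junctional homology. The default search window
`max_len = 200` bp comfortably covers the microhomology range relevant
to end-joining and template-switching mechanisms (usually < 30 bp) at
negligible cost; caller-supplied `HOMLEN`/`HOMSEQ` are left untouched
under their original keys so both estimates can be compared.

## Classification and feature matrices

A `ClassDefinition` is an ordered list of named predicates
(first-match-wins, fallback class for the rest) plus optional *preparer*
functions that annotate the container with the INFO keys the rules need.
Two schemes ship with the package:

* `simple`: translocation + {DEL, DUP, INV} × five length bins
  (<1 kb, 1–10 kb, 10–100 kb, 100 kb–1 Mb, ≥1 Mb), 16 rules.
* `pcawg_like`: 25 classes over three axes — one fragile-site class
  (either breakend on a CFS, evaluated first), {DEL, DUP, INV} ×
  {early, late replication} × {<50 kb, 50–500 kb, ≥500 kb} (18), three
  unknown-timing classes, translocation, insertion, and the fallback.
  The 50 kb / 500 kb breakpoints are the duplication-size boundaries
  used in the cancer-signature literature. Replication timing is classed
  by the first breakend's annotation; absent or conflicting values give
  `unknown` — a single deterministic rule rather than a heuristic vote.

The feature-matrix schema is always rule order plus the fallback column,
so its width depends only on the definition (17 columns for `simple`, 25
for `pcawg_like`), never on which classes happen to be populated. Row
sums equal each sample's record count — classes partition records by
construction.

## Signature extraction

With `M` the samples × classes count matrix, the model is `t(M) ≈ S·E`
with column-stochastic signatures `S` and non-negative exposures `E`.
Per candidate rank `k`, `n_iter` restarts each draw an independent
Poisson resample of the counts and a random non-negative initialization,
then run Frobenius multiplicative updates (cap 400 iterations,
relative-change tolerance 1e-6 checked every 10 — the factorizations
here are small and converge far earlier). The pooled `k·n_iter`
L1-normalized signature vectors are partitioned by k-medoids under
cosine distance, and *stability* is the mean silhouette width, with
singleton or geometrically identical clusters scoring 1. Consensus
signatures are L1-normalized cluster means; exposures come from
non-negative least squares of the original (un-resampled) matrix;
`reconstruction_error` is the relative Frobenius error of that consensus
fit. The selected rank maximizes stability with ties to the smaller k,
and the full per-k table is always returned so the user can override.

The resampling scheme, clustering metric and selection rule are the
package's own choices of the standard stability-NMF recipe; nothing in
them is fitted to data. Two practical notes from the simulations: the
restart count is the lever that separates genuine stability from
chance-consistent restarts (with few restarts an under-factorized rank
can look deceptively stable, because many restarts happen to agree on
the same merged pair of true signatures), so 16 restarts is a sensible
default scale; and mean silhouette saturates near 1 for several ranks on
very clean data, in which case the tie-to-smaller-k rule favours
parsimony. Group association uses the two-sided Mann–Whitney rank-sum
test per signature with Benjamini–Hochberg correction — distribution-free
and adequate for skewed exposures; with one sample per group it degrades
to the exact test rather than erroring.

## Synthetic data and what the tests show

`simulate_caller_vcfs()` mirrors a four-caller benchmark: shared truth
events (mixed DEL/DUP/INV and interchromosomal breakends, sizes 5–30 kb)
are emitted in each caller's dialect with per-caller breakend errors
drawn within ±`jitter`/2, so two callers' renderings of one breakend
differ by at most `jitter` bp — the merge threshold the files are
designed for — while every position stays within `jitter` bp of truth.
Reported confidence intervals have half-width `jitter`, guaranteeing CI
overlap for shared breakends. Distinct events are laid out with gaps
(≥ 20·jitter + 2 kb) that make cross-event links impossible at the
simulated jitter, so the truth clustering is recoverable exactly; each
caller also gets private events (20% of the shared count by default) to
exercise support filtering. `simulate_signature_matrix()` draws
exposures from Gamma(shape 2, mean `exposure_scale` per signature —
about 150 SVs per sample at the default 50, a realistic cancer-genome
load) and Poisson counts around `S·E`, with block-structured
`toy_signatures()` as truth.

These generators emulate coordinate noise, dialect divergence, caller
disagreement and count noise. They do **not** emulate systematic caller
biases (type-dependent sensitivity, shared false positives), realistic
SV size/recurrence distributions, overlapping true events, or reference
artefacts — so passing tests demonstrate correctness of the algorithms
under their stated models, not caller-benchmark performance on real
tumours.

Problem sizes used by the test-suite and the reproduction script: 50
truth events × 4 callers for merge recovery; 100 random instances
(≤ 60 records per caller) for the merge oracle; 1000 random junctions on
a 10 kb toy reference for the microhomology oracle; 100 random
container/BED instances for the annotation oracle; 200 samples × 25
classes, ranks 2–5 × 16 restarts for signature recovery. Each runs in
seconds; sizes were chosen as the smallest at which the properties are
exercised convincingly.

## Degenerate inputs and numerical choices

Empty containers round-trip as header-only files and classify to
all-zero rows. Unknown chromosomes in region filters yield empty results
with a message (a region query on an absent contig is a legitimate
no-hit, not an error), whereas unknown INFO keys, samples, callers and
malformed ALTs are errors naming the offender. Zero-valued merge
thresholds and all-degenerate CIs reduce both merge modes to
exact-duplicate matching. NMF updates add 1e-10 to denominators to avoid
0/0; signature columns that collapse to zero are left as zero rather
than renormalized. `lsqnonneg` solves each sample independently, so
exposure estimation is embarrassingly parallel in principle but is left
serial — the matrices are small.

## Known limitations

Long-read caller dialects (Sniffles, cuteSV), chromothripsis/chromoplexy
event grouping, fusion/frameshift consequence annotation, genotype
reconciliation across callers and reciprocal-overlap merging are out of
scope. The `pcawg_like` scheme is a faithful 25-class reconstruction on
the published axes, not a copy of any specific supplementary class list.
The CLI intentionally exposes only the simple classification; advanced
class definitions are a library-level feature.
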