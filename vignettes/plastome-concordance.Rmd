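---
title: "Measuring concordance between plastome assemblies"
author: "plastomeConcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring concordance between plastome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomeConcord)
```

## The problem

When the same chloroplast genome is assembled several times — from
Illumina or Nanopore reads, *de novo* or by mapping reads to a related
reference — the resulting consensus sequences differ in ways that matter
for downstream phylogenetics: long-read consensuses carry
deletion-dominated errors concentrated in homopolymer runs, and
mapping-based consensuses inherit biases from their reference.
`plastomeConcord` quantifies these differences at basepair resolution and
classifies them, so that the cost of a cheaper sequencing strategy can be
stated as numbers rather than impressions.

## The quadripartite model

A plastome record couples a DNA sequence with a region map: LSC, IRb, SSC
and IRa partition the sequence contiguously, IRb and IRa have equal length,
and the IRb subsequence equals the reverse complement of the IRa
subsequence.  These invariants are enforced by S4 validity, so an object
that exists is structurally sound.  All internal coordinates are 1-based
closed intervals (`IRanges`); the 0-based half-open convention appears only
at BED boundaries, where `rtracklayer` performs the conversion.

Because IRa is an exact mirror of IRb it contributes no independent
information, and *all comparisons are computed on the IRa-stripped
sequence* (`stripIRa()`, `LSC + IRb + SSC`).  This also avoids the aligner
having to disambiguate two identical 24 kb repeats.

`detectInvertedRepeat()` finds the longest maximal pair of exact
reverse-complement repeats by matching k-mers of the sequence against its
reverse complement and merging co-diagonal hits into maximal runs.  Exact
matching is deliberate: the repeat copies of a finished plastome are exact
mirrors by construction, and an assembly whose polished IR copies have
drifted apart should raise an error rather than be silently segmented (the
tolerance such inputs would need is not derivable from first principles,
so guessing is worse than failing).  Hyper-repetitive k-mers (occurring
more than 10 times) are skipped, so low-complexity periodic sequences may
legitimately report "no IR"; real plastomes are far from this regime.  The
sequence must be in the canonical rotation (IRa ending at the terminus,
the longer single-copy segment first); rotated genomes raise an error,
and circular-permutation normalization is out of scope.

Both SSC orientations coexist within individual plants, so
`normalizeSscOrientation()` flips a record's SSC when the edit distance to
the reference SSC is smaller for the reverse complement.  Ties leave the
record unchanged, which makes the operation idempotent.

## Alignment and the mismatch taxonomy

`alignPair()` is an anchor-and-fill global aligner: unique k-mers (default
`k = 21`) shared by both sequences are chained collinearly with a longest
increasing subsequence, merged into maximal exact blocks, and the gaps
between blocks are closed with affine-gap global dynamic programming
(match 1, mismatch −2, gap open 4, gap extend 1; a gap of length L costs
`4 + L`).  Segments whose optimal layout is provable without dynamic
programming — identical segments, few substitutions at equal length, a
single clean indel — are resolved directly; the substitution-only shortcut
applies while the total substitution penalty is below the cheapest gapped
layout, so it cannot change the optimum.  The aligner is deterministic for
fixed inputs and parameters.  Inputs with no collinear anchor chain (for
example a reverse-complemented SSC) fall back to full dynamic programming
when small enough and otherwise raise an "unalignable without
rearrangement" error that points at SSC normalization.  The scoring
parameters and `k` are exposed via `alignParams()`; externally computed
alignments can be supplied as 2-record aligned FASTA and bypass the
aligner entirely.

`adjustToReference()` then fixes the reference frame: terminal columns
where the reference is gapped (query sequence beyond the reference ends)
are deleted, and terminal columns where the query is gapped (reference
positions with no query coverage) become `N` in the query.  After
adjustment the alignment length equals the reference length plus the
internal insertion columns — the denominator convention of the identity
metric.

`classifyAlignment()` scans columns: a differing query base is a
substitution, a query gap under a reference base a deleted base, a
reference gap over a query base an inserted base, and a query `N` over a
reference base an `N` position.  Events are maximal runs of consecutive
deletion (insertion) columns.  Two conventions deserve emphasis, because
only they reproduce published identity columns from published counts:

* `N` positions are *not* mismatches (a base the assembly failed to cover
  is a different defect from a wrong base), but they *do* count against
  identity;
* the identity denominator is the reference length plus inserted bases.

Adjacent deletion and insertion runs are separate events, and
substitutions never merge into indel events; whether historical scripts
merged mixed runs is not decidable, so the self-consistent rule is
documented and tested.  Percentages are rounded half away from zero (two
decimals for identities, one for shares), matching how such tables are
conventionally printed; base R `round()` would round halves to even.

## Homopolymer attribution

`findHomopolymerRuns()` reports maximal single-base runs of at least 5 bp
(configurable; `N` never forms a run).  A deletion event is attributed to
homopolymer context if its deleted reference interval overlaps a run, *or*
if all deleted bases equal the base of an immediately adjacent run: an
aligner may place a one-base deletion from `AAAAA` at either edge of the
run, and a pure-overlap rule would systematically under-count edge
placements.  Insertions are attributed only when all inserted bases are
identical and match an overlapping or adjacent run; mixed-base insertions
are never attributed, a conservative choice that cannot inflate the
in-homopolymer fraction.

## Variant densities and markers

Variant tables are one position per record/event — not per base — matching
how variant callers emit indels.  Windows tile the reference from position
1 without overlap; the final partial window is kept (discarding it would
silently blind the scan to the last sub-window of the genome).  Windows
with strictly more than eight variants per kilobase are flagged, and
marker intervals (typically genes or intergenic spacers from an annotation
BED) are summarized as `variability% = 100 * variants / length`, with
hotspots bounded by the first and last variant inside a caller-supplied
sub-window.

## The simulator and what it does (not) show

The generator's defaults are the study conditions this package is built
around: a 150,191 bp genome (LSC 82,675 / IR 24,558 / SSC 18,400) at
37.45% G+C with independent bases; inter-species divergence of 0.83%
mismatched bases per reference bp composed of 28.8% substitutions, 37.7%
deleted and 33.5% inserted bases; and a consensus error process of
2.88e-3 mismatched bases per bp composed of 18.5/69.9/11.6%
substituted/deleted/inserted bases.  Divergence is applied to LSC, IRb and
SSC and mirrored into IRa, since plastome IRs evolve in concert through
biased gene conversion; truth tables are therefore reported in
IRa-stripped coordinates.

Indel lengths are truncated-geometric on 1–5 bp with mean 1.3, chosen to
match the aggregate deleted-bases-per-event ratio (~1.1–1.2) observed in
real comparisons.  Event counts are planted deterministically at their
expected values (composition noise then comes only from indel lengths and
alignment placement), and anchors keep a minimum spacing of
`2 * maxIndelLen + 2` so planted events never merge — which is what makes
exact truth-versus-recovery tests possible.

Deletion errors concentrate in homopolymers through a per-position weight
`hpBias^(runLength − 1)`.  The expected share of deletion anchors inside
runs of >= 5 bp implied by this weight field is computed on the actual
input sequence, and that share of anchors is planted inside distinct runs
(the rest outside).  Planting by share rather than by naive weighted
sampling is necessary because event spacing lets a run host at most one
anchor, which would otherwise systematically under-fill the runs; the
weight-field expectation is preserved exactly, including the `hpBias = 1`
null, under which the in-run fraction collapses to the genomic share of
homopolymer bases.  When `hpBias` is left `NA` it is calibrated by
root-finding so the expected in-run deletion-event share equals 0.80, the
regime reported for real long-read consensuses.

The amplicon panel emulates a 16-fragment long-range-PCR tiling with
fragment lengths in 6,086–12,499 bp, consecutive overlaps of at least
173 bp, and one declared sequence gap (default 100 bp — the gap's true
size is not published, only that a ~480 bp Sanger fragment closed it)
between fragments 14 and 15.  Reads are 500–3,000 bp sub-fragments
(mean ~3 kb matches the emulated run) with per-base error rates
sub/del/ins = 0.025/0.04/0.015 — deletion-dominated, ~8% total, a
realistic raw long-read regime.  A configurable fraction are palindromic
chimeras `prefix + revcomp(prefix)` with independent errors on each arm.
Read depth per amplicon is uniform; published per-fragment coverage is
graphical only, so unequal depth multipliers are left to the user.

`splitPalindromicRead()` detects chimeras by self-reverse-complement k-mer
voting: each k-mer of the read matching a k-mer of its reverse complement
votes for a mirror pivot, and a true palindrome concentrates votes (>= 3,
±2 bp jitter allowed for indels) on one pivot, which is then verified by
the normalized edit distance between arm 1 and the reverse complement of
arm 2 (<= 0.25 by default, arms >= 200 bp, fragments < 50 bp discarded).
Voting makes the per-read cost near-linear, and the verification step
keeps false splits on non-palindromic reads at the chance level of
spurious k-mer self-matches, which is negligible at `k = 15`.

What the simulator does *not* emulate: base-caller signal artifacts,
quality-score distributions (FASTQ qualities are a constant Q12, the modal
quality of the emulated run), adapter/barcode sequence, context-dependent
substitution spectra, and coverage unevenness.  Passing recovery tests
therefore demonstrates that the *analysis* stages are correct and
internally consistent under realistic error structure — not that any
particular real dataset will show these exact numbers.

## Numerical choices and degenerate inputs

* Rounding: half away from zero everywhere a percentage is reported.
* `gcFraction()` excludes `N` from numerator and denominator (GC of called
  bases); empty or all-`N` input returns `NA`.
* `identityPercent()` of an empty alignment is `NA`; homopolymer fractions
  with zero events are `NaN`.
* Ambiguous IR detection (two equal-length non-nested candidates) is an
  error listing the candidates, not a silent choice.
* Zero-rate simulations return their input unchanged with empty truth.
* Every stochastic operation takes a mandatory seed, restores the caller's
  RNG state, and is byte-reproducible; test problem sizes (10–150 kb
  genomes, 300–1,000 reads) were chosen so the whole suite validates every
  stage, including full study-scale runs, in about a minute.

## Known limitations

* The aligner assumes collinear genomes; inversions other than the SSC
  flip are out of scope, as is multiple alignment.
* IR detection requires exact repeat copies and canonical rotation.
* Identity reconstruction from published counts can disagree with a
  published identity in the last digit when unpublished `N` counts enter
  the denominator; one such case (a close-relative comparison printed as
  99.17% where the printed counts alone yield 99.18%) is known and left
  unresolved, since the missing `N` count cannot be recovered.
* `loadVariantsFromVcf()` reads CHROM/POS/FILTER only; genotype-level
  semantics (ploidy, allele depth) are intentionally ignored.
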