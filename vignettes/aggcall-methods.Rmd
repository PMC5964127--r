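---
title: "Methods: FMR1 repeat-structure calling and AGG-informed risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FMR1 repeat-structure calling and AGG-informed risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggcall)
```

This vignette documents the models and numerical choices behind
`aggcall`: how a repeat structure is represented, how a read is
decomposed and quality-gated, how a female's two X-linked alleles are
phased, how expansion risk is looked up, what the simulator does and
does not emulate, and where the method's limits are.

## The repeat-structure model

An allele's CGG tract is modeled as an ordered list of *triplet
blocks*: maximal runs of one 3-mer motif with a copy count, written
`(CGG)9(AGG)1(CGG)12`. Derived quantities are the total triplet count
(the diagnostic "repeat length" — interruptions included), the AGG
count, the 1-based tract positions of AGG blocks, and any
non-canonical interruptions (motifs that are neither CGG nor AGG, such
as the CTG and TGG interruptions occasionally observed at this locus).
The grammar is bit-exact: `BLOCK := "(" MOTIF ")" COUNT`, uppercase
motifs, counts ≥ 1, no whitespace. The parser additionally tolerates
two typeset renderings seen in print — underscores around counts
(`(CGG)_9_`) and a bare motif token meaning one copy (`CTG`) — but
canonical output always uses the plain form, so
`parse(format(x)) == x` holds block-for-block.

Classification is a pure function of total repeat length using the
standard diagnostic boundaries: < 45 normal, 45–54 intermediate,
55–200 premutation, > 200 full mutation. Display bins used in cohort
tables (e.g. "40–44") never influence classification.

## Read decomposition and QC

Consensus-level single-molecule reads are highly accurate but not
error-free, so decomposition is deliberately conservative:

1. **Anchor search.** The tract is the substring strictly between the
   best match of a 5′ flank anchor and the first 3′ anchor match
   downstream of it. Matching is an ungapped Hamming scan
   (`max_anchor_mismatches`, default 2, per anchor) on the forward
   read, then on its reverse complement. Ungapped scanning is
   deterministic, fast, and adequate at consensus accuracy; a read
   where either anchor is absent on both strands is a `no_anchor`
   call, not an error. Anchors must be ≥ 12 nt and must not contain a
   CGG-triplet run, so they cannot match inside the tract. The shipped
   flank pair is a documented synthetic placeholder — real assays
   supply their primer-defined flanks via the config file.
2. **Frame recovery.** A residual indel upstream of the tract shifts
   the triplet frame, so offsets 0/1/2 are scored by the fraction of
   complete triplets belonging to the known motif set and the best
   offset wins (ties toward 0, then 1). The known set is
   {CGG, AGG} plus the configured `known_interruptions`
   (default CTG and TGG), so a genuine rare interruption does not
   depress the correct frame's score.
3. **Decomposition.** Complete triplets are read from the chosen
   offset; maximal runs become blocks; 1–2 leftover bases at either
   end are trimmed and logged, never emitted as blocks.
4. **QC gate.** A read passes only if anchors were found, the tract is
   ≥ 3 nt, leftovers do not remain at *both* ends (that pattern is
   diagnostic of an internal indel and forces `frameshifted`), and the
   canonical fraction reaches `min_canonical_fraction` (default 0.9).
   There is no frame repair or realignment inside the tract: a read
   broken by an indel is excluded, which keeps every reported
   structure attributable to a literal read-out of intact reads — the
   auditable choice in a diagnostic context. The 0.9 default rejects
   mid-tract frameshifts (which corrupt roughly half the triplets)
   while tolerating a couple of substituted triplets in long tracts.

## Phasing two alleles

Pass reads of one female are split on repeat length: lengths are
sorted and cut at the largest inter-read gap, and two clusters are
accepted only when the gap is at least `min_length_separation`
(default 2 triplets) *and* each side has at least
`min_reads_per_allele` reads (default 10). A largest-gap split — not
k-means or EM — matches the strongly bimodal length signal of a
two-allele amplicon and is deterministic and parameter-light. Alleles
differing by a single triplet are not separable from residual indel
error at this coverage, hence the 2-triplet floor. If only one length
cluster results, a second pass looks for two distinct block patterns
at the same length, each with `min_reads_per_allele` support
(equal-length alleles that differ only in AGG layout), and splits on
structure. The per-allele consensus is the modal exact block list;
ties break toward the candidate closest to the cluster's median
length, then the lexicographically smallest notation, making the
result invariant under read permutation. A single surviving cluster
is reported as `single_cluster_possible_homozygote`: true homozygosity
and allelic dropout cannot be distinguished from the read set alone,
so the tool flags and the clinician decides.

`min_reads_per_allele = 10` reflects the modal-consensus logic: with
the default error model roughly half of a long allele's pass reads
carry a structure-altering substitution, so well under ~10 reads the
mode is weakly supported. Both thresholds are exposed in the pipeline
config and surfaced in the report for auditability.

## The expansion-risk model

Risk lookup is anchor-based and never interpolated. The table maps
(length bin, AGG count) to the published percent risk that a maternal
allele expands to a full mutation in one transmission; the shipped
default contains the eight most-used counseling anchors (2.6% for
AGG-free alleles under 60 repeats up to 100% at 95–100 repeats without
AGGs; 0.5%–60% for 2-AGG alleles of 69–89 repeats, with the 80–84 bin
stored as 30 and flagged approximate). Single published lengths are
stored as single-length bins; ranges only where the literature speaks
in ranges. Load-time validation enforces: risks in [0, 100],
non-overlapping bins per AGG count, risk non-decreasing with length at
fixed AGG count, and non-increasing in AGG count at overlapping
lengths — a malformed table is rejected with the offending entries
named.

Queries are restricted to intermediate and premutation alleles
(others are `not_applicable`). A cell with no anchor returns
`not_available` plus the nearest lower/upper anchors at the same AGG
count: in a counseling context an invented interpolation is worse
than an honest gap with published bounds. Categories (`high` ≥ 20%,
`low` < 5%, else `moderate`, both configurable) mirror how these
values are communicated. Maternal age is deliberately not an input —
its effect on expansion risk is unresolved in the literature.
Prioritization between two eligible alleles compares available risks;
when either is un-anchored it falls back to (fewer repeats, then more
AGGs), the direction the table's monotonicity invariants guarantee.

## What the simulator emulates

`simulate_sample()` builds each read as
`barcode + flank5 + expanded tract + flank3`, applies iid per-base
substitutions, insertions and deletions (defaults 0.2% each,
reflecting consensus-level residual error; configurable up to 20%),
optionally biases the longer allele's coverage
(`allelic_bias`), and emits each read on a random strand. A mandatory
seed makes output byte-identical across runs, and the truth manifest
records every read's source allele and injected error counts (tested
against the binomial expectation). `random_structure()` draws
structures with the conventional 5′ placement of AGGs after units of
9–10 CGGs.

Not emulated: context-dependent (homopolymer) error weighting,
PCR-cycle errors and chimeras, the raw-polymerase-pass to consensus
step, and length-dependent dropout of very large alleles. Passing
tests on simulated data therefore demonstrate the algorithmic
pipeline — anchoring, frame recovery, phasing, consensus, risk
lookup — under a clean iid error model, not instrument-specific
behaviour on clinical libraries.

## Problem sizes and numerical choices

The test suite exercises: grammar round-trips on 1,000 random
structures; expand/decompose identity on 500 random canonical
structures (lengths 10–120, 0–3 AGGs); single-base deletion injection
at every tract position of a 69-repeat read; error-free end-to-end
recovery of all ten worked-example genotypes at 30× per allele; and a
stochastic recovery study of 200 simulated females (lengths uniform
20–100, 0–3 AGGs, default error model, 30× per allele, fixed seeds).
All randomness is seeded; all tie-breaks (frame offsets, consensus,
equal-length cluster order) are deterministic, so every result is
reproducible to the byte.

## Known limitations

- **Pass-read depletion on long alleles.** Under the iid indel model
  the chance that a read of an *L*-repeat allele carries no
  frame-breaking indel falls roughly as `0.996^(3L)`; combined with
  the exclude-don't-repair QC policy, a 30× library leaves a
  long-premutation allele with ~8–12 pass reads, at the edge of the
  10-read floor. In the 200-female stochastic study this is the main
  reason a sample fails exact recovery: the affected allele is flagged
  (insufficient coverage or single-cluster) rather than called. For
  alleles above ~75 repeats, 60× per allele is the practical
  recommendation.
- **Near-equal allele lengths.** Pairs differing by ≤ 1 triplet are
  not separable by design; pairs differing by exactly 2 can merge when
  near-end-indel reads at ±1 triplet bridge the length gap.
- **Full mutations.** Alleles > 200 repeats are classified but the
  assay-level phenomena that make them hard to amplify and sequence
  are out of scope, as is methylation status.
- **Risk coverage.** The default table holds only the printed
  counseling anchors; cells such as (72, 2 AGG) are `not_available`
  with bounds until an operator loads a fuller published table.
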