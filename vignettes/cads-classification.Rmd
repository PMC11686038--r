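---
title: "Classifying chromatin accessibility dynamics across reprogramming systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying chromatin accessibility dynamics across reprogramming systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Somatic-cell reprogramming reshapes the chromatin landscape of a fibroblast
(MEF) toward the embryonic stem cell (ESC) state. Given ATAC-seq peak sets
collected at an ordered series of stages — here MEF, day 0, 4, 7, 10 of
induction, and ESC — for several reprogramming *systems* (a DsRed control
and factor-overexpression conditions: SALL4 alone, OCT4 alone, and the
SALL4+OCT4 combination), the questions are:

* which genomic regions open, close, or stay open over the course, and
  *when* the transition becomes permanent;
* which of those transitions are shared between systems and which are
  specific to one, in particular which are unique to the two-factor
  combination (synergy);
* which transitions carry direct factor binding (CUT&Tag peaks) and which
  are indirect;
* how the factors' co-occupancy *predicted* from single-factor experiments
  compares with their *actual* co-occupancy when co-expressed;
* which genes change expression in which systems, and how those changes
  relate to the MEF-to-ESC endpoint difference.

`cadsr` implements these classifications over standard inputs (BED/narrowPeak
peak files, a gene model, a count matrix), and ships a synthetic-data
generator with planted ground truth so every classifier can be tested for
recovery.

# The trajectory model

All peaks from every sample of every system are merged into one
**integrated background** (union of intervals; bookended intervals merge).
Each background region is then called *open* in sample (system, stage) when
it shares at least `min_bp = 1` base with a peak of that sample. A region's
occupancy pattern in one system is a Boolean vector over the stage axis,
and is mapped to a trajectory class by a total rule. With start state
`s` (MEF) and end state `e` (ESC):

| pattern | class |
|---|---|
| closed at MEF, open at ESC | `CO_k`, where stage *k*+1 is the earliest stage from which the region stays open through ESC |
| open at MEF, closed at ESC | `OC_k`, symmetric (earliest stage from which permanently closed) |
| open at both ends, open everywhere | `PO` (permanently open) |
| open at both ends, closed somewhere | `PO_UNSTABLE` |
| closed at both ends, open somewhere | `TRANSIENT` |
| never open | `NEVER_OPEN` |

`CO1` is therefore "closed in MEF, permanently open from day 0 onwards",
and `CO5`/`OC5` change state only at the ESC reference — transitions that
failed to happen during the course. The three residual classes exist
because a shared background guarantees patterns the named groups do not
cover (e.g. any region contributed only by *another* system's peaks is
`NEVER_OPEN` in this one); they are reported but excluded from CO/OC/PO
summaries.

**Earliest-permanent vs strict monotonicity.** For non-monotone patterns
(e.g. open at D0, closed at D4, open from D7 on) the subgroup index is
defined by the *earliest permanent* transition (`CO3` in the example): this
reproduces the stated definition of `CO1` exactly, is total, and reads
naturally as "the stage from which the new state holds". A
`strict_monotone` mode is available (`classify_patterns(mode =)` and the
pipeline config) that reserves `CO_k`/`OC_k` for single-transition patterns
and sends other changed patterns to `TRANSIENT`. The truth-table test
enumerates all 64 six-stage patterns: 16 map to CO classes (sizes 1, 1, 2,
4, 8 for CO1..CO5), 16 to OC, one to `PO`, one to `NEVER_OPEN`, and
flipping every bit of a pattern exchanges `CO_k` with `OC_k`.

# Cross-system comparisons

Because every system is classified on the same background, comparisons are
region-level set algebra. `compare_systems()` computes common/specific
region sets for a class scope; the figure-style Venn uses the scopes CO1-4,
OC1-4 and PO — the subgroups that complete their transition during the
course (CO5/OC5 are excluded as failed transitions). `synergy_patterns()`
partitions the combined system's transitions by which single-factor system
shares them: for the open direction, common-with-SALL4 (`O+S/S4-C-O`),
common-with-OCT4 (`O+S/O4-C-O`), O+S-only (`O+S-S-O`), and an all-three
residual; symmetrically for close. Within a direction the four sets are
disjoint and their union is exactly the combined system's scope set — an
identity asserted in tests over randomized assignments.

`subtract_control()` implements the day-matched control subtraction used
before motif analysis: whole-peak exclusion of system peaks overlapping
same-day control peaks by at least `min_bp` (read-level peak calling
against a control library is out of scope here).

# Binding integration

`classify_effects()` crosses each region's trajectory class with day-0
binding evidence for a factor: regions that close are `direct_close` when
bound, `indirect_close` when not; regions that open are
`direct_open`/`indirect_open`; everything else is
`bound_static`/`unbound_static`. The six classes partition the background,
and direct+indirect counts per direction cross-foot to the CO/OC totals.
Day-0 binding is the default anchor because the direct/indirect definition
is stated at the start of induction; passing the union of stages gives a
bound-at-any-stage variant.

Predicted co-binding of two factors is the merged set of pairwise overlaps
between their peak sets measured in *separate* single-factor systems;
actual co-binding applies the same operator to the two factors' peaks
within the combined system. Counting merged overlap regions (rather than
raw peaks of either factor) makes the counts symmetric in the two factors
and makes the bookkeeping identities exact: with predicted (C3), actual
(C4), lost (C5 = predicted regions with no actual overlap) and gained
(C6 = actual regions with no predicted overlap),
`|C4| = |C3 overlapping C4| + |C6|` holds by construction.
`promoter_fraction()` reports the fraction of a region set's midpoints
within 1 kb of a TSS, the statistic used to compare lost/gained sets.

# Peak-to-gene annotation

`annotate_to_genes()` assigns each peak, by its midpoint, to the nearest
TSS (signed, strand-aware distance; ties broken to the lexicographically
smaller gene id) and to exactly one category with precedence promoter bins
(≤1 kb, 1-2 kb, 2-3 kb, mirroring the 3 kb TSS focus) > exon > intron >
downstream (≤3 kb past the strand-aware gene end) > distal intergenic.
Peaks on chromosomes absent from the model are distal with no gene.

# Expression classification

Counts are normalised by median-of-ratios size factors (the standard
geometric-mean reference), implemented in-package so the pipeline is
self-contained; a reader for external DE tables (`gene`, `log2FC`, `padj`)
accepts the output of any standard engine instead.

The built-in caller tests each (system, stage) against the control system
at the same stage on `log2(normalized + 1)`. The default method fits a
two-group linear model per gene and applies empirical-Bayes variance
moderation with a mean-variance trend (via limma). This choice was made
after measuring the alternative: a plain per-gene Welch t-test at the
generator's study conditions (4-fold effects, NB dispersion 0.05, three
replicates, BH across 2,000 genes) detects under 20% of planted effects
per stage, because 4-df variance estimates are too unstable to survive
multiple-testing correction; moderation is the standard remedy at this
replicate number and restores per-stage power to ~1 without touching the
thresholds. The plain Welch test remains available as `method = "welch"`.
Calls require `|log2FC| >= 1` (2-fold) *and* BH-adjusted `p <= 0.05`; both
thresholds are config-exposed (the fold-change-2 convention follows the
endpoint-bin definition; the testing thresholds are package defaults).
Genes under 10 average normalised counts are not tested. Single-replicate
groups fall back to fold-change-only calls.

Per system, up/down calls are unioned over stages and the
**both-direction exclusion rule** removes genes called up at one stage and
down at another within the same system. Across systems, each gene carrying
a direction is mapped to the exact subset of systems carrying it; genes
with conflicting directions between systems are dropped entirely (the
"common/specific up" definitions require the other systems to show no
change or the same direction, leaving conflicts undefined).

The endpoint ratio `(ESC + 1)/(MEF + 1)` over normalised means bins each
gene as `high` (≥ 2), `low` (≤ 0.5) or `mid`; boundary values belong to
the outer bins, and the pseudocount guards zero-expression references.
Cluster labels enumerate combinations × bins in a fixed documented order —
all-three, S4/O+S, O4/O+S, S4/O4, O+S, S4, O4; bins high, mid, low — so
`UC1` is all-three-up with high endpoint ratio and `UC21` is OCT4-specific
up with low ratio (`DC*` symmetric for down; the label order beyond the
first three is a package convention, since only the bin rule is defined by
the legends). A single-system mode (one system vs control) emits `C1-C3`
(up × bins) and `C4-C6` (down × bins). Within a cluster, genes are grouped
by the stage of their expression peak (minimum for down-clusters) in axis
order, ties broken by gene id.

# The synthetic generator

`make_fixture()` builds a fully self-contained study on a three-chromosome
genome: a CADs chromosome carrying 100 disjoint regions per named class
(PO, CO1-5, OC1-5) per system — 4,400 regions, each emitting a peak in
sample (system, stage) exactly when its class's canonical pattern is open
there; a binding chromosome carrying the planted co-binding structure
(40 lost / 60 common / 100 gained regions, preserving the lost < common <
gained ordering of the real comparison at desk scale, plus single-factor
decoys); and a gene chromosome with 2,000 non-overlapping genes, 10 planted
per (direction × combination × bin) cluster. Counts are negative binomial
with gene-constant dispersion 0.05, three replicates per sample, library
factors uniform on [0.7, 1.3], 4-fold planted effects in every induction
stage of the planted systems, and endpoint means realising ratios 4, 1 and
1/4 for the high/mid/low bins. Direct binding marks a Bernoulli(0.5)
subset of each system's CO/OC regions with an exact day-0 peak; because
both factors bind the combined system's regions independently, regions
bound by both are genuine actual co-binding and the truth tables record
them. Noise is controlled by `jitter_sd` (Gaussian boundary jitter) and
`dropout` (probability an open call is omitted); the noiseless default
makes background regions correspond 1:1 to planted regions, so recovery
must be exact.

All randomness flows from one master seed through per-component sub-seeds
drawn once, so the genome, peaks, binding and counts are each
independently reproducible, and `write_fixture()` output is byte-identical
across runs.

**What the generator does and does not emulate.** It reproduces the
*structure* the classifiers consume — presence/absence peak patterns,
overlap topology, NB counts with planted effects — not read-level reality:
no fragment-size or Tn5 bias, no peak-width or signal-strength
distributions, no correlated replicate structure, no gene-length effects,
and per-system MEF/ESC reference peak files rather than one shared
reference sample. Passing recovery tests therefore demonstrates
correctness of the classification logic under controlled noise, not
end-to-end performance on real sequencing data.

# Numerical and design choices

* Coordinates are BED-style 0-based half-open in files, 1-based closed
  (IRanges) in memory; conversion happens only at I/O boundaries. Abutting
  peaks share no base and do not overlap; they do merge at gap 0.
* Overlap threshold `min_bp = 1` everywhere by default.
* Degenerate inputs: empty peak files parse to empty sets; an all-empty
  background is an error; a sample with all-zero counts is an error;
  all-`ns` DE tables yield empty direction sets and clusters.
* Report files contain no timestamps so that re-runs are byte-identical;
  timing goes to the message log.
* Problem sizes in the test suite: brute-force oracle comparisons use
  1,000-interval random sets over 20 seeds; identity checks use 500
  randomized trials per family; the planted-recovery and determinism
  checks run on the full default fixture (4,400 regions, 2,000 genes, 54
  samples). These sizes exercise every code path at comfortable desk
  scale.

# Limitations

* Occupancy is binary peak overlap; signal-level (read count) occupancy
  calling is out of scope, as are peak calling, motif and GO enrichment,
  and alignment — peak files are consumed as given.
* The built-in DE caller is a normal-theory test on log counts, not a
  count-model fit; for publication-grade DE, supply external engine output
  via `read_external_de()`.
* Real genomic counts (tens of thousands of regions) derive from deposited
  sequencing data; the package reproduces the *procedures* and verifies
  them on planted truth, not the published numbers.
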