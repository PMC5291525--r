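---
title: "Methods: the Z-curve correlation coefficient and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Z-curve correlation coefficient and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zccurve)
```

## The model

A bacterial chromosome replicated bidirectionally from a single origin has
two replichores. Asymmetric mutational pressure (notably cytosine
deamination on the leading strand) and selection (codon preferences, gene
orientation) leave the leading and lagging strands with different base
compositions. The Z-curve decomposition turns a sequence into three
cumulative integer walks — purine−pyrimidine ($x_n$), amino−keto ($y_n$) and
weak−strong hydrogen bonding ($z_n$) — from which two disparity tracks
follow exactly:

$$a_n = \tfrac{x_n + y_n}{2} = A_n - T_n, \qquad
  b_n = \tfrac{x_n - y_n}{2} = G_n - C_n .$$

Both tracks switch slope at the replication origin and terminus. The ZCC
index is the Pearson correlation $r(a, b)$ over $n = 1,\dots,N$: a single
windowless number summarizing whether AT and GC biases move together
(positive; A and G jointly enriched on the leading strand — purine
asymmetry) or oppositely (negative; the common G+T-rich leading strand).
Because the tracks are cumulative, no window size is chosen and no
smoothing is applied; the index uses every position of the genome once.

The RY–MK index is the same correlation computed on $x$ and $y$ directly.

## Conventions and edge cases

* **Summation range.** The correlation runs over the $N$ sequence positions
  $n = 1..N$; the origin point $n = 0$ (where all tracks are zero by
  construction) is not a sequence position and is excluded. At genome scale
  its inclusion changes $r$ by a negligible amount; the choice is fixed so
  small worked examples are exact.
* **Ambiguity codes.** IUPAC ambiguity codes are accepted and advance the
  position index without touching any of the four base counters. This
  preserves positional alignment with annotations; it treats an ambiguous
  run as locally bias-free, which slightly attenuates the index on heavily
  gapped assemblies. `U` is rejected: the toolkit is DNA-only.
* **Degenerate tracks.** A track with zero variance (e.g. a homopolymer)
  has no defined correlation. Degeneracy is detected exactly (constancy),
  and the result is a flagged undefined value rather than a silent 0, so
  cohort summaries can skip such records; a strict mode raises instead.
* **Numerics.** All curves are integer arrays, so the defining identities
  hold exactly. Pearson $r$ is computed from centered sums accumulated with
  R's long-double `sum()`, then clamped to $[-1, 1]$; agreement with a
  naive per-base reference is asserted to $10^{-12}$ in the test suite.
  Centering before multiplication keeps the products small relative to the
  uncentered moment sums, which is what makes that tolerance attainable at
  genome-scale $N$.

## Origin and terminus from disparity extrema

On the cumulative $G-C$ track the slope is positive along each leading arc,
so, read from the origin, the curve is an inverted V with its peak at the
terminus. Two conventions are possible when pairing extrema with (ori, ter);
this package adopts the geometry-consistent one — **ori at the minimum, ter
at the maximum** of the $G-C$ track — because it is the only pairing
consistent with G-enrichment of the leading strand. The alternative pairing
(maximum → origin) appears in parts of the literature; `estimate_ori_ter()`
documents its convention and the boxed results are insensitive to the label
swap (it exchanges ori and ter).

Before the extremum search on a circular genome the track is detrended by
subtracting the chord from $(0, b_0)$ to $(N, b_N)$. A circular genome
deposited at an arbitrary rotation has a net drift that moves the raw
extrema toward the deposited ends; removing the chord makes the estimator
rotation-equivariant, which the tests assert directly. The confidence score
is the detrended peak-to-trough amplitude per base, clipped to $[0,1]$ — an
estimate of the average skew magnitude, near zero for unskewed sequences.

When a curated oriC interval is supplied, ori is its integer midpoint (ties
broken downward) and ter is either given or taken as the detrended extremum
farthest from ori on the circle.

## Strand assignment and SGD

Genes are assigned by their midpoint: on the half-open arc $[ori, ter)$
(increasing coordinates, wrapping) a forward-strand gene is leading; on
$[ter, ori)$ the rule is mirrored. Midpoint assignment is a deliberate
simplification — a gene spanning ori or ter is attributed to the arc holding
its midpoint — chosen because it is deterministic and exhausts the circle
(every midpoint lies in exactly one arc, asserted by enumeration in the
tests). The SGD fraction is the share of assignable genes on the leading
strand. Internal coordinates are 0-based half-open; every file boundary is
1-based inclusive, converted exactly once in the I/O layer.

## Cohort statistics

Per-phylum summaries report sign counts and percentages over all genomes of
the phylum (degenerate and exactly-zero indexes in their own columns — the
sign dichotomy assumes nonzero values, and an exact zero is possible on toy
inputs), the mean and SD of the defined indexes, and the majority-sign group
label (P-ZCC / N-ZCC; exact ties are left unclassified with a warning).
Phyla with 15 or fewer genomes are dropped by default (`min_n = 15`,
strictly-greater), guarding group labels against small samples.

Boxplot outliers use Tukey fences $Q_1 - 1.5\,\mathrm{IQR}$ and
$Q_3 + 1.5\,\mathrm{IQR}$ with strictly-outside flagging. Quartiles are
interpolated order statistics (`stats::quantile` type 7, the mainstream
default); the convention only moves borderline outliers and is switchable
via `qtype`.

The polymerase cross-tab classifies genomes with PolC as PC regardless of
accompanying DnaE subtypes (DnaE1–DnaE3 and DnaEX are united as DnaE) and
the rest as DE, tabulated per phylum in two variants: all matched genomes,
and with a supplied outlier list removed. Genomes with unknown polymerase
status are excluded, with counts reported, since survey metadata rarely
covers a whole cohort.

## The synthetic generator

`generate_genome()` samples the deposited forward strand independently per
position: from `leading_probs` on the arc where the forward strand leads,
and from the complement-mapped probabilities on the other arc (there the
reverse-complement strand is the leading one, so forward base $b$ appears
with the leading probability of its complement). Defaults are the package's
study conditions: $N = 200$ kb, per-base enrichment $\delta = 0.05$ of A and
G on the leading strand (`regime_probs("purine")`), 200 genes of mean length
900 bp placed on the leading strand with probability 0.78 — magnitudes in
the range observed in strongly strand-biased bacteria, and large enough that
the expected disparity slopes ($p_A - p_T$ and $p_G - p_C$ per base) stand
clear of sampling noise at that length.

The generator is first-order by design: the ZCC statistic depends only on
cumulative single-base counts, so dinucleotide structure, codon structure,
deamination gradients and transcription-coupled repair are deliberately not
modeled. Genes are placed as non-overlapping intervals, not ORFs, because
SGD needs only positions and strands. Consequently, passing tests show that
the estimators recover the parameters of this composition model — they do
not certify behavior under real-genome features such as horizontally
acquired islands, rRNA operon clusters, or multiple replication origins.

## Problem sizes and determinism

The shipped checks use 1,000 random sequences (lengths 2–500) for oracle
equivalence, 500 for the symmetry laws, 20 seeds per regime at 200 kb for
sign recovery, 20 genomes of 500 kb for ori/ter recovery, 1,000 genes for
SGD recovery, and a 2-phylum × 20-genome cohort end to end — sizes at which
every recovered quantity is stable across seeds while the whole suite runs
in well under a minute on one core. Every stochastic step takes an explicit
seed; `generate_cohort()` refuses to run without one and produces
byte-identical files given the same seed.

## Known limitations

* Single-origin circular chromosomes only; linear chromosomes and
  multi-origin replicons are out of scope, as are windowed or local
  correlation profiles (the statistic is deliberately windowless).
* No significance testing of the index is provided; at genome-scale $N$ the
  usual correlation tests are meaningless (autocorrelated cumulative
  tracks), and the index is used descriptively.
* Plasmid handling is by chromosome selection (`longest_only`) rather than
  joint analysis; per-replicon results are otherwise independent.
* Extremum-based ori/ter estimates degrade on genomes with weak or locally
  inverted skew; the confidence score flags, but does not correct, such
  cases.
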