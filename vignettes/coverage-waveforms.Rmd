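---
title: "Coverage waveform motifs at structural-variant breakpoints"
author: "SVWaveform authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage waveform motifs at structural-variant breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SVWaveform)
```

## The problem

Short-read structural-variant (SV) callsets are noisy: breakpoints are
imprecise, and an unknown fraction of calls is wrong. One signal that is
informative about a breakpoint independent of the caller is the per-base
read depth (depth of coverage, DOC) around it: a homozygous deletion drops
coverage towards zero past its left breakpoint, a duplication lifts it
towards twice the baseline, and so on. SVWaveform implements a complete
stack for working with these waveforms on top of per-base coverage and SV
VCFs:

1. a lossless two-byte binary coverage format (**BCOV**) with an index for
   constant-time window slicing;
2. extraction of fixed-width DOC profiles at typed breakpoint loci;
3. DTW K-means clustering of compressed profiles, and a symbolic (SAX)
   motif-discovery pipeline with a reference-point-pruned nearest-neighbour
   search, bootstrap aggregation and motif merging;
4. scanning of new coverage tracks for the discovered motifs;
5. a synthetic-coverage simulator so that every stage is testable without
   sequencing data.

## Windows, loci and profiles

A profile is the depth over a window of `2 * halfWidth` bp centred on a
breakpoint; the default half-width of 256 bp matches the scale of typical
short-read inserts, giving 512-value profiles. Our window convention: the
window at 1-based position `p` with half-width `w` covers `[p - w, p + w - 1]`,
so the breakpoint sits at 0-based offset `w`. Windows are never padded:
a window that would leave the contig is dropped, as is a window whose values
are all zero (in real callsets this zero-drop is what unbalances left/right
profile counts for some classes).

Breakpoint typing follows the SV class: interval SVs at least as long as the
window contribute a left (`L`) and a right (`R`) locus; insertions a single
breakpoint (`BP`); interval SVs shorter than the window but at least
`minSvLen` (20 bp) are "special" (`spSV`) and contribute a single locus.
Records shorter than 20 bp are discarded, as are records whose site filter
is anything but exactly `PASS` (and, when the VCF carries per-sample `FT`,
carriers whose `FT` is not `PASS`). Variant length is `end - start + 1`; at
the 20 bp boundary the record is kept. Three choices here were genuinely
open and are fixed as follows:

* the `spSV` window is anchored at the variant midpoint
  (`floor((start + end) / 2)`), so that the entire sub-window variant lies
  inside the profile rather than only its left edge;
* copy-number gain/loss records never produce `spSV` loci (the taxonomy
  reserves the class for DEL/DUP/INV);
* a profile is dropped only when *all* of its values are zero - partial
  zeros are real signal.

## BCOV

Depth is stored as one little-endian unsigned 16-bit integer per position,
sequentially, with no header; a plain-text sidecar (`.idx`) lists
`(contig, byte offset, n positions)` so a window is two seeks away. The
two-byte cell fixes the representable ceiling at 65535; deeper positions are
clamped by the encoder. Endianness is not dictated by the design - we fix
little-endian so files are portable and document it here. Decoding is the
exact inverse of encoding for in-range values, which the suite asserts by
property testing against randomly drawn tracks.

## From depths to symbols

Profiles destined for clustering or discovery are processed as:

* **pooling** - average pooling in 8 bp windows (512 -> 64 points). This is
  the aggregation step of classic SAX performed explicitly, so the SAX
  transform itself is applied point-per-point afterwards.
* **normalization** - z-scaling to zero mean, unit variance, with the
  population (1/n) standard deviation as in the SAX literature. Sample-level
  moments (mean/sd of the sequencing sample) can be supplied instead, and
  are what the build pipeline uses, since "unit variance within a sample"
  can be read per-profile or per-sample; both are implemented, sample-level
  is the pipeline default. A constant profile normalizes to zeros.
* **SAX** - discretisation into an alphabet of 24 symbols by equiprobable
  standard-normal cells, i.e. breakpoints at quantiles `k/24`. A value lying
  exactly on a cell boundary takes the upper symbol (so constant zero maps
  to symbol 12 under the even default alphabet); the convention is fixed by
  `findInterval` semantics and used identically everywhere.
* **segmentation** - all overlapping 32-symbol windows of the 64-symbol
  word, stride 1 by default (the stride is configurable; 1 is the natural
  reading of "overlapping" segmentation).

The SAX distance (MINDIST) between equal-length words is
`sqrt(n/w) * sqrt(sum(cell(a_i, b_i)^2))` with `cell` zero for identical or
adjacent symbols and otherwise the gap between the inner quantile
breakpoints. It never exceeds the Euclidean distance of the normalized
signals (tested as a property), which is what makes symbolic search sound.

## Clustering

Compressed, normalized profiles are clustered by K-means under dynamic time
warping (DTW): squared pointwise costs, monotone warping paths anchored at
both ends, no warping-window constraint by default (a Sakoe-Chiba band is
available in the configuration). Barycenters are updated by DTW barycenter
averaging; initialisation is k-means++-style seeding on DTW distances with
10 restarts, keeping the lowest-inertia solution, and the objective trace is
checked to be non-increasing on every run. The cluster count is fixed at
two: a silhouette analysis over bootstrap subsamples (80 runs without
replacement by default; the subset size for this experiment is exposed in
the configuration since it is not dictated by the design) selects `k = 2`
on breakpoint-like pools, and the package reproduces that decision on its
synthetic two-family and three-family fixtures.

When the larger cluster holds strictly more than 66% of the profiles, motif
discovery is restricted to it; otherwise both clusters are searched. The
strictly-greater reading matters only exactly at the boundary: a 66/34 split
still searches both.

The compression-consistency experiment quantifies whether the 8 bp pooling
perturbs clustering more than the random seed does: per repeat, a subset of
100 profiles is clustered compressed under two seeds (`C0`, `C1`) and
uncompressed under the first seed (`C2`); agreements (maximised over label
permutations) between `C0`/`C1` and `C0`/`C2` form two distributions that a
one-sided two-sample Kolmogorov-Smirnov test compares. One reading of the
experiment would make the third arm identical to the first (same data, same
seed, same preprocessing) and the comparison vacuous; the uncompressed arm
is the only non-degenerate interpretation and is what we implement.

## Motif discovery

Segments are grouped by a nearest-neighbour search that avoids the
quadratic all-pairs SAX distance computation through linearisation: every
segment is projected onto two 1D axes, its SAX distances `S_i` and `C_i` to
two fixed reference words - the SAX transforms of z-normalized sine and
cosine on `[0, pi/2]` (one non-decreasing, one non-increasing, mirror images
of one another, identical across runs). A pair is a candidate only if it is
close in *both* projections; the SAX distance is evaluated for candidates
alone, and pairs within `eps` are linked. Groups are the single-linkage
components of that graph (single linkage makes the brute-force oracle
well-defined), ranked by size with ties broken by the smaller mean
intra-group distance.

Two numerical points deserve care:

* **Exactness of the pruning.** The SAX distance is not a metric - adjacent
  symbols are at distance zero, so the triangle inequality fails and
  `|S_i - S_j| <= dist(i, j)` does *not* hold in general. A literal
  `|S_i - S_j| <= eps` filter can therefore drop true neighbours (our
  property tests catch it doing so on jittered families). The violation is
  bounded, however: per position it cannot exceed
  `max_{r,c} [ max_s |cell(r,s) - cell(c,s)| - cell(r,c) ]`, a quantity we
  compute exhaustively per alphabet (about 0.349 at alphabet 24). Widening
  the candidate window by `sqrt(n/w) * sqrt(segLen)` times this bound makes
  the pruned search provably identical to the all-pairs grouping, and that
  is the default; the literal filter remains available (`knnExact = FALSE`)
  as the faster approximate variant.
* **Group representative.** A single-linkage group built from sliding
  segments typically chains neighbouring offsets of the same underlying
  waveform. Averaging its members position-wise would blur those shifted
  copies into a ramp no member actually has, so the group representative is
  the *central member* - the member word closest to the group's positional
  mean - and it carries its own origin offset. That offset yields the
  motif's **anchor**: the pooled offset of the breakpoint inside the motif
  word, which is what lets a scan hit report a breakpoint coordinate.

`eps` is not dictated by the design; it is calibrated once per pool as the
5th percentile of pairwise SAX distances over a deterministic sample of
segments, and is exposed in the configuration.

Discovery runs over bootstrap subsets - by default 360 subsets of 960
profiles per (SV class, breakpoint side, genotype) combination, drawn
without replacement within a subset, or with replacement when the pool is
smaller than the subset size (flagged in the log). Each subset contributes
the top-ranked group's representative per searched cluster; candidates are
then merged greedily - while any pair lies within `mergeEps` (default:
`eps`) the closest pair merges, supports add, and the final representative
is the support-weighted per-position rounded mean (round-half-even, rounded
once over the winning family's original candidates) with the same weighting
applied to the anchor. The largest family's representative is the
predominant motif. A motif whose family collected fewer than 10% of the
subsets is reported as "no convincing motif" - insertion breakpoints, whose
waveforms do not repeat, are expected to end up below this floor; the floor
itself is a package choice, exposed in the configuration.

## Scanning

Scanning applies the discovery preprocessing to each tile of a coverage
track (512 bp tiles, stride 8 bp by default), slides the motif over the
tile's SAX word, and reports spans whose MINDIST falls at or below a
threshold, collapsing overlapping same-motif hits to the best-scoring one.
Scores are invariant to uniform scaling of the raw coverage because the
normalization absorbs scale. The default threshold is motif-specific,
calibrated as the 1st percentile of scores on simulated motif-free coverage
at the same depth - the design gives no threshold, so we anchor it to an
interpretable null quantile; stricter thresholds are a flag away. With the
anchor, the best hit converts to a 1-based breakpoint estimate; on synthetic
homozygous deletions this estimate lands within one pooling window (8 bp)
of the true breakpoint, which the acceptance suite asserts.

## The simulator

`simulateSample()` draws per-base depth from Poisson (optionally
negative-binomial, since real coverage is overdispersed) noise around a
rate profile: baseline 30x by default, scaled inside events by copy factors
(deletion 0 hom / 0.5 het, duplication and CNV gain 2 / 1.5, CNV loss like
deletion). Inversions are copy-neutral, so they are given a synthetic
breakpoint "edge artifact": a linear dip to 0.3x over a 50 bp shoulder at
each breakpoint, standing in for the alignment-quality drop real inversions
show; insertions get a narrow 0.5x dip over +/-15 bp. These artifact shapes
are inventions (labelled as such) whose purpose is to give copy-neutral
classes structure that discovery can find, not faithful models of alignment
behaviour.

`plantedMotifDataset()` builds profile pools for recovery experiments: a
32-point template occupies the central 256 bp (each point spans one pooling
window), the flanks continue at the template's edge values - a breakpoint
window does not return to a common baseline on both sides - and Gaussian
noise of sd `sqrt(30)` (the Poisson sd at 30x) is added, with optional
shift/stretch jitter to emulate imprecise breakpoints. Built-in templates
use ramped transitions over 6 points rather than single-base steps, because
real breakpoint waveforms change over a read-length-scale shoulder. The
full-dip deletion template (`DEL_DIP`) is the recovery benchmark: its
anchored comparison is rank-informative along the whole word. A hard
two-level step template would make a poor benchmark *regardless of recovery
quality*: its true SAX word is almost entirely rank ties, so any +/-1
symbol wobble in an otherwise faithful recovery decorrelates the ranks -
a property of the comparison, not of the discovery.

## What the synthetic tests do and do not show

The simulator emulates depth scale, sampling noise, genotype dosage and
breakpoint-local artifacts. It does not emulate GC bias, mappability
structure, alignment soft-clipping, batch effects between samples, or
caller-specific breakpoint error distributions. Passing recovery and
localisation tests therefore demonstrates that the machinery - extraction,
clustering, symbolic search, merging, scanning - is correct and internally
consistent at realistic noise levels, not that motifs learned on one real
cohort transfer to another.

## Problem sizes used by the test-suite

The statistical defaults (360 bootstrap subsets of 960 profiles, 80
consistency repeats of 100 profiles, 10 K-means restarts) describe
full-scale runs. The package's own test and acceptance fixtures run the
identical code at smaller sizes chosen for tight iteration: pools of
30-240 profiles, 12-24 bootstrap subsets of 64-96 profiles, 3 K-means
restarts, subsampling runs of 10x50 for the cluster-count experiment, and
4-6 consistency repeats of 30-40 profiles. All sizes are set through the
configuration object, so scaling up changes no code path.

## Known limitations

* DTW K-means with barycenter averaging converges to local optima; restarts
  mitigate but do not remove seed dependence (the consistency experiment
  measures exactly this).
* The anchor of a motif is a single offset; motifs whose bootstrap families
  straddle several offsets localise correspondingly more coarsely.
* The store is a validated file-backed relational object, adequate for
  cohort-scale extracts; it is not a concurrent database server.
* Insertion profiles carry little recurrent waveform; the pipeline reports
  them honestly as unconvincing rather than inventing a motif.
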