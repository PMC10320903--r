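---
title: "Methods: region-set pileups, embeddings and per-bin enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-set pileups, embeddings and per-bin enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionstack)
```

`regionstack` is a headless analysis core for exploratory epigenomics around
genomic region sets: given a set of loci sharing a property (transcription
start sites, ChIP-seq peaks, domain boundaries, ...), it asks what 1D
coverage tracks and 2D contact maps look like around those loci, which
sub-populations of loci exist, and which other region sets co-locate with
them — all at multiple genomic length scales. This vignette describes the
models and procedures, the tunable parameters, the synthetic data the test
suite runs on, and the numerical choices made where the design was open.

## Region models and resolution stacks

All coordinates are 0-based half-open (`[start, end)`, BED-native), at every
interface.

**Point regions** are analysed around an anchor, defined for a record
`[start, end)` as the floor midpoint `floor((start + end) / 2)`. A
`point_config(windowsize = w, binsize = b)` turns each anchor `c` into the
frame `[c - w, c + w)` split into `2w/b` bins; `b` must divide `2w`, which
is validated. `w` is a *half*-width — the convention of pileup tools, where
"±50 kb" means a 100 kb window. The anchor always falls on the boundary
between the two central bins, so profiles are symmetric around an inter-bin
boundary, not a bin.

**Interval regions** are analysed over their whole extent plus proportional
flanks: a record of length `L` gets bins of width `p * L` starting at
`start - flank * L` (default flank 0.2, i.e. 20% of the interval on either
side), `round((1 + 2 * flank) / p)` bins in total. Because bin width scales
with `L`, intervals of any length produce the same number of bins —
length-normalized profiles, e.g. gene bodies of different sizes aligned
start-to-end. When `(1 + 2 * flank) / p` is not an integer the two published
constraints (span exactly `interval + flanks`; bin width exactly `p * L`)
cannot both hold; `regionstack` keeps the bin width exact and anchors the
first bin at the left flank edge, so the frame span may deviate from the
nominal span by a fraction of one bin. Interval bin edges are real-valued
and only rounded (half-up) to integer bp at extraction time, which avoids
cumulative drift across bins; widths below 1 bp are clamped to 1 bp with a
warning.

A **resolution stack** (`resolution_stack()`) precomputes frames for one
region set under several configurations. It is a pure function — the same
call always returns the same frames — so results are cacheable by
(region set, config). Defaults are `w ∈ {50 kb, 200 kb, 1 Mb}` at 25 bins
per side for points and `p ∈ {0.05, 0.1}` at flank 0.2 for intervals.

Bins may extend below coordinate 0 or past the chromosome end; such bins are
carried (frame counts always equal record counts — nothing is silently
dropped) but flagged out-of-bounds and extracted as `NaN`. Strand is carried
but never acted on implicitly; `extract_1d(flip_minus_strand = TRUE)` is the
only, explicit, flipping mechanism.

## 1D and 2D feature extraction

**1D tracks** (`open_track()`) are bigWig files or a bedGraph-like text
dialect. A bin query returns the mean over the bin's basepairs, where
basepairs not covered by any interval count as **0** (read-density
semantics: absence of signal, not absence of data) while basepairs outside
the chromosome are **missing** (`NaN`). Queries are computed from a
per-chromosome cumulative integral of the step function, so splitting a
range into sub-queries and length-weighted averaging reproduces the single
query exactly.

**2D contact stores** (`open_contacts()`) are cooler `.cool`/`.mcool` files
or a text triplet dialect. Values are used as stored (raw counts);
`balance = TRUE` applies the stored per-bin weight column when present.
Matrices are symmetrized from the stored triangle; bins inside the
chromosome with no stored pixel are 0, bins outside are `NaN`. Because a
store is tiled from coordinate 0, a window of arbitrary phase cannot be
represented exactly: point-frame extraction snaps the window start to the
nearest store bin (`round(start / binsize) * binsize`), displacing the
window by at most half a bin. Interval frames are filled by querying the
largest native resolution at or below the frame bin width and
block-averaging fine bins onto frame bins (assignment by fine-bin
midpoint), `NaN`-ignoring within each block.

**Aggregation** is the `NaN`-ignoring mean in every case — per bin across
regions in 1D, per pixel across snippets in 2D — with the number of
contributing regions exposed as a `valid_count` attribute. An all-`NaN`
snippet therefore drops out pixel-wise, not snippet-wise.

**Stacked profiles** subsample uniformly at random, without replacement and
seeded, to at most 1000 rows (the cap of the original interface) before
ordering. The returned `sort_order` names the retained region ids, so the
identical subsample and order can be applied to a second stack of the same
region set (`apply_sort_order()`); this "coupled sorting" is an explicit
value passed between calls, never hidden state. Row statistics
(`row_mean`, `center_bin`) sort with all-`NaN` rows last and ties broken by
region index, so sorting is stable and reproducible.

For interpreting pileup maps, `distance_normalize()` divides each diagonal
band of an average map by its own mean, removing the distance decay, and
`quadrant_contrast()` compares contacts spanning the central anchor
(cross-quadrant) to contacts within each side: ratios below 1 indicate
insulation, ratios near 1 its absence.

## Feature embedding and clustering

The **1D representation** is an `n × m` matrix of mean signal per region and
per track: one scalar per feature, computed as the `NaN`-ignoring mean over
the region's frame.

The **2D representation** turns each square contact snippet of side `m`
bins into `f² = 100` pixel features (default `f = 10`): Gaussian smoothing,
block downsampling to `f × f`, then row-major flattening. Kernel geometry
follows the interpolation factor:

\[ I = \lfloor m / f \rfloor, \qquad K = \lfloor (I+1)/2 \rfloor, \qquad
\sigma = 4K + 1. \]

`σ = 4K + 1` makes the Gaussian much wider than its `K × K` truncation
window, so the kernel is nearly a box filter; the formula is implemented
literally as published, and flagged here because the conventional relation
is the transposed `K ≈ 4σ + 1`. The truncated kernel is renormalized to sum
1, applied separably with reflect-101 padding (edge pixel not repeated).
For even `K` — where reference implementations reject the kernel size —
integer tap offsets `-(K/2) … (K/2 − 1)` are used; both choices preserve
constants exactly, and the test oracle pins the same definition.
Downsampling splits the side into `f` contiguous blocks whose sizes differ
by at most one and takes block means; snippets smaller than `f` are
upsampled nearest-neighbour without smoothing. `NaN` cells are imputed as 0
before smoothing (with the per-snippet `NaN` fraction reported); snippets
more than half `NaN` are excluded and reported.

`embed_and_cluster()` embeds with UMAP (uwot, library defaults, seeded,
single-threaded so results are bit-reproducible) for display, and clusters
with k-means — **on the original high-dimensional feature rows, not the 2D
coordinates**, so clusters reflect similarity of the full feature vectors
rather than of their projection. `k` is any integer ≥ 2 (the original
interface offers presets 10 and 20). Features are not standardized by
default (`standardize = TRUE` opts in). Cluster labels are 1-based (R
convention). Cluster summaries are arithmetic means of member rows;
per-cluster feature intensities are min–max normalized per feature across
clusters, with constant features mapped to 0.5 by convention.
`subset_from_clusters()` turns chosen clusters back into a region set in
original record order.

## Per-bin locus-overlap enrichment

The association analysis reimplements LOLA-style overlap enrichment at
single-bin resolution. The universe is always the genome-wide tiling of the
assembly at the chosen bin size, from coordinate 0, last partial bin
included. For each relative bin of the frames, the target is the set of
universe bins overlapped (≥ 1 bp) by that bin across regions; each
candidate feature set is the query. Every universe bin is classified into
the 2×2 table

| | overlaps query | does not |
|---|---|---|
| **target** | a | c |
| **non-target** | b | d |

and the enrichment is the odds ratio `(a·d)/(b·c)`. The overlap predicate
is ≥ 1 bp, not fraction-based. The Haldane–Anscombe correction (add 0.5 to
every cell when any cell is 0) is on by default so ratios stay finite and
rankable; an empty target margin (`a + c = 0`) is undefined and reported
`NaN` regardless. No p-values are computed — the method reports odds ratios
only.

For planted-signal analyses, `snap_regions_to_bins()` aligns region anchors
to the universe grid so each relative bin coincides with exactly one
universe bin. Without snapping, a relative bin generally straddles two
universe bins and a signal planted in single bins is diluted (in the test
conditions, a closed-form odds ratio of 76 reads out around 13 unsnapped);
general, unaligned geometry remains fully supported.

## The synthetic data generator

Every test runs on synthetic data from `synth_config()`; all generators are
pure functions of (config, seed) and write byte-identical files on re-runs.
The defaults define the reference study conditions:

* **Genome**: 2 chromosomes × 1 Mb.
* **Regions**: 500 anchors, uniform with a guaranteed minimum spacing of
  2 kb (order-statistics construction, no lattice artifacts), each with a
  hidden subtype ("active"/"repressed", 50/50) stored in a sidecar, never in
  the BED.
* **Tracks**: Gaussian background noise (sd 1) clamped at 0, plus Gaussian
  bumps of height 5 (five noise sd) at the anchors of responsive subtypes —
  emulating ChIP-seq read density enriched at peaks. Piecewise constant at
  100 bp.
* **Contacts**: expected counts `100 · (d + 1)^{-1}` with `d` the bin
  distance, modulated at responsive anchors by a multiplicative row/column
  stripe (strength 1) and by depletion of contacts crossing the bin
  boundary nearest the anchor (insulation, strength 0.6), then
  Poisson-sampled; symmetric by construction, 10 kb bins.
* **Feature sets**: universe bins overlapping anchors included with
  probability 0.8, all other bins with probability 0.05, giving an expected
  center-bin odds ratio of `(0.8/0.2)/(0.05/0.95) ≈ 76` at large n.

Analyses choose their geometry to match their question: metaprofile
demonstrations use sparser anchors (5 kb spacing) with narrower peaks (sd
1 kb) and ±10 kb windows so neighbouring regions do not overlap; the
subtype-recovery study uses ±1 kb windows at 100 bp bins with peak sd
300 bp for the same reason; insulation studies switch stripes off so the
two planted 2D effects are not confounded (stripes *raise* cross-quadrant
signal, insulation lowers it). Problem sizes in the tests — up to 500
regions, 2 Mb genomes, 100-instance oracle sweeps — keep the full suite
around half a minute while leaving all effects many standard errors from
their nulls.

What the generator does **not** emulate: read-level sampling noise,
GC/mappability bias, copy-number variation, inter-chromosomal contacts,
distance-dependent dispersion beyond Poisson, or correlated placement of
features (each feature-set bin is independent). Passing tests therefore
demonstrate correctness of the computations and recoverability of planted
structure, not robustness to every artifact of real sequencing data.

## Numerical choices and degenerate inputs

* Rounding of real-valued coordinates is half-up (`floor(x + 0.5)`),
  including negatives.
* Means are `NaN`-ignoring everywhere; a bin/pixel with no valid
  contributions stays `NaN` rather than 0.
* The subsample in `stacked_profiles()` requires an explicit seed whenever
  it actually subsamples; there is no silent RNG use, and seeded sections
  restore the caller's RNG state.
* Empty region sets produce empty (0-row) frames and stacks; aggregation of
  an empty stack is an error rather than a silent `NaN` vector.
* k-means uses 10 restarts (`nstart = 10`) and up to 100 iterations; UMAP
  runs single-threaded with `n_neighbors` capped at `n − 1` for small sets.
* The odds ratio of a saturated table (query covering the whole universe)
  is finite only under the Haldane correction; the uncorrected variant
  returns `NaN`, never `Inf`.

## Known limitations

* `.hic` files are not read; cooler (plus the text dialect) is the 2D
  backend.
* Contact queries are intra-chromosomal only.
* Interval-region 2D extraction block-averages a finer native resolution;
  if no native resolution is at least as fine as the frame bin width, it is
  an error rather than an interpolation.
* The per-bin enrichment loops over (bin × feature set) pairs; it is sized
  for thousands of universe bins and tens of feature sets, not for
  genome-wide scans at 1 kb on mammalian genomes.
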