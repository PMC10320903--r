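# regionstack

Multi-scale analysis of genomic region sets: signal pileups, stacked
profiles, feature embeddings and per-bin locus-overlap enrichment — as a
headless R library with a reproducible command-line interface.

## What it is for

Given a set of genomic loci that share a property — all transcription start
sites, all ChIP-seq peaks for a factor, all domain boundaries — a recurring
set of questions arises in regulatory genomics and chromosome-organization
work:

* What does a coverage track (ChIP-seq, ATAC-seq read density) look like
  *on average* around these loci, and region by region?
* What does the Hi-C contact map look like around them — stripes?
  insulation?
* Are the loci one homogeneous population, or a mixture of sub-populations
  with distinct chromatin profiles?
* Which *other* region sets (peak sets, annotations) overlap them, and at
  which relative position?

`regionstack` answers these on point regions (anchor ± window) and interval
regions (whole extent + 20% flanks, length-normalized bins), precomputing a
**resolution stack** of binned frames per region set so the same loci can
be examined at several length scales. All coordinates are 0-based half-open
(BED-native).

The core quantities:

* **1D/2D pileups** — snippet stacks `S[i, j]` (region × bin) or
  `S[i, j, k]` (region × bin × bin), reduced by NaN-ignoring means to
  average profiles and aggregate maps.
* **Stacked line profiles** — the per-region heatmap matrix, subsampled
  (seeded) to ≤ 1000 rows, with explicit, shareable sort orders so several
  stacks of one region set can be sorted coherently.
* **Feature embedding** — per-region feature vectors (mean track signal, or
  smoothed 10×10-downsampled contact snippets flattened to 100 pixel
  features with kernel geometry `I = ⌊m/f⌋`, `K = ⌊(I+1)/2⌋`, `σ = 4K+1`),
  embedded in 2D with UMAP and clustered with k-means on the raw
  high-dimensional features.
* **Per-bin enrichment** — for each relative bin of the region set and each
  candidate feature set, the odds ratio `(a·d)/(b·c)` of the 2×2 table
  counting genome-wide universe bins by (target / non-target) ×
  (overlaps query / not), with Haldane–Anscombe correction; a LOLA-style
  association localized along the relative coordinate.

A fully seeded synthetic-data module (toy genomes, tracks with planted
peaks, contact matrices with distance decay / stripes / insulation, feature
sets with planted positional enrichment) makes every analysis testable with
zero downloads. See `vignettes/regionstack-methods.Rmd` for the methods in
detail.

## Worked example

```r
library(regionstack)

cfg <- synth_config(seed = 42, n_regions = 200, min_spacing = 5000,
                    peak_width = 1000)
asm     <- synth_genome(cfg)          # <genome_assembly> synth - 2 chromosomes, 2e+06 bp total
regions <- synth_regions(cfg, asm)    # <region_set> point kind, 200 records
track   <- synth_track(cfg, asm, regions, c(active = 1, repressed = 0))

# average profile in a +/-10 kb window, 500 bp bins (40 bins)
frames  <- point_frames(regions, point_config(10000, 500))
profile <- aggregate_1d(extract_1d(track, frames))
round(profile[18:23], 2)
#> 1.37 2.07 2.58 2.60 2.03 1.30
which.max(profile)
#> 21
```

The planted coverage peak is recovered at the frame center (the anchor sits
between bins 20 and 21 of 40); the profile rises from the ~0.5 background
(clamped unit noise) to ~2.6 at the center — the planted bumps sit on the
"active" half of the regions only, so the average peak is about half the
planted amplitude.

```r
# where does a feature set overlap these regions, in relative coordinates?
universe <- make_universe(asm, 1000)
feats    <- synth_feature_sets(cfg, regions, universe)
enr      <- per_bin_enrichment(
  point_frames(snap_regions_to_bins(regions, 1000), point_config(3000, 1000)),
  feats, universe)
round(enr$or[1, ], 2)
#> 0.38 0.34 0.42 76.00 0.34 0.34
rank_features(enr, 4)
#>      feature odds_ratio
#> 1 feature_01         76
```

The feature set planted at region centers (inclusion probability 0.8 at
center bins vs 0.05 elsewhere) shows an odds ratio of 76 exactly at the
anchor bin — matching the closed form `(0.8/0.2)/(0.05/0.95) ≈ 76` — and
background-level enrichment in the flanking bins.

## Command-line interface

A thin wrapper over the same functions is installed at
`system.file("cli", "regionstack", package = "regionstack")`:

```sh
regionstack synth --seed 7 --out demo
regionstack aggregate1d --regions demo/regions.bed \
    --chrom-sizes demo/genome.chrom.sizes --track demo/track.txt \
    --window 20000 --binsize 2000 --out demo/agg
regionstack lola --regions demo/regions.bed \
    --chrom-sizes demo/genome.chrom.sizes --features demo/feature_01.bed \
    --window 30000 --binsize 10000 --out demo/lola
```

Subcommands: `aggregate1d`, `aggregate2d`, `stack`, `embed1d`, `embed2d`,
`lola`, `synth`. Every run writes its outputs plus a `manifest.json`
(inputs, parameters, seed, version — no timestamps); re-running a command
with the same manifest reproduces all outputs byte-identically.

## Text dialects

Besides bigWig and cooler, both feature readers accept plain-text dialects
so pipelines can run without binary files.

1D track (bedGraph-like, tab-separated, 0-based half-open, non-overlapping):

```
# chrom: chr1 1000000
chr1<TAB>0<TAB>100<TAB>2.5
```

2D contacts (per-chromosome bin indices `i`, `j` at the declared bin size;
one triangle suffices, symmetrized at query time):

```
# binsize: 10000
# chrom: chr1 1000000
chr1<TAB>0<TAB>1<TAB>5
```

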