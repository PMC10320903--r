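#' Resolution configurations
#'
#' A resolution configuration determines how a region is turned into a binned
#' coordinate frame. Point regions use an absolute window: half-width `w` bp
#' on each side of the anchor, split into bins of `b` bp (`b` must divide
#' `2w`). Interval regions use proportional geometry: bin width is a fraction
#' `p` of the interval length and the interval is extended by
#' `flank_fraction` of its length on either side, so differently sized
#' intervals all yield the same number of bins (length normalization).
#'
#' @param windowsize Half-width `w` in bp (total window `2w`).
#' @param binsize Bin width `b` in bp; must divide `2 * windowsize` exactly.
#' @return A `resolution_config` of subclass `point_config` or
#'   `interval_config`.
#' @examples
#' point_config(windowsize = 50000, binsize = 2000)   # 50 bins
#' interval_config(binsize_fraction = 0.1)            # 14 bins at flank 0.2
#' @export
point_config <- function(windowsize, binsize) {
  stopifnot(is.numeric(windowsize), is.numeric(binsize))
  w <- as.numeric(windowsize); b <- as.numeric(binsize)
  if (w <= 0 || b <= 0) stop("windowsize and binsize must be positive")
  if ((2 * w) %% b != 0) {
    stop("binsize (", b, ") must divide the full window 2*windowsize (", 2 * w, ")")
  }
  structure(list(kind = "point", windowsize = w, binsize = b,
                 n_bins = as.integer(2 * w / b)),
            class = c("point_config", "resolution_config"))
}

#' @rdname point_config
#' @param binsize_fraction Bin width as a fraction `p` of interval length,
#'   `0 < p <= 1 + flank_fraction`.
#' @param flank_fraction Flank extension on either side as a fraction of
#'   interval length (default 0.2, i.e. 20% neighbouring sequence).
#' @export
interval_config <- function(binsize_fraction, flank_fraction = 0.2) {
  p <- as.numeric(binsize_fraction); f <- as.numeric(flank_fraction)
  if (f < 0) stop("flank_fraction must be >= 0")
  if (p <= 0 || p > 1 + f) stop("binsize_fraction must satisfy 0 < p <= 1 + flank_fraction")
  structure(list(kind = "interval", binsize_fraction = p, flank_fraction = f,
                 n_bins = as.integer(round((1 + 2 * f) / p))),
            class = c("interval_config", "resolution_config"))
}

#' Default resolution stacks
#'
#' Points: half-windows of 50 kb, 200 kb and 1 Mb, each at 25 bins per side.
#' Intervals: bin fractions 0.05 and 0.1 at 20% flanks.
#'
#' @param kind `"point"` or `"interval"`.
#' @return List of `resolution_config`s.
#' @export
default_configs <- function(kind = c("point", "interval")) {
  kind <- match.arg(kind)
  if (kind == "point") {
    lapply(c(5e4, 2e5, 1e6), function(w) point_config(w, w / 25))
  } else {
    lapply(c(0.05, 0.1), interval_config)
  }
}

# round-half-up to integer bp; interval bin edges are real until extraction
round_half_up <- function(x) floor(x + 0.5)

new_bin_frames <- function(chrom, strand, edges, chrom_len, kind, region_ids) {
  n_bins <- ncol(edges) - 1L
  left <- round_half_up(edges[, -(n_bins + 1L), drop = FALSE])
  right <- round_half_up(edges[, -1L, drop = FALSE])
  oob <- left < 0 | right > chrom_len  # any bp outside [0, chrom length)
  structure(list(chrom = chrom, strand = strand, edges = edges, oob = oob,
                 n_bins = n_bins, kind = kind, chrom_len = chrom_len,
                 region_ids = region_ids),
            class = "bin_frames")
}

#' Binned coordinate frames ("snippets" geometry)
#'
#' `point_frames()` computes, for each record with anchor `c`, the frame
#' `[c - w, c + w)` split into `2w/b` bins of `b` bp. `interval_frames()`
#' computes, for each record `[s, e)` of length `L`, bins of width
#' `p * L` starting at `s - flank * L`, `round((1 + 2*flank)/p)` bins in
#' total — identical bin counts for intervals of any length. Edges may extend
#' below 0 or beyond the chromosome end; such bins are flagged out of bounds
#' and extracted as `NaN`. Interval bin edges are kept real-valued and rounded
#' half-up to integer bp only at extraction time.
#'
#' @param regions A [region_set()] of matching kind.
#' @param cfg A [point_config()] or [interval_config()].
#' @return A `bin_frames` object: per-region `chrom`, `strand`, an
#'   `n x (n_bins+1)` edge matrix, an out-of-bounds mask, and `region_ids`
#'   aligned to `regions` row order.
#' @export
point_frames <- function(regions, cfg) {
  stopifnot(inherits(regions, "region_set"), inherits(cfg, "point_config"))
  if (region_kind(regions) != "point") {
    stop("point_frames requires a point-kind region set")
  }
  n <- nrow(regions)
  anchors <- region_anchors(regions)
  edges <- outer(anchors - cfg$windowsize,
                 seq(0, 2 * cfg$windowsize, by = cfg$binsize), `+`)
  if (n == 0L) edges <- matrix(numeric(), 0L, cfg$n_bins + 1L)
  new_bin_frames(regions$chrom, regions$strand, edges,
                 chrom_length(region_assembly(regions), regions$chrom),
                 "point", seq_len(n))
}

#' @rdname point_frames
#' @export
interval_frames <- function(regions, cfg) {
  stopifnot(inherits(regions, "region_set"), inherits(cfg, "interval_config"))
  if (region_kind(regions) != "interval") {
    stop("interval_frames requires an interval-kind region set")
  }
  n <- nrow(regions)
  L <- regions$end - regions$start
  width <- cfg$binsize_fraction * L
  if (n > 0 && any(width < 1)) {
    warning(sum(width < 1), " region(s) with bin width below 1 bp; clamped to 1 bp")
    width <- pmax(width, 1)
  }
  left <- regions$start - cfg$flank_fraction * L
  edges <- outer(width, 0:cfg$n_bins) + left
  if (n == 0L) edges <- matrix(numeric(), 0L, cfg$n_bins + 1L)
  new_bin_frames(regions$chrom, regions$strand, edges,
                 chrom_length(region_assembly(regions), regions$chrom),
                 "interval", seq_len(n))
}

#' Integer bin edges of a frame set
#'
#' Rounds the (possibly real-valued) frame edges half-up to integer bp — the
#' coordinates actually used at extraction time.
#'
#' @param frames A `bin_frames` object.
#' @return An `n x (n_bins+1)` integer-valued matrix of edges in bp.
#' @export
frame_edges <- function(frames) {
  stopifnot(inherits(frames, "bin_frames"))
  round_half_up(frames$edges)
}

#' Precompute a resolution stack
#'
#' Computes frames for one region set at every configuration, the precomputed
#' multi-scale representation that downstream pileups and enrichment reuse. A
#' pure function: results are cacheable by (region set, config) and identical
#' across calls.
#'
#' @param regions A [region_set()].
#' @param configs Non-empty list of `resolution_config`s matching the region
#'   kind.
#' @return Named list of `bin_frames`, one per config; names encode the
#'   config (`w<w>_b<b>` or `p<p>_f<flank>`).
#' @export
resolution_stack <- function(regions, configs = default_configs(region_kind(regions))) {
  stopifnot(inherits(regions, "region_set"))
  if (length(configs) == 0L) stop("configs must be a non-empty list")
  kinds <- vapply(configs, function(cfg) cfg$kind, "")
  if (any(kinds != region_kind(regions))) {
    stop("all configs must match the region kind '", region_kind(regions), "'")
  }
  out <- lapply(configs, function(cfg) {
    if (cfg$kind == "point") point_frames(regions, cfg) else interval_frames(regions, cfg)
  })
  names(out) <- vapply(configs, function(cfg) {
    if (cfg$kind == "point") {
      sprintf("w%g_b%g", cfg$windowsize, cfg$binsize)
    } else {
      sprintf("p%g_f%g", cfg$binsize_fraction, cfg$flank_fraction)
    }
  }, "")
  out
}

#' @export
print.bin_frames <- function(x, ...) {
  cat("<bin_frames>", length(x$chrom), "frames x", x$n_bins, "bins (",
      x$kind, "kind ),", sum(x$oob), "out-of-bounds bins\n")
  invisible(x)
}

n_frames <- function(frames) length(frames$chrom)
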