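#' Genome-wide bin universe
#'
#' Tiles every chromosome of an assembly with bins of `binsize` bp starting
#' at coordinate 0; the last bin of each chromosome may be partial. The
#' universe is the background against which per-bin locus-overlap enrichment
#' is measured — always all genome-wide bins of the matched size.
#'
#' @param assembly A [genome_assembly()].
#' @param binsize Bin size in bp.
#' @return A `bin_universe` with per-chromosome bin counts, global-id
#'   offsets and `total_bins = sum(ceiling(length / binsize))`.
#' @export
make_universe <- function(assembly, binsize) {
  stopifnot(inherits(assembly, "genome_assembly"), binsize > 0)
  n_bins <- ceiling(assembly$chrom_sizes / binsize)
  offsets <- c(0, cumsum(n_bins))[seq_along(n_bins)]
  names(offsets) <- names(n_bins)
  structure(list(assembly = assembly, binsize = binsize, n_bins = n_bins,
                 offsets = offsets, total_bins = as.integer(sum(n_bins))),
            class = "bin_universe")
}

# global universe-bin ids (1-based) overlapped >= 1 bp by [start, end) on chrom;
# intervals are clipped to the chromosome, unknown chromosomes yield none
universe_bin_ids <- function(universe, chrom, start, end) {
  b <- universe$binsize
  ids <- vector("list", length(chrom))
  nb <- universe$n_bins[chrom]
  off <- universe$offsets[chrom]
  len <- universe$assembly$chrom_sizes[chrom]
  for (r in seq_along(chrom)) {
    if (is.na(nb[r])) next
    s <- max(start[r], 0)
    e <- min(end[r], len[r])
    if (e <= s) next
    ids[[r]] <- off[r] + seq.int(floor(s / b), floor((e - 1) / b)) + 1
  }
  unique(unlist(ids, use.names = FALSE))
}

#' Snap a point region set to a bin grid
#'
#' Replaces each region's anchor by the left boundary of the universe bin
#' containing it, yielding a point region set whose frames (at a bin width
#' equal to `binsize`) tile the genome-wide bin grid exactly — so each
#' relative bin of each region coincides with exactly one universe bin.
#' This is the natural geometry for per-bin association analysis, where a
#' bin is the target region; without snapping, a relative bin generally
#' straddles two universe bins and planted signal is diluted.
#'
#' @param regions A point-kind [region_set()].
#' @param binsize Bin size of the universe grid in bp.
#' @return A point [region_set()] with one `binsize`-wide record per region,
#'   whose anchors are multiples of `binsize`.
#' @export
snap_regions_to_bins <- function(regions, binsize) {
  stopifnot(inherits(regions, "region_set"), binsize > 0)
  cb <- floor(region_anchors(regions) / binsize) * binsize
  start <- cb - floor(binsize / 2)
  end <- cb + ceiling(binsize / 2)
  len <- chrom_length(region_assembly(regions), regions$chrom)
  keep <- start >= 0 & end <= len
  if (any(!keep)) {
    warning(sum(!keep), " region(s) too close to a chromosome edge to snap; dropped")
  }
  out <- region_set(data.frame(chrom = regions$chrom, start = start, end = end,
                               name = regions$name,
                               strand = regions$strand)[keep, , drop = FALSE],
                    region_assembly(regions), "point")
  st <- attr(regions, "subtypes")
  if (!is.null(st)) attr(out, "subtypes") <- st[keep]
  out
}

#' Per-region target bins
#'
#' For per-bin enrichment, each relative bin of a frame set becomes a target
#' interval: one genomic interval per region, namely that region's
#' `bin_index`-th bin. Out-of-bounds bins are dropped (their count is
#' attached as attribute `n_dropped`).
#'
#' @param frames A `bin_frames` object.
#' @param bin_index Relative bin, 1-based, `1 <= bin_index <= n_bins`.
#' @return data.frame of `chrom`, `start`, `end` target intervals.
#' @export
bin_targets <- function(frames, bin_index) {
  stopifnot(inherits(frames, "bin_frames"),
            bin_index >= 1L, bin_index <= frames$n_bins)
  edges <- frame_edges(frames)
  keep <- !frames$oob[, bin_index]
  out <- data.frame(chrom = frames$chrom[keep],
                    start = edges[keep, bin_index],
                    end = edges[keep, bin_index + 1L])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Contingency table for locus-overlap enrichment
#'
#' Snaps the target intervals to universe bins (a universe bin is "target"
#' if any target interval overlaps it by at least 1 bp) and classifies every
#' universe bin by target membership and query overlap (again >= 1 bp):
#' `a` target bins overlapping the query, `b` non-target bins overlapping,
#' `c` target bins not overlapping, `d` the rest. `a + b + c + d` always
#' equals the universe size.
#'
#' @param target data.frame of `chrom`, `start`, `end` intervals (e.g. from
#'   [bin_targets()]).
#' @param query A [region_set()] (the candidate feature set).
#' @param universe A [make_universe()] result.
#' @return A `contingency_table` list with counts `a`, `b`, `c`, `d` and
#'   `total_bins`.
#' @export
contingency <- function(target, query, universe) {
  stopifnot(inherits(universe, "bin_universe"))
  t_bins <- universe_bin_ids(universe, target$chrom, target$start, target$end)
  q_bins <- universe_bin_ids(universe, query$chrom, query$start, query$end)
  a <- length(intersect(t_bins, q_bins))
  c_ <- length(t_bins) - a
  b <- length(q_bins) - a
  d <- universe$total_bins - a - b - c_
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c_),
                 d = as.integer(d), total_bins = universe$total_bins),
            class = "contingency_table")
}

#' Odds ratio of a contingency table
#'
#' `OR = (a * d) / (b * c)`. With the Haldane–Anscombe correction (default),
#' 0.5 is added to every cell whenever any cell is zero, keeping ratios
#' finite and rankable; with `correction = "none"` a zero denominator yields
#' `NaN`. An empty target margin (`a + c = 0`, e.g. every frame bin out of
#' bounds) is undefined and reported as `NaN` regardless of correction.
#'
#' @param t A `contingency_table`.
#' @param correction `"haldane"` (default) or `"none"`.
#' @return Odds ratio as a single double.
#' @export
odds_ratio <- function(t, correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(t, "contingency_table"))
  if (t$a + t$c == 0L) return(NaN)
  cells <- c(t$a, t$b, t$c, t$d)
  if (correction == "haldane" && any(cells == 0)) cells <- cells + 0.5
  if (cells[2] * cells[3] == 0) return(NaN)
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Per-bin locus-overlap enrichment profile
#'
#' For every relative bin of the frames and every candidate feature set,
#' computes the contingency table (bin as target, feature set as query,
#' genome-wide bins as universe) and its odds ratio — localizing enrichment
#' along the relative coordinate of the region set rather than summarizing
#' whole regions.
#'
#' @param frames A `bin_frames` object for the region set of interest.
#' @param feature_sets Named list of [region_set()]s (candidate features).
#' @param universe A [make_universe()] result. Its bin size would normally
#'   match the frame bin width.
#' @param correction Passed to [odds_ratio()].
#' @return An `enrichment_profile`: `or` (features x bins matrix), `counts`
#'   (features x bins x 4 array of a, b, c, d), `top_feature` (per-bin name
#'   of the most enriched feature).
#' @export
per_bin_enrichment <- function(frames, feature_sets, universe,
                               correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(frames, "bin_frames"), length(feature_sets) >= 1L)
  fnames <- names(feature_sets) %||% paste0("feature", seq_along(feature_sets))
  nb <- frames$n_bins
  or <- matrix(NaN, length(feature_sets), nb, dimnames = list(fnames, NULL))
  counts <- array(0L, c(length(feature_sets), nb, 4L),
                  dimnames = list(fnames, NULL, c("a", "b", "c", "d")))
  q_bins <- lapply(feature_sets, function(q)
    universe_bin_ids(universe, q$chrom, q$start, q$end))
  for (bi in seq_len(nb)) {
    tg <- bin_targets(frames, bi)
    t_bins <- universe_bin_ids(universe, tg$chrom, tg$start, tg$end)
    for (fi in seq_along(feature_sets)) {
      a <- length(intersect(t_bins, q_bins[[fi]]))
      tab <- structure(list(a = a, b = length(q_bins[[fi]]) - a,
                            c = length(t_bins) - a,
                            d = as.integer(universe$total_bins - length(t_bins) -
                                             length(q_bins[[fi]]) + a),
                            total_bins = universe$total_bins),
                       class = "contingency_table")
      counts[fi, bi, ] <- c(tab$a, tab$b, tab$c, tab$d)
      or[fi, bi] <- odds_ratio(tab, correction)
    }
  }
  top <- apply(or, 2L, function(x) {
    if (all(is.na(x))) NA_character_ else fnames[which.max(x)]
  })
  structure(list(or = or, counts = counts, top_feature = top,
                 binsize = universe$binsize),
            class = "enrichment_profile")
}

#' Ranked feature list at one relative bin
#'
#' @param profile An `enrichment_profile`.
#' @param bin_index Relative bin (1-based).
#' @return data.frame of `feature`, `odds_ratio` sorted by decreasing odds
#'   ratio, ties broken by feature name.
#' @export
rank_features <- function(profile, bin_index) {
  stopifnot(inherits(profile, "enrichment_profile"))
  x <- profile$or[, bin_index]
  ord <- order(-x, names(x), na.last = TRUE)
  data.frame(feature = names(x)[ord], odds_ratio = unname(x[ord]))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> a =", x$a, "b =", x$b, "c =", x$c, "d =", x$d,
      "(", x$total_bins, "universe bins )\n")
  invisible(x)
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat("<enrichment_profile>", nrow(x$or), "feature set(s) x", ncol(x$or),
      "bins at binsize", x$binsize, "\n")
  invisible(x)
}
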