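#' Extract 1D snippets over bin frames
#'
#' Queries a signal track at every frame, producing the region-by-bin snippet
#' stack behind metaprofiles and stacked line profiles. Out-of-bounds bins are
#' `NaN`; rows for regions entirely off-chromosome are all-`NaN` and
#' preserved. With `flip_minus_strand = TRUE` the rows of `-`-strand records
#' are reversed so that bins read 5' to 3'; frames are never flipped
#' implicitly.
#'
#' @param track A [open_track()] result.
#' @param frames A `bin_frames` object ([point_frames()]/[interval_frames()]).
#' @param flip_minus_strand Reverse rows of minus-strand records.
#' @return A 1D `snippet_stack`: an `n_regions x n_bins` matrix with
#'   attribute `region_ids`.
#' @export
extract_1d <- function(track, frames, flip_minus_strand = FALSE) {
  stopifnot(inherits(track, "signal_track"), inherits(frames, "bin_frames"))
  edges <- frame_edges(frames)
  n <- n_frames(frames)
  vals <- matrix(NaN, n, frames$n_bins)
  for (r in seq_len(n)) {
    vals[r, ] <- query_track_edges(track, frames$chrom[r], edges[r, ])
  }
  vals[frames$oob] <- NaN
  if (flip_minus_strand) {
    minus <- frames$strand == "-"
    vals[minus, ] <- vals[minus, rev(seq_len(frames$n_bins)), drop = FALSE]
  }
  new_snippet_stack(vals, frames$region_ids)
}

new_snippet_stack <- function(values, region_ids) {
  structure(values, region_ids = region_ids,
            class = c("snippet_stack", class(values)))
}

stack_region_ids <- function(stack) attr(stack, "region_ids")

is_stack_2d <- function(stack) length(dim(stack)) == 3L

#' Average profile of a 1D snippet stack
#'
#' Per-bin mean across regions, ignoring `NaN`; a bin that is `NaN` in every
#' row stays `NaN`. The number of contributing regions per bin is attached as
#' attribute `valid_count`.
#'
#' @param stack A 1D `snippet_stack` from [extract_1d()].
#' @return Numeric vector of length `n_bins` with attribute `valid_count`.
#' @export
aggregate_1d <- function(stack) {
  stopifnot(inherits(stack, "snippet_stack"), !is_stack_2d(stack))
  if (nrow(stack) == 0L) stop("cannot aggregate an empty stack")
  valid <- colSums(!is.na(stack))
  out <- suppressWarnings(colMeans(stack, na.rm = TRUE))
  out[valid == 0L] <- NaN
  attr(out, "valid_count") <- valid
  out
}

#' Extract 2D contact snippets over bin frames
#'
#' For point frames whose bin width matches a native store bin size, snippet
#' `(i, j, k)` is the contact value between frame-i bins `j` and `k`; the
#' query window is snapped to the store's bin grid (a store tiled from
#' coordinate 0 cannot represent an arbitrary-phase window). For interval
#' frames, the largest native bin size not exceeding the smallest frame bin
#' width is queried and block-averaged onto the frame bins (fine bins
#' assigned by midpoint). Off-chromosome rows and columns are `NaN`.
#'
#' @param contacts A [open_contacts()] result.
#' @param frames A `bin_frames` object.
#' @param binsize Native bin size to use; default picks the frame bin width
#'   (point kind) or the largest native size at or below the smallest frame
#'   bin width (interval kind).
#' @param balance Use stored balancing weights (see [query_contacts()]).
#' @return A 2D `snippet_stack`: `n_regions x n_bins x n_bins` array.
#' @export
extract_2d <- function(contacts, frames, binsize = NULL, balance = FALSE) {
  stopifnot(inherits(contacts, "contact_store"), inherits(frames, "bin_frames"))
  n <- n_frames(frames)
  nb <- frames$n_bins
  out <- array(NaN, c(n, nb, nb))
  if (frames$kind == "point") {
    bw <- if (n > 0) frames$edges[1, 2] - frames$edges[1, 1] else NA_real_
    if (is.null(binsize)) binsize <- bw
    if (!is.null(bw) && n > 0 && binsize != bw) {
      stop("point frames have bin width ", bw, " but binsize ", binsize, " requested")
    }
    if (!format(as.numeric(binsize), scientific = FALSE) %in%
          names(contacts$resolutions)) {
      stop("binsize ", binsize, " not in store; available: ",
           paste(contacts$binsizes, collapse = ", "))
    }
    for (r in seq_len(n)) {
      qstart <- round(frames$edges[r, 1] / binsize) * binsize
      out[r, , ] <- query_contacts(contacts, frames$chrom[r], qstart,
                                   qstart + nb * binsize, binsize, balance)
    }
  } else {
    edges <- frame_edges(frames)
    min_bw <- min(edges[, -1, drop = FALSE] - edges[, -(nb + 1L), drop = FALSE])
    fine <- contacts$binsizes[contacts$binsizes <= min_bw]
    if (length(fine) == 0L) {
      stop("no native binsize <= frame bin width ", min_bw, "; available: ",
           paste(contacts$binsizes, collapse = ", "))
    }
    fb <- max(fine)
    for (r in seq_len(n)) {
      e <- edges[r, ]
      fstart <- floor(e[1] / fb) * fb
      fend <- ceiling(e[nb + 1L] / fb) * fb
      fm <- query_contacts(contacts, frames$chrom[r], fstart, fend, fb, balance)
      mids <- fstart + (seq_len(nrow(fm)) - 0.5) * fb
      grp <- findInterval(mids, e, rightmost.closed = FALSE)
      keep <- grp >= 1L & grp <= nb
      grp <- factor(grp[keep], levels = seq_len(nb))
      sub <- fm[keep, keep, drop = FALSE]
      # block mean of fine pixels within each coarse cell, NaN-ignoring
      cnt <- (!is.na(sub)) * 1
      sub0 <- ifelse(is.na(sub), 0, sub)
      sums <- rowsum(t(rowsum(sub0, grp)), grp)
      cnts <- rowsum(t(rowsum(cnt, grp)), grp)
      out[r, , ] <- ifelse(cnts > 0, sums / cnts, NaN)
    }
  }
  oob <- frames$oob
  for (r in seq_len(n)) {
    out[r, oob[r, ], ] <- NaN
    out[r, , oob[r, ]] <- NaN
  }
  new_snippet_stack(out, frames$region_ids)
}

#' Average map of a 2D snippet stack
#'
#' Pixel-wise mean across snippets, ignoring `NaN` (so an all-`NaN` snippet
#' drops out per-pixel, not per-snippet). The per-pixel count of contributing
#' snippets is attached as attribute `valid_count`.
#'
#' @param stack A 2D `snippet_stack` from [extract_2d()].
#' @return `n_bins x n_bins` numeric matrix with attribute `valid_count`.
#' @export
aggregate_2d <- function(stack) {
  stopifnot(inherits(stack, "snippet_stack"), is_stack_2d(stack))
  if (dim(stack)[1] == 0L) stop("cannot aggregate an empty stack")
  valid <- apply(!is.na(stack), c(2, 3), sum)
  out <- suppressWarnings(apply(stack, c(2, 3), mean, na.rm = TRUE))
  out[valid == 0L] <- NaN
  attr(out, "valid_count") <- valid
  out
}

#' Distance-normalize an average contact map
#'
#' Divides every diagonal band of a square matrix by that band's NaN-ignoring
#' mean, removing the power-law distance decay so that structure (stripes,
#' insulation) stands out as deviation from 1.
#'
#' @param m Square numeric matrix (e.g. from [aggregate_2d()]).
#' @return Matrix of observed/expected ratios.
#' @export
distance_normalize <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- nrow(m)
  d <- abs(row(m) - col(m))
  band_mean <- vapply(0:(n - 1), function(k) {
    v <- m[d == k]
    if (all(is.na(v))) NaN else mean(v, na.rm = TRUE)
  }, 0)
  m / band_mean[d + 1L]
}

#' Cross- versus within-quadrant contrast around the frame center
#'
#' Splits a (distance-normalized) average map at the central anchor into
#' upstream and downstream halves and compares the mean of cross-quadrant
#' pixels (contacts spanning the anchor) to the mean of within-quadrant
#' off-diagonal pixels. Ratios below 1 indicate insulation at the anchor;
#' approximately 1 indicates no boundary.
#'
#' @param m Square matrix with an even side (anchor on the central bin
#'   boundary).
#' @param normalize Distance-normalize first (default TRUE).
#' @return `list(cross, within, ratio)`.
#' @export
quadrant_contrast <- function(m, normalize = TRUE) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) %% 2L == 0L)
  if (normalize) m <- distance_normalize(m)
  h <- nrow(m) / 2L
  up <- seq_len(h); down <- h + seq_len(h)
  off <- abs(row(m) - col(m)) > 0
  cross <- mean(m[up, down], na.rm = TRUE)
  within <- mean(c(m[up, up][off[up, up]], m[down, down][off[down, down]]),
                 na.rm = TRUE)
  list(cross = cross, within = within, ratio = cross / within)
}

#' Sort order for stacked profiles
#'
#' Computes a permutation of regions by a per-row statistic of a 1D stack.
#' All-`NaN` rows sort last; ties are broken by region index (stable). The
#' returned `sort_order` carries region ids and provenance so it can be
#' applied to another stack of the same region set ("coupled sorting" across
#' widgets).
#'
#' @param stack A 1D `snippet_stack`.
#' @param statistic `"row_mean"` (NaN-ignoring mean over bins) or
#'   `"center_bin"` (mean of the two middle bins).
#' @param descending Sort largest first.
#' @param provenance Optional label recording which track/statistic produced
#'   the order.
#' @return A `sort_order`: region ids in display order plus provenance.
#' @export
sort_order_by_track <- function(stack, statistic = c("row_mean", "center_bin"),
                                descending = FALSE, provenance = NULL) {
  stopifnot(inherits(stack, "snippet_stack"), !is_stack_2d(stack))
  statistic <- match.arg(statistic)
  stat <- switch(statistic,
    row_mean = suppressWarnings(rowMeans(stack, na.rm = TRUE)),
    center_bin = {
      nb <- ncol(stack)
      mid <- if (nb %% 2L == 0L) c(nb %/% 2L, nb %/% 2L + 1L) else (nb + 1L) %/% 2L
      suppressWarnings(rowMeans(stack[, mid, drop = FALSE], na.rm = TRUE))
    })
  stat[!is.finite(stat)] <- NA
  perm <- order(if (descending) -stat else stat, seq_along(stat), na.last = TRUE)
  new_sort_order(stack_region_ids(stack)[perm],
                 provenance %||% paste0(statistic, if (descending) " desc" else " asc"))
}

new_sort_order <- function(region_ids, provenance = NULL) {
  structure(list(region_ids = region_ids, provenance = provenance),
            class = "sort_order")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a sort order to a snippet stack
#'
#' Reorders (and possibly subsets) the rows of a stack to match the region
#' ids of `order` — the mechanism behind coupled sorting of several stacked
#' profile displays over one region set.
#'
#' @param stack A `snippet_stack` (1D or 2D).
#' @param order A `sort_order`.
#' @return The reordered stack; errors if `order` references region ids not
#'   present in `stack`.
#' @export
apply_sort_order <- function(stack, order) {
  stopifnot(inherits(stack, "snippet_stack"), inherits(order, "sort_order"))
  idx <- match(order$region_ids, stack_region_ids(stack))
  if (anyNA(idx)) stop("sort order references region ids absent from the stack")
  vals <- if (is_stack_2d(stack)) stack[idx, , , drop = FALSE]
          else stack[idx, , drop = FALSE]
  new_snippet_stack(vals, order$region_ids)
}

#' Stacked line-profile matrix
#'
#' Builds the region-by-bin heatmap matrix: if the stack holds more than
#' `max_rows` regions it is first subsampled — uniformly at random, without
#' replacement, seeded — to exactly `max_rows` rows (default cap 1000), then
#' ordered. The returned `sort_order` names the retained region ids so the
#' identical subsample/order can be applied to another stack of the same
#' region set.
#'
#' @param stack A 1D `snippet_stack`.
#' @param max_rows Maximum number of rows retained (default 1000).
#' @param order Optional `sort_order` (e.g. from [sort_order_by_track()] on
#'   another track); it then defines both the subset and the row order.
#' @param seed Integer seed for the subsample (required when subsampling
#'   without an explicit `order`).
#' @return `list(matrix = <rows x n_bins>, order = <sort_order>)`.
#' @export
stacked_profiles <- function(stack, max_rows = 1000L, order = NULL, seed = NULL) {
  stopifnot(inherits(stack, "snippet_stack"), !is_stack_2d(stack))
  ids <- stack_region_ids(stack)
  if (!is.null(order)) {
    out <- apply_sort_order(stack, order)
    if (nrow(out) > max_rows) stop("sort order retains more than max_rows rows")
    return(list(matrix = unclass(out), order = order))
  }
  keep_ids <- ids
  if (length(ids) > max_rows) {
    if (is.null(seed)) stop("subsampling below ", length(ids),
                            " regions requires a seed")
    keep_ids <- with_seed(seed, sort(sample(ids, max_rows)))
  }
  ord <- new_sort_order(keep_ids, "identity")
  out <- apply_sort_order(stack, ord)
  list(matrix = unclass(out), order = ord)
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Write a profile or stacked matrix as TSV
#'
#' Stacked matrices get a leading `region_id` column; profiles one value per
#' bin.
#'
#' @param x Numeric vector (profile) or matrix with attribute/ids.
#' @param path Output path.
#' @param region_ids Optional ids for matrix rows.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path, region_ids = NULL) {
  if (is.matrix(x)) {
    df <- data.table::as.data.table(x)
    names(df) <- paste0("bin", seq_len(ncol(x)))
    if (!is.null(region_ids)) df <- cbind(region_id = region_ids, df)
    data.table::fwrite(df, path, sep = "\t")
  } else {
    data.table::fwrite(data.table::data.table(bin = seq_along(x), value = as.numeric(x)),
                       path, sep = "\t")
  }
  invisible(path)
}
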