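#' Per-region 1D feature matrix
#'
#' Builds the high-dimensional representation for 1D embedding: entry
#' `(i, j)` is the NaN-ignoring mean signal of track `j` over region `i`'s
#' whole frame — one scalar per region per feature.
#'
#' @param regions A [region_set()].
#' @param tracks Named list of [open_track()] results (names become feature
#'   labels).
#' @param cfg A `resolution_config` matching the region kind.
#' @return A `feature_matrix`: `n_regions x n_tracks` matrix with feature
#'   labels as column names and attribute `region_ids`.
#' @export
feature_matrix_1d <- function(regions, tracks, cfg) {
  stopifnot(inherits(regions, "region_set"), length(tracks) >= 1L)
  frames <- if (cfg$kind == "point") point_frames(regions, cfg)
            else interval_frames(regions, cfg)
  labels <- names(tracks) %||% paste0("feature", seq_along(tracks))
  cols <- lapply(seq_along(tracks), function(j) {
    stk <- extract_1d(tracks[[j]], frames)
    v <- suppressWarnings(rowMeans(stk, na.rm = TRUE))
    if (all(!is.finite(v))) {
      stop("track '", labels[j], "' has no signal over any region")
    }
    v
  })
  fm <- do.call(cbind, cols)
  colnames(fm) <- labels
  new_feature_matrix(fm, frames$region_ids)
}

new_feature_matrix <- function(values, region_ids) {
  structure(values, region_ids = region_ids,
            class = c("feature_matrix", class(values)))
}

#' Smoothing parameters for 2D pixel features
#'
#' For a quadratic snippet of side `m` bins downsampled to side `f`, the
#' interpolation factor is `I = floor(m / f)`, the Gaussian kernel size
#' `K = floor((I + 1) / 2)` and its standard deviation `sigma = 4K + 1`.
#' When `m < f` (`I = 0`) no smoothing applies and the snippet is upsampled
#' instead.
#'
#' @param m Snippet side length in bins.
#' @param f Target side length (default 10).
#' @return List with `m`, `f`, `I`, `K`, `sigma` (class `smoothing_params`).
#' @examples
#' smoothing_params(100)  # I = 10, K = 5, sigma = 21
#' smoothing_params(50)   # I = 5,  K = 3, sigma = 13
#' @export
smoothing_params <- function(m, f = 10L) {
  stopifnot(m >= 1, f >= 1)
  I <- as.integer(m) %/% as.integer(f)
  K <- (I + 1L) %/% 2L
  structure(list(m = as.integer(m), f = as.integer(f), I = as.integer(I),
                 K = as.integer(K), sigma = if (I >= 1L) 4L * K + 1L else NA_integer_),
            class = "smoothing_params")
}

# reflect-101 index map: 1 2 3 4 -> pad left gives 3 2 | 1 2 3 4
reflect_index <- function(i, m) {
  if (m == 1L) return(rep(1L, length(i)))
  p <- 2L * (m - 1L)
  i <- ((i - 1L) %% p + p) %% p + 1L
  ifelse(i > m, p + 2L - i, i)
}

# separable Gaussian smoothing with a K-tap truncated kernel, reflect padding
gaussian_smooth <- function(mat, K, sigma) {
  if (K <= 1L) return(mat)
  off <- seq_len(K) - 1L - (K %/% 2L)  # integer taps; asymmetric for even K
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  conv1 <- function(x) {  # smooth along rows of a matrix
    n <- ncol(x)
    out <- matrix(0, nrow(x), n)
    for (t in seq_along(off)) {
      idx <- reflect_index(seq_len(n) + off[t], n)
      out <- out + w[t] * x[, idx, drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(mat))))
}

# block means with near-equal contiguous blocks (sizes differ by at most 1)
block_downsample <- function(mat, f) {
  m <- nrow(mat)
  grp <- rep(seq_len(f), times = diff(round(seq(0, m, length.out = f + 1L))))
  sums <- t(rowsum(t(rowsum(mat, grp)), grp))  # block sums (rows x cols)
  sums / outer(tabulate(grp, f), tabulate(grp, f))
}

nearest_upsample <- function(mat, f) {
  m <- nrow(mat)
  idx <- floor((seq_len(f) - 1L) * m / f) + 1L
  mat[idx, idx, drop = FALSE]
}

#' Pixel features of 2D snippets
#'
#' Converts each square contact snippet into a flat feature row: Gaussian
#' smoothing with the [smoothing_params()] kernel (reflect padding), block
#' resampling to `f x f`, then row-major flattening to `f^2` values (100 at
#' the default). Snippets smaller than `f` are upsampled (nearest neighbour)
#' without smoothing. `NaN` cells are imputed as 0 before smoothing; rows
#' whose snippet is more than half `NaN` are excluded and reported via
#' attributes `excluded_ids` and `nan_fraction`.
#'
#' @param stack A 2D `snippet_stack` (snippet sides may vary per region, in
#'   which case parameters are computed per snippet).
#' @param f Target side length (default 10).
#' @return A `feature_matrix` of `f^2` columns.
#' @export
pixel_features_2d <- function(stack, f = 10L) {
  stopifnot(inherits(stack, "snippet_stack"), is_stack_2d(stack))
  n <- dim(stack)[1]
  m <- dim(stack)[2]
  sp <- smoothing_params(m, f)
  nan_frac <- numeric(n)
  rows <- matrix(NA_real_, n, f * f)
  for (r in seq_len(n)) {
    snip <- stack[r, , ]
    nan_frac[r] <- mean(is.na(snip))
    if (nan_frac[r] > 0.5) next
    snip[is.na(snip)] <- 0
    red <- if (sp$I >= 1L) {
      block_downsample(gaussian_smooth(snip, sp$K, sp$sigma), f)
    } else {
      nearest_upsample(snip, f)
    }
    rows[r, ] <- as.vector(t(red))  # row-major flatten
  }
  keep <- nan_frac <= 0.5
  fm <- new_feature_matrix(rows[keep, , drop = FALSE],
                           stack_region_ids(stack)[keep])
  colnames(fm) <- paste0("px", seq_len(f * f))
  attr(fm, "excluded_ids") <- stack_region_ids(stack)[!keep]
  attr(fm, "nan_fraction") <- nan_frac
  fm
}

#' Embed regions and cluster them
#'
#' Embeds the feature matrix into 2D with UMAP (library defaults, seeded,
#' single-threaded for reproducibility) and clusters the regions with k-means
#' — on the original high-dimensional feature rows, not the 2D coordinates,
#' so groups reflect similarity of the full multi-dimensional feature
#' vectors. Rows with any non-finite value are excluded beforehand and
#' reported. Features are used unscaled by default; `standardize = TRUE`
#' z-scores each feature first.
#'
#' @param fm A `feature_matrix`.
#' @param k Number of clusters (presets in the original interface: 10 or 20).
#' @param seed Integer seed controlling both UMAP and k-means.
#' @param standardize Z-score features before embedding/clustering.
#' @return An `embedding_result`: `coords` (n x 2), `labels` (1..k per
#'   retained region), `cluster_summaries` (k x m mean feature rows),
#'   `intensity` (per-cluster min-max normalized feature table, see
#'   [cluster_intensity()]), `region_ids`, `excluded_ids`, `seed`.
#' @export
embed_and_cluster <- function(fm, k = 10L, seed = 1L, standardize = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  ids <- attr(fm, "region_ids")
  X <- unclass(fm)
  finite <- apply(is.finite(X), 1L, all)
  X <- X[finite, , drop = FALSE]
  n <- nrow(X)
  if (k < 2L || n <= k) stop("need 2 <= k < n retained regions (n = ", n, ")")
  Xc <- if (standardize) {
    sd0 <- apply(X, 2L, stats::sd)
    scale(X, scale = ifelse(sd0 > 0, sd0, 1))
  } else X
  coords <- with_seed(seed, uwot::umap(Xc, n_neighbors = min(15L, n - 1L),
                                       n_threads = 1L, n_sgd_threads = 0L))
  km <- with_seed(seed + 1L, stats::kmeans(Xc, centers = k, nstart = 10L,
                                           iter.max = 100L))
  labels <- km$cluster
  summaries <- rowsum(X, labels) / as.vector(table(factor(labels, levels = sort(unique(labels)))))
  structure(list(coords = coords, labels = labels,
                 cluster_summaries = summaries,
                 intensity = cluster_intensity(new_feature_matrix(X, ids[finite]), labels),
                 region_ids = ids[finite], excluded_ids = ids[!finite],
                 k = k, seed = seed),
            class = "embedding_result")
}

#' Normalized per-cluster feature intensities
#'
#' Raw value: mean of each feature within each cluster. Normalized value:
#' per-feature min-max across clusters, so the weakest cluster maps to 0 and
#' the strongest to 1; a feature constant across clusters maps to 0.5 by
#' convention.
#'
#' @param fm A `feature_matrix` (rows aligned with `labels`).
#' @param labels Integer cluster label per row.
#' @return List with matrices `raw` and `normalized` (clusters x features).
#' @export
cluster_intensity <- function(fm, labels) {
  X <- unclass(fm)
  stopifnot(nrow(X) == length(labels))
  lv <- sort(unique(labels))
  raw <- rowsum(X, labels) / as.vector(table(factor(labels, levels = lv)))
  rng_min <- apply(raw, 2L, min)
  rng_max <- apply(raw, 2L, max)
  span <- rng_max - rng_min
  normalized <- sweep(raw, 2L, rng_min)
  normalized <- sweep(normalized, 2L, ifelse(span > 0, span, 1), `/`)
  normalized[, span == 0] <- 0.5
  list(raw = raw, normalized = normalized)
}

#' Create a sub-region-set from chosen clusters
#'
#' Selects the records whose cluster label is in `chosen`, preserving the
#' original record order — the route from an embedding back to a named,
#' exportable region set.
#'
#' @param regions The [region_set()] the embedding was computed on.
#' @param result An `embedding_result` (or an integer label vector aligned
#'   with `region_ids`).
#' @param chosen Non-empty set of cluster ids.
#' @param name Name for the new region set (stored in the `name` column).
#' @return A [region_set()] of the selected records.
#' @export
subset_from_clusters <- function(regions, result, chosen, name = "cluster_subset") {
  stopifnot(inherits(regions, "region_set"), length(chosen) >= 1L)
  if (inherits(result, "embedding_result")) {
    labels <- result$labels
    ids <- result$region_ids
  } else {
    labels <- result
    ids <- seq_along(labels)
  }
  empty <- setdiff(chosen, labels)
  if (length(empty)) warning("chosen cluster(s) with zero members: ",
                             paste(empty, collapse = ", "))
  sel <- sort(ids[labels %in% chosen])
  out <- as.data.frame(regions)[sel, , drop = FALSE]
  out$name <- name
  region_set(out, region_assembly(regions), region_kind(regions))
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("<embedding_result>", length(x$labels), "regions,", x$k,
      "clusters, seed", x$seed, "\n")
  invisible(x)
}
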