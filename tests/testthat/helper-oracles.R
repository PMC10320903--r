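# Shared fixtures and independent brute-force oracles.

toy_assembly <- function(sizes = c(chr1 = 1e6)) {
  genome_assembly("toy", sizes)
}

toy_regions <- function(assembly, chrom, start, end, kind = "point",
                        strand = NULL) {
  df <- data.frame(chrom = chrom, start = start, end = end)
  if (!is.null(strand)) df$strand <- strand
  region_set(df, assembly, kind)
}

# write a text-dialect track from an interval table and open it
toy_track <- function(intervals, assembly = NULL, dir = tempdir()) {
  path <- tempfile("track", tmpdir = dir, fileext = ".txt")
  write_track_text(intervals, path,
                   chrom_sizes = if (!is.null(assembly)) assembly$chrom_sizes)
  open_track(path, assembly)
}

# random non-overlapping step intervals on one chromosome
random_intervals <- function(chrom, len, n_steps = 20) {
  cuts <- sort(sample.int(len - 1, n_steps))
  edges <- c(0, cuts, len)
  covered <- runif(length(edges) - 1) < 0.7
  data.frame(chrom = chrom,
             start = edges[-length(edges)][covered],
             end = edges[-1][covered],
             value = round(runif(sum(covered), 0, 10), 3))
}

# ORACLE: per-basepair mean over one bin; uncovered bp = 0, off-chromosome NaN
oracle_bin_mean <- function(intervals, chrom, a, b, chrom_len) {
  if (a < 0 || b > chrom_len) return(NaN)
  bp <- seq.int(a, b - 1)
  val <- numeric(length(bp))
  iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(iv))) {
    hit <- bp >= iv$start[r] & bp < iv$end[r]
    val[hit] <- iv$value[r]
  }
  mean(val)
}

oracle_extract_1d <- function(intervals, frames, assembly) {
  edges <- frame_edges(frames)
  out <- matrix(NaN, length(frames$chrom), frames$n_bins)
  for (r in seq_along(frames$chrom)) {
    len <- chrom_length(assembly, frames$chrom[r])
    for (j in seq_len(frames$n_bins)) {
      out[r, j] <- oracle_bin_mean(intervals, frames$chrom[r],
                                   edges[r, j], edges[r, j + 1], len)
    }
  }
  out
}

# ORACLE: dense symmetric contact matrix for one chromosome
oracle_dense_matrix <- function(pixels, chrom, n_bins) {
  m <- matrix(0, n_bins, n_bins)
  px <- pixels[pixels$chrom == chrom, , drop = FALSE]
  for (r in seq_len(nrow(px))) {
    m[px$i[r] + 1, px$j[r] + 1] <- m[px$i[r] + 1, px$j[r] + 1] + px$value[r]
    if (px$i[r] != px$j[r]) {
      m[px$j[r] + 1, px$i[r] + 1] <- m[px$j[r] + 1, px$i[r] + 1] + px$value[r]
    }
  }
  m
}

# ORACLE: slice the dense matrix for a query window, NaN outside chromosome
oracle_query_contacts <- function(pixels, chrom, start, end, binsize, chrom_len) {
  nb <- ceiling(chrom_len / binsize)
  dense <- oracle_dense_matrix(pixels, chrom, nb)
  q <- start / binsize + seq_len((end - start) / binsize) - 1
  out <- matrix(NaN, length(q), length(q))
  ok <- q >= 0 & q < nb
  out[ok, ok] <- dense[q[ok] + 1, q[ok] + 1]
  out
}

# ORACLE: exhaustive per-universe-bin membership contingency table
oracle_contingency <- function(target, query, universe) {
  asm <- universe$assembly
  b <- universe$binsize
  a <- bb <- cc <- d <- 0L
  for (ch in names(asm$chrom_sizes)) {
    len <- asm$chrom_sizes[[ch]]
    for (i in seq_len(ceiling(len / b)) - 1L) {
      s <- i * b; e <- min((i + 1) * b, len)
      olap <- function(df) any(df$chrom == ch & df$start < e & df$end > s &
                                 pmax(df$start, s) < pmin(df$end, e))
      in_t <- nrow(target) > 0 && olap(target)
      in_q <- nrow(query) > 0 && olap(query)
      if (in_t && in_q) a <- a + 1L
      else if (!in_t && in_q) bb <- bb + 1L
      else if (in_t && !in_q) cc <- cc + 1L
      else d <- d + 1L
    }
  }
  list(a = a, b = bb, c = cc, d = d)
}

# ORACLE: full 2D Gaussian convolution (outer-product kernel, reflect-101)
oracle_gaussian_smooth <- function(mat, K, sigma) {
  if (K <= 1) return(mat)
  off <- seq_len(K) - 1 - (K %/% 2)
  w <- exp(-off^2 / (2 * sigma^2)); w <- w / sum(w)
  kern <- outer(w, w)
  m <- nrow(mat); n <- ncol(mat)
  refl <- function(i, mm) {
    while (any(i < 1 | i > mm)) {
      i[i < 1] <- 2 - i[i < 1]
      i[i > mm] <- 2 * mm - i[i > mm]
    }
    i
  }
  out <- matrix(0, m, n)
  for (r in seq_len(m)) for (s in seq_len(n)) {
    acc <- 0
    for (u in seq_along(off)) for (v in seq_along(off)) {
      acc <- acc + kern[u, v] * mat[refl(r + off[u], m), refl(s + off[v], n)]
    }
    out[r, s] <- acc
  }
  out
}

oracle_block_downsample <- function(mat, f) {
  m <- nrow(mat)
  bounds <- round(seq(0, m, length.out = f + 1))
  out <- matrix(0, f, f)
  for (r in seq_len(f)) for (s in seq_len(f)) {
    out[r, s] <- mean(mat[(bounds[r] + 1):bounds[r + 1],
                          (bounds[s] + 1):bounds[s + 1]])
  }
  out
}

# majority-map cluster purity against hidden subtype labels
cluster_purity <- function(labels, truth) {
  tab <- table(labels, truth)
  sum(apply(tab, 1, max)) / sum(tab)
}
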