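test_that("extract_1d fills rows from frames, NaNs out-of-bounds bins", {
  asm <- toy_assembly(c(chr1 = 1e5))
  tr <- toy_track(data.frame(chrom = "chr1", start = 0, end = 1e5, value = 3), asm)
  rs <- toy_regions(asm, rep("chr1", 5), seq(2e4, 6e4, by = 1e4) - 500,
                    seq(2e4, 6e4, by = 1e4) + 500)
  st <- extract_1d(tr, point_frames(rs, point_config(4000, 1000)))
  expect_equal(dim(st), c(5L, 8L))
  expect_true(all(st == 3))

  # frame overlapping chromosome start: leading NaN bins
  rs2 <- toy_regions(asm, "chr1", 1500, 2500)
  st2 <- extract_1d(tr, point_frames(rs2, point_config(4000, 1000)))
  expect_true(all(is.nan(st2[1, 1:2])))
  expect_true(all(st2[1, 3:8] == 3))
})

test_that("extract_1d matches the per-bp oracle on random tracks and frames", {
  asm <- toy_assembly(c(chr1 = 2000))
  for (seed in 1:15) {
    set.seed(seed)
    iv <- random_intervals("chr1", 2000)
    tr <- toy_track(iv, asm)
    anchors <- sample(seq(100, 1900, by = 10), 4)
    rs <- toy_regions(asm, rep("chr1", 4), anchors - 5, anchors + 5)
    fr <- point_frames(rs, point_config(200, 50))
    expect_equal(unclass(extract_1d(tr, fr)),
                 oracle_extract_1d(iv, fr, asm),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("minus-strand rows are reversed only when asked", {
  asm <- toy_assembly(c(chr1 = 1e4))
  tr <- toy_track(data.frame(chrom = "chr1", start = c(0, 5000),
                             end = c(5000, 1e4), value = c(1, 9)), asm)
  rs <- toy_regions(asm, c("chr1", "chr1"), c(4500, 4500), c(5500, 5500),
                    strand = c("+", "-"))
  fr <- point_frames(rs, point_config(2000, 1000))
  st <- extract_1d(tr, fr)
  expect_equal(st[1, ], st[2, ])
  stf <- extract_1d(tr, fr, flip_minus_strand = TRUE)
  expect_equal(stf[2, ], rev(st[2, ]))
})

test_that("aggregate_1d is a NaN-ignoring column mean", {
  st <- regionstack:::new_snippet_stack(rbind(c(1, 2), c(3, 4)), 1:2)
  expect_equal(as.numeric(aggregate_1d(st)), c(2, 3))
  st2 <- regionstack:::new_snippet_stack(rbind(c(1, NaN), c(3, 4)), 1:2)
  expect_equal(as.numeric(aggregate_1d(st2)), c(2, 4))
  st3 <- regionstack:::new_snippet_stack(rbind(c(1, NaN), c(3, NaN)), 1:2)
  expect_true(is.nan(aggregate_1d(st3)[2]))
  expect_error(aggregate_1d(regionstack:::new_snippet_stack(
    matrix(0, 0, 3), integer())), "empty")
})

test_that("aggregate_1d matches a naive column loop on random stacks", {
  set.seed(11)
  vals <- matrix(rnorm(200), 20, 10)
  vals[sample(200, 30)] <- NaN
  st <- regionstack:::new_snippet_stack(vals, 1:20)
  want <- vapply(1:10, function(j) {
    v <- vals[, j][!is.na(vals[, j])]
    if (length(v)) mean(v) else NaN
  }, 0)
  expect_equal(as.numeric(aggregate_1d(st)), want, tolerance = 1e-12)
})

test_that("extract_2d slices snippets that match the dense oracle", {
  len <- 4000; b <- 100
  asm <- toy_assembly(c(chr1 = len))
  for (seed in 1:10) {
    set.seed(seed)
    nb <- len / b
    ij <- t(apply(matrix(sample.int(nb, 60, replace = TRUE) - 1, ncol = 2), 1, sort))
    px <- data.frame(chrom = "chr1", i = ij[, 1], j = ij[, 2], value = rpois(30, 4))
    px <- px[!duplicated(px[, c("i", "j")]), ]
    path <- tempfile(fileext = ".txt")
    write_contacts_text(px, path, b, c(chr1 = len))
    cs <- open_contacts(path)
    anchors <- sample(seq(0, len, by = b), 3)  # grid-aligned anchors
    rs <- toy_regions(asm, rep("chr1", 3), pmax(anchors - 50, 0),
                      pmin(anchors + 50, len))
    fr <- point_frames(rs, point_config(300, 100))
    st <- extract_2d(cs, fr)
    for (r in 1:3) {
      c0 <- floor((rs$start[r] + rs$end[r]) / 2)
      q0 <- round((c0 - 300) / b) * b  # extraction snaps to the store grid
      want <- oracle_query_contacts(px, "chr1", q0, q0 + 600, b, len)
      expect_equal(st[r, , ], want)
    }
  }
})

test_that("aggregate_2d averages pixel-wise, NaN-ignoring, and keeps symmetry", {
  a1 <- rbind(c(0, 2), c(2, 0)); a2 <- rbind(c(2, 0), c(0, 2))
  arr <- array(NaN, c(2, 2, 2)); arr[1, , ] <- a1; arr[2, , ] <- a2
  st <- regionstack:::new_snippet_stack(arr, 1:2)
  expect_equal(unclass(aggregate_2d(st)), matrix(1, 2, 2), ignore_attr = TRUE)

  # all-NaN snippet excluded per pixel, not per snippet
  arr3 <- array(NaN, c(3, 2, 2)); arr3[1, , ] <- a1; arr3[2, , ] <- a2
  st3 <- regionstack:::new_snippet_stack(arr3, 1:3)
  expect_equal(unclass(aggregate_2d(st3)), matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(unclass(attr(aggregate_2d(st3), "valid_count")),
               matrix(2, 2, 2), ignore_attr = TRUE)

  # random stacks vs triple loop oracle
  set.seed(5)
  arr4 <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  arr4[sample(36, 6)] <- NaN
  st4 <- regionstack:::new_snippet_stack(arr4, 1:4)
  want <- matrix(0, 3, 3)
  for (j in 1:3) for (k in 1:3) {
    v <- arr4[, j, k][!is.na(arr4[, j, k])]
    want[j, k] <- if (length(v)) mean(v) else NaN
  }
  expect_equal(unclass(aggregate_2d(st4)), want, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("symmetric stores aggregate to symmetric maps", {
  cfg <- synth_config(seed = 8, n_regions = 30)
  asm <- synth_genome(cfg)
  rs <- synth_regions(cfg, asm)
  cs <- synth_contacts(cfg, asm, rs)
  agg <- aggregate_2d(extract_2d(cs, point_frames(rs, point_config(50000, 10000))))
  expect_lt(max(abs(agg - t(agg)), na.rm = TRUE), 1e-9)
})

test_that("planted coverage peaks are recovered at the frame center", {
  cfg <- synth_config(seed = 14, n_regions = 200)
  asm <- synth_genome(cfg)
  rs <- synth_regions(cfg, asm)
  tr <- synth_track(cfg, asm, rs, c(active = 1, repressed = 1))
  prof <- aggregate_1d(extract_1d(tr, point_frames(rs, point_config(50000, 2000))))
  # anchor sits between bins 25 and 26 of 50
  expect_lte(abs(which.max(prof) - 25.5), 1.5)
})

test_that("planted insulation depresses cross-quadrant contacts; null does not", {
  cfg <- synth_config(seed = 19, n_regions = 100, stripe_strength = 0,
                      insulation_strength = 0.6)
  asm <- synth_genome(cfg)
  rs <- synth_regions(cfg, asm)
  both <- c(active = 1, repressed = 1)
  fr <- point_frames(rs, point_config(50000, 10000))
  qc <- quadrant_contrast(aggregate_2d(extract_2d(synth_contacts(cfg, asm, rs, both), fr)))
  expect_lt(qc$cross, qc$within)
  cfg0 <- synth_config(seed = 19, n_regions = 100, stripe_strength = 0,
                       insulation_strength = 0)
  qc0 <- quadrant_contrast(aggregate_2d(extract_2d(synth_contacts(cfg0, asm, rs, both), fr)))
  expect_lt(abs(log(qc0$ratio)), 0.1)
})

test_that("stacked profiles cap rows, preserve under-cap stacks and seed the subsample", {
  vals <- matrix(rnorm(2500 * 4), 2500, 4)
  st <- regionstack:::new_snippet_stack(vals, 1:2500)
  res <- stacked_profiles(st, max_rows = 1000, seed = 3)
  expect_equal(nrow(res$matrix), 1000L)
  expect_identical(res$order$region_ids,
                   stacked_profiles(st, max_rows = 1000, seed = 3)$order$region_ids)
  st5 <- regionstack:::new_snippet_stack(vals[1:500, ], 1:500)
  expect_equal(nrow(stacked_profiles(st5, seed = 1)$matrix), 500L)
  expect_error(stacked_profiles(st, max_rows = 1000), "seed")
})

test_that("sort orders rank by statistic with stable ties and NaN rows last", {
  st <- regionstack:::new_snippet_stack(rbind(c(5, 5), c(1, 1), c(3, 3)), 1:3)
  expect_equal(sort_order_by_track(st, "row_mean", descending = TRUE)$region_ids,
               c(1L, 3L, 2L))
  st2 <- regionstack:::new_snippet_stack(rbind(c(2, 2), c(9, 9), c(4, 4)), 1:3)
  expect_equal(sort_order_by_track(st2, "row_mean", descending = TRUE)$region_ids,
               c(2L, 3L, 1L))
  ties <- regionstack:::new_snippet_stack(matrix(1, 4, 3), 1:4)
  expect_equal(sort_order_by_track(ties, "row_mean")$region_ids, 1:4)
  nanrow <- regionstack:::new_snippet_stack(rbind(c(NaN, NaN), c(1, 1)), 1:2)
  expect_equal(sort_order_by_track(nanrow, "row_mean")$region_ids, c(2L, 1L))
})

test_that("applying a sort order twice is idempotent and aggregation is order-invariant", {
  set.seed(23)
  vals <- matrix(rnorm(40), 10, 4)
  st <- regionstack:::new_snippet_stack(vals, 1:10)
  ord <- sort_order_by_track(st, "row_mean", descending = TRUE)
  once <- apply_sort_order(st, ord)
  twice <- apply_sort_order(once, ord)
  expect_equal(unclass(once), unclass(twice), ignore_attr = TRUE)
  expect_equal(as.numeric(aggregate_1d(once)), as.numeric(aggregate_1d(st)))
  bad <- regionstack:::new_sort_order(c(1L, 99L))
  expect_error(apply_sort_order(st, bad), "absent")
})

test_that("a coupled sort order reorders a second stack consistently", {
  set.seed(31)
  a <- regionstack:::new_snippet_stack(matrix(rnorm(60), 20, 3), 1:20)
  b <- regionstack:::new_snippet_stack(matrix(rnorm(60), 20, 3), 1:20)
  ord <- sort_order_by_track(a, "row_mean", descending = TRUE)
  b_sorted <- apply_sort_order(b, ord)
  expect_equal(attr(b_sorted, "region_ids"), ord$region_ids)
  expect_equal(unclass(b_sorted), unclass(b)[ord$region_ids, ],
               ignore_attr = TRUE)
})
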