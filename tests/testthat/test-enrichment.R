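test_that("universe tiling counts whole and partial bins", {
  expect_equal(make_universe(toy_assembly(c(chr1 = 10000)), 1000)$total_bins, 10)
  expect_equal(make_universe(toy_assembly(c(chr1 = 10500)), 1000)$total_bins, 11)
  expect_equal(make_universe(toy_assembly(c(chr1 = 10000, chr2 = 5000)),
                             1000)$total_bins, 15)
})

test_that("bin_targets emits one interval per in-bounds region", {
  asm <- toy_assembly(c(chr1 = 1e5))
  rs <- toy_regions(asm, rep("chr1", 5), seq(1e4, 5e4, by = 1e4) - 500,
                    seq(1e4, 5e4, by = 1e4) + 500)
  fr <- point_frames(rs, point_config(3000, 1000))
  tg <- bin_targets(fr, 1)
  expect_equal(nrow(tg), 5L)
  expect_equal(tg$end - tg$start, rep(1000, 5))
  # region near chromosome start loses its leading bin
  rs2 <- toy_regions(asm, "chr1", 1500, 2500)
  fr2 <- point_frames(rs2, point_config(3000, 1000))
  tg2 <- bin_targets(fr2, 1)
  expect_equal(nrow(tg2), 0L)
  expect_equal(attr(tg2, "n_dropped"), 1L)
})

test_that("contingency reproduces the hand-enumerated 10-bin example", {
  asm <- toy_assembly(c(chr1 = 10000))
  u <- make_universe(asm, 1000)
  target <- data.frame(chrom = "chr1", start = 0, end = 4000)      # bins 0..3
  query <- toy_regions(asm, c("chr1", "chr1"), c(0, 4000), c(3000, 6000),
                       kind = "interval")                          # bins 0,1,2 + 4,5
  ct <- contingency(target, query, u)
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(3L, 2L, 1L, 4L))
  expect_equal(odds_ratio(ct), 6.0)
  expect_equal(ct$a + ct$b + ct$c + ct$d, u$total_bins)
})

test_that("odds ratio applies the Haldane correction and independence gives 1", {
  tbl <- function(a, b, c, d) structure(list(a = a, b = b, c = c, d = d,
                                             total_bins = a + b + c + d),
                                        class = "contingency_table")
  expect_equal(odds_ratio(tbl(0, 0, 5, 5)), 1.0)          # empty query neutral
  expect_true(is.nan(odds_ratio(tbl(0, 0, 5, 5), "none")))
  expect_equal(odds_ratio(tbl(2, 4, 3, 6)), 1.0)          # a/c = b/d
  expect_true(is.nan(odds_ratio(tbl(0, 5, 0, 5))))        # empty target margin
  # query covering every universe bin: c = d = 0
  asm <- toy_assembly(c(chr1 = 5000))
  u <- make_universe(asm, 1000)
  ct <- contingency(data.frame(chrom = "chr1", start = 0, end = 2000),
                    toy_regions(asm, "chr1", 0, 5000, kind = "interval"), u)
  expect_equal(c(ct$c, ct$d), c(0L, 0L))
  expect_true(is.nan(odds_ratio(ct, "none")))
  expect_true(is.finite(odds_ratio(ct, "haldane")))
})

test_that("contingency matches exhaustive enumeration on random toy genomes", {
  for (seed in 1:40) {
    set.seed(seed)
    sizes <- c(chrA = sample(20:90, 1) * 10, chrB = sample(20:90, 1) * 10)
    asm <- toy_assembly(sizes)
    u <- make_universe(asm, 10)
    rand_iv <- function(n) {
      ch <- sample(names(sizes), n, replace = TRUE)
      s <- vapply(ch, function(x) sample.int(sizes[[x]] - 15, 1), 0)
      data.frame(chrom = ch, start = s,
                 end = pmin(s + sample(5:40, n, replace = TRUE), sizes[ch]))
    }
    target <- rand_iv(5)
    qdf <- rand_iv(8)
    query <- region_set(qdf, asm, "interval")
    got <- contingency(target, query, u)
    want <- oracle_contingency(target, qdf, u)
    expect_identical(c(got$a, got$b, got$c, got$d),
                     c(want$a, want$b, want$c, want$d))
    # OR matches the closed formula under Haldane handling
    cells <- c(got$a, got$b, got$c, got$d)
    if (any(cells == 0)) cells <- cells + 0.5
    if (got$a + got$c > 0) {
      expect_equal(odds_ratio(got), (cells[1] * cells[4]) / (cells[2] * cells[3]))
    }
  }
})

test_that("odds ratios are invariant to record and feature order", {
  asm <- toy_assembly(c(chr1 = 2000))
  u <- make_universe(asm, 100)
  set.seed(3)
  qdf <- data.frame(chrom = "chr1", start = seq(0, 1800, by = 200),
                    end = seq(0, 1800, by = 200) + sample(50:150, 10, replace = TRUE))
  q1 <- region_set(qdf, asm, "interval")
  q2 <- region_set(qdf[sample(nrow(qdf)), ], asm, "interval")
  target <- data.frame(chrom = "chr1", start = c(0, 600), end = c(200, 800))
  expect_equal(odds_ratio(contingency(target, q1, u)),
               odds_ratio(contingency(target, q2, u)))
})

test_that("snapped frames put each target on exactly one universe bin", {
  cfg <- synth_config(seed = 3, n_regions = 50)
  asm <- synth_genome(cfg)
  rs <- snap_regions_to_bins(synth_regions(cfg, asm), 1000)
  u <- make_universe(asm, 1000)
  fr <- point_frames(rs, point_config(3000, 1000))
  for (bi in seq_len(fr$n_bins)) {
    tg <- bin_targets(fr, bi)
    expect_true(all(tg$start %% 1000 == 0))
    expect_true(all(tg$end - tg$start == 1000))
    # one universe bin per target interval
    expect_equal(length(regionstack:::universe_bin_ids(u, tg$chrom, tg$start,
                                                       tg$end)),
                 length(unique(paste(tg$chrom, tg$start))))
  }
})

test_that("per-bin enrichment peaks at the planted center bin and ranks features", {
  cfg <- synth_config(seed = 13, n_regions = 300)
  asm <- synth_genome(cfg)
  rs <- synth_regions(cfg, asm)
  u <- make_universe(asm, 1000)
  feats <- synth_feature_sets(cfg, rs, u, n_sets = 2)
  fr <- point_frames(snap_regions_to_bins(rs, 1000), point_config(3000, 1000))
  prof <- per_bin_enrichment(fr, feats, u)
  center <- 4L  # anchor bin of a 6-bin frame
  for (f in 1:2) {
    expect_equal(unname(which.max(prof$or[f, ])), center)
    expect_gt(prof$or[f, center], 10)
  }
  expect_equal(unique(prof$top_feature[center]),
               rownames(prof$or)[which.max(prof$or[, center])])
  rk <- rank_features(prof, center)
  expect_equal(rk$odds_ratio, sort(rk$odds_ratio, decreasing = TRUE))
  # counts always sum to the universe size
  expect_true(all(apply(prof$counts, c(1, 2), sum) == u$total_bins))
})

test_that("a uniformly random feature set is unenriched at every bin", {
  cfg <- synth_config(seed = 17, n_regions = 300, p_center = 0.3,
                      p_background = 0.3)
  asm <- synth_genome(cfg)
  rs <- synth_regions(cfg, asm)
  u <- make_universe(asm, 1000)
  feats <- synth_feature_sets(cfg, rs, u)
  prof <- per_bin_enrichment(point_frames(rs, point_config(3000, 1000)), feats, u)
  expect_true(all(prof$or > 0.7 & prof$or < 1.4))
})

test_that("odds ratio at the center bin grows with the planted overlap fraction", {
  ors <- vapply(c(0.2, 0.5, 0.8), function(p) {
    cfg <- synth_config(seed = 29, n_regions = 300, p_center = p,
                        p_background = 0.05)
    asm <- synth_genome(cfg)
    rs <- synth_regions(cfg, asm)
    u <- make_universe(asm, 1000)
    feats <- synth_feature_sets(cfg, rs, u)
    prof <- per_bin_enrichment(point_frames(snap_regions_to_bins(rs, 1000),
                                            point_config(1000, 1000)),
                               feats, u)
    prof$or[1, 2]
  }, 0)
  expect_true(all(diff(ors) > 0))
})

test_that("an empty target margin is reported as NaN downstream", {
  asm <- toy_assembly(c(chr1 = 1e4))
  rs <- toy_regions(asm, "chr1", 400, 600)  # frame entirely below 0 at bin 1
  fr <- point_frames(rs, point_config(3000, 1000))
  u <- make_universe(asm, 1000)
  feats <- list(f = toy_regions(asm, "chr1", 0, 1000, kind = "interval"))
  prof <- per_bin_enrichment(fr, feats, u)
  expect_true(is.nan(prof$or[1, 1]))
})
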