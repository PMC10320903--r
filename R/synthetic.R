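#' Synthetic study configuration
#'
#' One configuration object drives every synthetic generator, so a whole toy
#' study (genome, regions, tracks, contacts, feature sets) is a pure function
#' of the configuration and its seed. Defaults describe the reference
#' conditions used throughout the package's tests: a 2-chromosome 2 Mb toy
#' genome, 500 point regions, planted coverage peaks five noise standard
#' deviations high, Hi-C-like contacts with power-law distance decay plus
#' anchor stripes and insulation, and feature sets hitting region centers
#' with probability 0.8 against a 0.05 background.
#'
#' @param seed Integer master seed; each generator derives a fixed offset
#'   stream from it.
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param n_regions Number of regions to plant.
#' @param min_spacing Minimum distance between region anchors in bp.
#' @param interval_length_range Range (bp) for interval-kind region lengths,
#'   drawn log-uniformly.
#' @param peak_height Planted coverage peak amplitude (signal units).
#' @param peak_width Gaussian peak standard deviation in bp.
#' @param noise_sd Track background noise standard deviation.
#' @param track_step Step (bp) of the piecewise-constant synthetic track.
#' @param hic_binsize Contact-matrix bin size in bp.
#' @param hic_scale Expected contact count at distance 0.
#' @param decay_exponent Power-law distance-decay exponent `alpha` in
#'   `E[count] = hic_scale * (d + 1)^-alpha` (d in bins).
#' @param stripe_strength Multiplicative row/column enrichment at responsive
#'   anchors (0 = none).
#' @param insulation_strength Fractional depletion of contacts crossing a
#'   responsive anchor, in `[0, 1)` (0 = none).
#' @param p_center,p_background Inclusion probabilities for feature-set bins
#'   overlapping region centers vs all other universe bins.
#' @param mixture_fractions Named fractions of hidden region subtypes.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         chrom_sizes = c(synthA = 1e6, synthB = 1e6),
                         n_regions = 500L,
                         min_spacing = 2000,
                         interval_length_range = c(5000, 50000),
                         peak_height = 5,
                         peak_width = 5000,
                         noise_sd = 1,
                         track_step = 100,
                         hic_binsize = 10000,
                         hic_scale = 100,
                         decay_exponent = 1,
                         stripe_strength = 1,
                         insulation_strength = 0.6,
                         p_center = 0.8,
                         p_background = 0.05,
                         mixture_fractions = c(active = 0.5, repressed = 0.5)) {
  stopifnot(p_center >= 0, p_center <= 1, p_background >= 0, p_background <= 1,
            insulation_strength >= 0, insulation_strength < 1,
            stripe_strength >= 0, n_regions >= 1, min_spacing > 0,
            all(mixture_fractions >= 0), abs(sum(mixture_fractions) - 1) < 1e-9)
  if (length(chrom_sizes) == 0L) stop("config needs at least one chromosome")
  structure(as.list(environment()), class = "synth_config")
}

#' Synthetic genome assembly
#'
#' @param cfg A [synth_config()].
#' @param path Optional path; when given, a chrom.sizes file is written.
#' @return A [genome_assembly()]; deterministic for a fixed config.
#' @export
synth_genome <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  asm <- genome_assembly("synth", cfg$chrom_sizes)
  if (!is.null(path)) write_chrom_sizes(asm, path)
  asm
}

#' Synthetic region set with hidden subtypes
#'
#' Anchors are drawn uniformly from a grid of `min_spacing`-separated slots
#' (guaranteeing the minimum spacing) and each region is assigned a hidden
#' subtype per `mixture_fractions` — the ground truth that downstream
#' recovery tests (pileups, clustering, enrichment) try to rediscover.
#' Subtype labels are returned as attribute `subtypes` and optionally
#' written to a sidecar TSV, never into the BED name column.
#'
#' @param cfg A [synth_config()].
#' @param assembly A [genome_assembly()] (normally [synth_genome()]).
#' @param kind `"point"` (1 kb records around each anchor) or `"interval"`
#'   (lengths log-uniform in `interval_length_range`).
#' @param sidecar_path Optional path for a `name TAB subtype` TSV.
#' @return A [region_set()] with attribute `subtypes` (character vector).
#' @export
synth_regions <- function(cfg, assembly, kind = c("point", "interval"),
                          sidecar_path = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(assembly, "genome_assembly"))
  kind <- match.arg(kind)
  sp <- cfg$min_spacing
  sizes <- assembly$chrom_sizes
  # per-chromosome capacity with one spacing-wide margin at each end
  capacity <- pmax(floor((sizes - 2 * sp) / sp) + 1, 0)
  if (sum(capacity) < cfg$n_regions) {
    stop("genome too small for ", cfg$n_regions, " regions at spacing ", sp)
  }
  out <- with_seed(cfg$seed + 101L, {
    # allocate regions to chromosomes by length, capped by capacity
    n_ch <- stats::rmultinom(1, cfg$n_regions, sizes)[, 1]
    while (any(n_ch > capacity)) {
      over <- which(n_ch > capacity)[1]
      spare <- which(n_ch < capacity)
      move <- n_ch[over] - capacity[over]
      n_ch[over] <- capacity[over]
      n_ch[spare[1]] <- n_ch[spare[1]] + move
    }
    # uniform anchors with guaranteed spacing: order statistics + offsets
    anchors <- do.call(rbind, lapply(names(sizes)[n_ch > 0], function(ch) {
      n <- n_ch[[ch]]
      slack <- sizes[[ch]] - 2 * sp - (n - 1) * sp
      u <- sort(stats::runif(n, 0, slack))
      data.frame(chrom = ch, pos = floor(sp + u + (seq_len(n) - 1) * sp))
    }))
    subtypes <- sample(names(cfg$mixture_fractions), cfg$n_regions,
                       replace = TRUE, prob = cfg$mixture_fractions)
    if (kind == "point") {
      start <- anchors$pos - 500
      end <- anchors$pos + 500
    } else {
      lr <- log(cfg$interval_length_range)
      len <- round(exp(stats::runif(cfg$n_regions, lr[1], lr[2])))
      start <- anchors$pos
      end <- pmin(start + len, chrom_length(assembly, anchors$chrom))
    }
    list(df = data.frame(chrom = anchors$chrom, start = start, end = end,
                         name = sprintf("region_%04d", seq_len(cfg$n_regions))),
         subtypes = subtypes)
  })
  rs <- region_set(out$df, assembly, kind)
  attr(rs, "subtypes") <- out$subtypes
  if (!is.null(sidecar_path)) {
    utils::write.table(data.frame(name = out$df$name, subtype = out$subtypes),
                       sidecar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rs
}

#' Synthetic 1D coverage track with planted peaks
#'
#' Emulates a read-density (ChIP-seq-like) track: Gaussian background noise
#' clamped at zero plus Gaussian bumps of height
#' `peak_height * subtype_effects[subtype]` and sd `peak_width` at the
#' anchors of responsive subtypes. The track is piecewise constant at
#' `track_step` resolution.
#'
#' @param cfg A [synth_config()].
#' @param assembly A [genome_assembly()].
#' @param regions A [synth_regions()] result (needs attribute `subtypes`).
#' @param subtype_effects Named multiplier per subtype (0 = unresponsive).
#' @param path Optional output path; `.bw`/`.bigwig` writes bigWig via
#'   rtracklayer, anything else the plain-text dialect.
#' @param stream Integer offset added to the seed so several independent
#'   tracks can be drawn from one config.
#' @return A `signal_track`, queryable immediately.
#' @export
synth_track <- function(cfg, assembly, regions,
                        subtype_effects = c(active = 1, repressed = 0),
                        path = NULL, stream = 0L) {
  stopifnot(inherits(cfg, "synth_config"), inherits(regions, "region_set"))
  subtypes <- attr(regions, "subtypes")
  if (is.null(subtypes)) subtypes <- rep(names(subtype_effects)[1], nrow(regions))
  anchors <- region_anchors(regions)
  step <- cfg$track_step
  dt <- data.table::rbindlist(lapply(names(assembly$chrom_sizes), function(ch) {
    len <- assembly$chrom_sizes[[ch]]
    ns <- ceiling(len / step)
    mids <- (seq_len(ns) - 0.5) * step
    val <- with_seed(cfg$seed + 211L + stream * 1000L + match(ch, names(assembly$chrom_sizes)),
                     stats::rnorm(ns, 0, cfg$noise_sd))
    on_ch <- which(regions$chrom == ch)
    for (r in on_ch) {
      amp <- cfg$peak_height * (subtype_effects[subtypes[r]] %||% 0)
      if (is.na(amp) || amp == 0) next
      lo <- max(1L, floor((anchors[r] - 4 * cfg$peak_width) / step))
      hi <- min(ns, ceiling((anchors[r] + 4 * cfg$peak_width) / step))
      idx <- lo:hi
      val[idx] <- val[idx] +
        amp * exp(-(mids[idx] - anchors[r])^2 / (2 * cfg$peak_width^2))
    }
    data.table::data.table(chrom = ch, start = (seq_len(ns) - 1) * step,
                           end = pmin(seq_len(ns) * step, len),
                           value = pmax(0, val))
  }))
  if (!is.null(path)) {
    if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
      write_track_bigwig(dt, path, assembly)
    } else {
      write_track_text(dt, path, assembly$chrom_sizes)
    }
  }
  track_from_intervals(dt, assembly$chrom_sizes, path %||% "<synthetic>")
}

write_track_bigwig <- function(dt, path, assembly) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("writing bigWig requires the rtracklayer package")
  }
  gr <- GenomicRanges::GRanges(dt$chrom,
                               IRanges::IRanges(dt$start + 1, dt$end),
                               score = dt$value)
  GenomeInfoDb::seqlengths(gr) <- assembly$chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "BigWig")
  invisible(path)
}

#' Synthetic contact matrices with planted stripes and insulation
#'
#' Expected counts follow a power-law distance decay
#' `hic_scale * (d + 1)^-decay_exponent` (d in bins). At anchors of
#' responsive subtypes, the anchor row and column are multiplied by
#' `1 + stripe_strength * effect` (a stripe) and contacts crossing the
#' anchor by `1 - insulation_strength * effect` (insulation, the signature
#' of a domain boundary). Counts are Poisson-sampled and symmetric by
#' construction.
#'
#' @inheritParams synth_track
#' @param path Optional output path; `.cool` writes a cooler file, anything
#'   else the plain-text dialect.
#' @return A `contact_store` at `cfg$hic_binsize` resolution.
#' @export
synth_contacts <- function(cfg, assembly, regions,
                           subtype_effects = c(active = 1, repressed = 0),
                           path = NULL, stream = 0L) {
  stopifnot(inherits(cfg, "synth_config"), inherits(regions, "region_set"))
  subtypes <- attr(regions, "subtypes")
  if (is.null(subtypes)) subtypes <- rep(names(subtype_effects)[1], nrow(regions))
  b <- cfg$hic_binsize
  anchors <- region_anchors(regions)
  px <- data.table::rbindlist(lapply(names(assembly$chrom_sizes), function(ch) {
    len <- assembly$chrom_sizes[[ch]]
    nb <- as.integer(ceiling(len / b))
    d <- abs(outer(seq_len(nb), seq_len(nb), `-`))
    M <- cfg$hic_scale * (d + 1)^(-cfg$decay_exponent)
    on_ch <- which(regions$chrom == ch)
    for (r in on_ch) {
      eff <- subtype_effects[subtypes[r]] %||% 0
      if (is.na(eff) || eff == 0) next
      a <- floor(anchors[r] / b) + 1L
      if (a >= 1L && a <= nb && cfg$stripe_strength > 0) {
        s <- 1 + cfg$stripe_strength * eff
        M[a, ] <- M[a, ] * s
        M[, a] <- M[, a] * s
      }
      # deplete contacts across the bin boundary nearest the anchor
      ab <- round(anchors[r] / b)
      if (ab >= 1L && ab < nb && cfg$insulation_strength > 0) {
        dep <- 1 - cfg$insulation_strength * eff
        M[1:ab, (ab + 1L):nb] <- M[1:ab, (ab + 1L):nb] * dep
        M[(ab + 1L):nb, 1:ab] <- M[(ab + 1L):nb, 1:ab] * dep
      }
    }
    ut <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
    cnt <- with_seed(cfg$seed + 307L + stream * 1000L +
                       match(ch, names(assembly$chrom_sizes)),
                     stats::rpois(nrow(ut), M[ut]))
    keep <- cnt > 0
    data.table::data.table(chrom = ch, i = ut[keep, 1] - 1L,
                           j = ut[keep, 2] - 1L, value = as.numeric(cnt[keep]))
  }))
  if (!is.null(path)) {
    if (grepl("\\.m?cool$", path, ignore.case = TRUE)) {
      write_cool(px, path, b, assembly)
    } else {
      write_contacts_text(px, path, b, assembly$chrom_sizes)
    }
  }
  res <- list(list(binsize = b, chrom_len = assembly$chrom_sizes,
                   pixels = normalize_pixels(px), weights = NULL))
  names(res) <- format(b, scientific = FALSE)
  new_contact_store("memory", path %||% "<synthetic>", res)
}

#' Synthetic feature sets with planted positional enrichment
#'
#' Each feature set is a set of universe bins: bins overlapping a region
#' anchor are included with probability `p_center`, every other genome-wide
#' bin with probability `p_background`. At large n the center-bin odds ratio
#' approaches `(p_center / (1 - p_center)) / (p_background / (1 - p_background))`.
#'
#' @param cfg A [synth_config()].
#' @param regions A [region_set()] whose anchors carry the enrichment.
#' @param universe A [make_universe()] result.
#' @param n_sets Number of independent feature sets.
#' @param p_center,p_background Override the config probabilities.
#' @return Named list of [region_set()]s (interval kind, one record per
#'   included bin).
#' @export
synth_feature_sets <- function(cfg, regions, universe, n_sets = 1L,
                               p_center = cfg$p_center,
                               p_background = cfg$p_background) {
  stopifnot(inherits(cfg, "synth_config"), inherits(universe, "bin_universe"))
  anchors <- region_anchors(regions)
  center_ids <- universe_bin_ids(universe, regions$chrom, anchors, anchors + 1)
  asm <- universe$assembly
  b <- universe$binsize
  # global bin id -> genomic interval
  id_coords <- function(ids) {
    ch_idx <- findInterval(ids - 1, universe$offsets)
    ch <- names(universe$offsets)[ch_idx]
    i <- ids - 1 - universe$offsets[ch_idx]
    data.frame(chrom = ch, start = i * b,
               end = pmin((i + 1) * b, chrom_length(asm, ch)))
  }
  out <- lapply(seq_len(n_sets), function(s) {
    ids <- with_seed(cfg$seed + 401L + s, {
      all_ids <- seq_len(universe$total_bins)
      is_center <- all_ids %in% center_ids
      p <- ifelse(is_center, p_center, p_background)
      all_ids[stats::runif(universe$total_bins) < p]
    })
    region_set(id_coords(ids), asm, "interval")
  })
  names(out) <- sprintf("feature_%02d", seq_len(n_sets))
  out
}
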