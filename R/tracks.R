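#' Open a 1D signal track
#'
#' Returns a queryable coverage track. Two backends are auto-detected:
#' * **bigWig** (`.bw`, `.bigwig`, `.bigWig`) via rtracklayer, read-only;
#' * a **plain-text dialect** (bedGraph-like) for fully text-based pipelines:
#'   tab-separated `chrom  start  end  value` with 0-based half-open
#'   coordinates, optional `# chrom: <name> <length>` header lines declaring
#'   chromosome sizes, and `#` comments. Intervals on one chromosome must not
#'   overlap.
#'
#' Bin queries return the mean over covered basepairs, with basepairs not
#' covered by any interval counted as 0 (read-density semantics); bins with
#' any basepair outside `[0, chromosome length)` — or on a chromosome the
#' track knows nothing about — are `NaN`. For the text dialect without an
#' `assembly` or size headers, chromosome ends are unknown and only
#' negative coordinates are out of bounds.
#'
#' @param path Track file path.
#' @param assembly Optional [genome_assembly()] supplying chromosome lengths
#'   (overrides any sizes stored in the file).
#' @return A `signal_track` object.
#' @seealso [query_track()], [extract_1d()]
#' @export
open_track <- function(path, assembly = NULL) {
  if (!file.exists(path)) stop("track file not found: ", path)
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
    open_track_bigwig(path, assembly)
  } else {
    open_track_text(path, assembly)
  }
}

open_track_text <- function(path, assembly = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*chrom:", lines, value = TRUE)
  chrom_len <- numeric(0)
  if (length(hdr)) {
    parts <- strsplit(trimws(sub("^#\\s*chrom:", "", hdr)), "\\s+")
    chrom_len <- vapply(parts, function(p) as.numeric(p[2]), 0)
    names(chrom_len) <- vapply(parts, `[`, "", 1)
  }
  body <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))]
  if (length(body)) {
    dt <- data.table::fread(text = body, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "value"))
  } else {
    dt <- data.table::data.table(chrom = character(), start = numeric(),
                                 end = numeric(), value = numeric())
  }
  if (!is.null(assembly)) {
    stopifnot(inherits(assembly, "genome_assembly"))
    chrom_len <- assembly$chrom_sizes
  }
  track_from_intervals(dt, chrom_len, path)
}

# build a text-backend signal_track from an in-memory interval table
track_from_intervals <- function(dt, chrom_len = numeric(0), path = "<memory>") {
  dt <- data.table::as.data.table(dt)
  if (nrow(dt) && any(dt$start >= dt$end)) stop("track interval with start >= end")
  data.table::setorder(dt, chrom, start)
  by_chrom <- split(dt, by = "chrom")
  chroms <- lapply(by_chrom, function(d) {
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
      stop("overlapping intervals in track on chromosome ", d$chrom[1])
    }
    len <- d$end - d$start
    list(s = d$start, e = d$end, v = d$value,
         cum = c(0, cumsum(d$value * len))[seq_len(nrow(d))])
  })
  if (length(chrom_len) == 0L) {
    chrom_len <- rep(Inf, length(chroms))
    names(chrom_len) <- names(chroms)
  }
  unknown <- setdiff(names(chroms), names(chrom_len))
  if (length(unknown)) {
    stop("track intervals on chromosomes without a declared length: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(backend = "text", path = path, chroms = chroms,
                 chrom_len = chrom_len, cache = NULL),
            class = "signal_track")
}

open_track_bigwig <- function(path, assembly = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading bigWig requires the rtracklayer package")
  }
  bwf <- rtracklayer::BigWigFile(path)
  si <- rtracklayer::seqinfo(bwf)
  chrom_len <- as.numeric(GenomeInfoDb::seqlengths(si))
  names(chrom_len) <- GenomeInfoDb::seqnames(si)
  if (!is.null(assembly)) chrom_len <- assembly$chrom_sizes
  structure(list(backend = "bigwig", path = path, chroms = NULL,
                 chrom_len = chrom_len, cache = new.env(parent = emptyenv())),
            class = "signal_track")
}

# lazily materialize one bigWig chromosome into the text-backend form
track_chrom_data <- function(track, chrom) {
  if (track$backend == "text") return(track$chroms[[chrom]])
  if (!is.null(track$cache[[chrom]])) return(track$cache[[chrom]])
  len <- track$chrom_len[[chrom]]
  gr <- rtracklayer::import(rtracklayer::BigWigFile(track$path),
                            which = GenomicRanges::GRanges(
                              chrom, IRanges::IRanges(1, len)))
  d <- list(s = as.numeric(GenomicRanges::start(gr)) - 1,
            e = as.numeric(GenomicRanges::end(gr)),
            v = as.numeric(gr$score))
  d$cum <- c(0, cumsum(d$v * (d$e - d$s)))[seq_along(d$s)]
  track$cache[[chrom]] <- d
  d
}

# integral of the track value over [0, x) on one chromosome (absent = 0)
track_integral <- function(d, x) {
  if (is.null(d) || length(d$s) == 0L) return(rep(0, length(x)))
  idx <- findInterval(x, d$s)
  out <- numeric(length(x))
  pos <- idx > 0L
  i <- idx[pos]
  out[pos] <- d$cum[i] + d$v[i] * pmin(pmax(x[pos] - d$s[i], 0), d$e[i] - d$s[i])
  out
}

# core bin extraction against explicit (possibly unequal) edges
query_track_edges <- function(track, chrom, edges) {
  nb <- length(edges) - 1L
  len <- track$chrom_len[chrom]
  if (is.na(len)) return(rep(NaN, nb))
  d <- track_chrom_data(track, chrom)
  W <- track_integral(d, edges)
  vals <- diff(W) / diff(edges)
  vals[edges[-(nb + 1L)] < 0 | edges[-1L] > len] <- NaN
  vals
}

#' Query a signal track in bins
#'
#' Splits `[start, end)` into `n_bins` equal bins and returns the per-bin mean
#' signal (uncovered bp count as 0; out-of-chromosome bins are `NaN`).
#' Splitting a range into sub-queries and length-weighted averaging
#' reproduces the single-query values.
#'
#' @param track A [open_track()] result.
#' @param chrom Chromosome name.
#' @param start,end Query range in bp (0-based half-open); may extend outside
#'   the chromosome.
#' @param n_bins Number of equal bins.
#' @return Numeric vector of length `n_bins`.
#' @export
query_track <- function(track, chrom, start, end, n_bins) {
  stopifnot(inherits(track, "signal_track"), end > start, n_bins >= 1)
  query_track_edges(track, chrom, seq(start, end, length.out = n_bins + 1L))
}

#' Write a track in the plain-text dialect
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @param chrom_sizes Optional named vector written as `# chrom:` header lines.
#' @return `path`, invisibly.
#' @export
write_track_text <- function(intervals, path, chrom_sizes = NULL) {
  hdr <- character(0)
  if (!is.null(chrom_sizes)) {
    hdr <- sprintf("# chrom: %s %s", names(chrom_sizes),
                   format(chrom_sizes, scientific = FALSE, trim = TRUE))
  }
  writeLines(hdr, path)
  data.table::fwrite(intervals[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track>", x$backend, "backend:", x$path, "\n")
  invisible(x)
}
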