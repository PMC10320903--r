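#' Region sets
#'
#' A region set is a typed collection of genomic intervals — the unit of
#' analysis for pileups, embeddings and enrichment. Coordinates are 0-based
#' half-open (`[start, end)`, BED-native) everywhere in this package.
#'
#' Two kinds exist:
#' * `"point"` — regions analysed around an anchor coordinate, defined as the
#'   floor midpoint `floor((start + end) / 2)`; the surrounding window is an
#'   analysis parameter (see [point_config()]).
#' * `"interval"` — regions analysed over their full extent plus proportional
#'   flanks, so bins scale with interval length (see [interval_config()]).
#'
#' @param records A data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `strand` (`+`, `-` or `.`).
#' @param assembly A [genome_assembly()]; records must fit inside it.
#' @param kind `"point"` or `"interval"`.
#' @return A `region_set`: a data.frame with columns
#'   `chrom`, `start`, `end`, `name`, `strand` and attributes `kind`,
#'   `assembly`.
#' @seealso [load_bed()], [write_bed()], [region_anchors()]
#' @export
region_set <- function(records, assembly, kind = c("point", "interval")) {
  kind <- match.arg(kind)
  stopifnot(inherits(assembly, "genome_assembly"), is.data.frame(records))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(records))) {
    stop("records must have columns chrom, start, end")
  }
  n <- nrow(records)
  df <- data.frame(
    chrom = as.character(records$chrom),
    start = as.numeric(records$start),
    end = as.numeric(records$end),
    name = if ("name" %in% names(records)) as.character(records$name) else rep(".", n),
    strand = if ("strand" %in% names(records)) as.character(records$strand) else rep(".", n),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    if (any(!df$strand %in% c("+", "-", "."))) stop("strand must be one of '+', '-', '.'")
    len <- chrom_length(assembly, df$chrom)
    if (anyNA(len)) {
      bad <- unique(df$chrom[is.na(len)])
      stop("records on chromosomes absent from assembly: ", paste(bad, collapse = ", "))
    }
    if (any(df$start < 0) || any(df$start >= df$end) || any(df$end > len)) {
      stop("records must satisfy 0 <= start < end <= chromosome length")
    }
  }
  structure(df, kind = kind, assembly = assembly,
            class = c("region_set", "data.frame"))
}

#' @rdname region_set
#' @param x A `region_set`.
#' @export
region_kind <- function(x) {
  stopifnot(inherits(x, "region_set"))
  attr(x, "kind")
}

#' @rdname region_set
#' @export
region_assembly <- function(x) {
  stopifnot(inherits(x, "region_set"))
  attr(x, "assembly")
}

#' Anchor coordinates of a point region set
#'
#' The anchor of a record `[start, end)` is `floor((start + end) / 2)`.
#'
#' @param x A `region_set` (any kind).
#' @return Numeric vector of anchor coordinates in bp.
#' @export
region_anchors <- function(x) {
  stopifnot(inherits(x, "region_set"))
  floor((x$start + x$end) / 2)
}

#' Load a BED file as a region set
#'
#' Reads BED3/BED6 (tab-separated, 0-based half-open). Column 4 is taken as the
#' record name and column 6 as strand when present; `#` comment, `track` and
#' `browser` lines are skipped. Records are kept in file order.
#'
#' @param path BED file path.
#' @param assembly A [genome_assembly()].
#' @param kind `"point"` or `"interval"`.
#' @param on_unknown_chrom What to do with records whose chromosome is absent
#'   from `assembly`: `"warn"` (default) drops them with a warning, `"error"`
#'   aborts the load.
#' @return A [region_set()].
#' @export
load_bed <- function(path, assembly, kind = c("point", "interval"),
                     on_unknown_chrom = c("warn", "error")) {
  kind <- match.arg(kind)
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(region_set(data.frame(chrom = character(), start = numeric(),
                                 end = numeric()), assembly, kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", lineno[which(nf < 3L)[1]],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1]], ": non-integer coordinates")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1]], ": start >= end")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[4L], ""), ".")
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[6L], ""), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  known <- !is.na(chrom_length(assembly, chrom))
  if (any(!known)) {
    msg <- paste0(sum(!known), " record(s) on chromosomes absent from assembly '",
                  assembly$name, "' (", paste(unique(chrom[!known]), collapse = ", "), ")")
    if (on_unknown_chrom == "error") stop(msg)
    warning(msg, "; dropped")
  }
  region_set(data.frame(chrom = chrom, start = start, end = end,
                        name = name, strand = strand)[known, , drop = FALSE],
             assembly, kind)
}

#' Write a region set as BED
#'
#' Emits BED6 (name `.`, score 0) preserving the 0-based half-open convention,
#' so a write/[load_bed()] round trip reproduces the records exactly.
#'
#' @param x A [region_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "region_set"))
  df <- data.frame(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = x$name, score = 0L, strand = x$strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", attr(x, "kind"), "kind,", nrow(x), "records on assembly",
      attr(x, "assembly")$name, "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
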