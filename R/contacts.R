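#' Open a 2D contact store
#'
#' Returns a queryable intra-chromosomal contact matrix. Backends:
#' * **cooler** `.cool` (single resolution) and `.mcool` (multi-resolution)
#'   files, read via rhdf5;
#' * a **plain-text dialect** for text-only pipelines: header lines
#'   `# binsize: <bp>` and `# chrom: <name> <length>`, then tab-separated
#'   `chrom  bin_i  bin_j  value` triplets with per-chromosome bin indices
#'   (bin `i` covers `[i*binsize, (i+1)*binsize)`). Only one triangle need be
#'   stored; matrices are symmetrized at query time.
#'
#' Contact values are used as stored (raw counts) by default; `balance = TRUE`
#' in [query_contacts()] applies a stored per-bin weight column when present
#' (cooler `bins/weight`).
#'
#' @param path Contact store path.
#' @return A `contact_store` object.
#' @seealso [query_contacts()], [extract_2d()]
#' @export
open_contacts <- function(path) {
  if (!file.exists(path)) stop("contact store not found: ", path)
  if (grepl("\\.m?cool$", path, ignore.case = TRUE)) {
    open_contacts_cool(path)
  } else {
    open_contacts_text(path)
  }
}

new_contact_store <- function(backend, path, resolutions) {
  binsizes <- sort(as.numeric(names(resolutions)))
  structure(list(backend = backend, path = path, binsizes = binsizes,
                 resolutions = resolutions),
            class = "contact_store")
}

# one resolution = list(binsize, chrom_len, pixels dt(chrom,i,j,value), weights)
normalize_pixels <- function(dt) {
  swap <- dt$i > dt$j
  if (any(swap)) {
    tmp <- dt$i[swap]; dt$i[swap] <- dt$j[swap]; dt$j[swap] <- tmp
  }
  dt <- dt[, list(value = sum(value)), by = c("chrom", "i", "j")]
  data.table::setkeyv(dt, c("chrom", "i", "j"))
  dt
}

open_contacts_text <- function(path) {
  lines <- readLines(path)
  bs_hdr <- grep("^#\\s*binsize:", lines, value = TRUE)
  if (length(bs_hdr) != 1L) stop("text contact store needs exactly one '# binsize:' header")
  binsize <- as.numeric(trimws(sub("^#\\s*binsize:", "", bs_hdr)))
  if (!is.finite(binsize) || binsize <= 0) stop("invalid binsize header")
  ch_hdr <- grep("^#\\s*chrom:", lines, value = TRUE)
  chrom_len <- numeric(0)
  if (length(ch_hdr)) {
    parts <- strsplit(trimws(sub("^#\\s*chrom:", "", ch_hdr)), "\\s+")
    chrom_len <- vapply(parts, function(p) as.numeric(p[2]), 0)
    names(chrom_len) <- vapply(parts, `[`, "", 1)
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body)) {
    dt <- data.table::fread(text = body, sep = "\t", header = FALSE,
                            col.names = c("chrom", "i", "j", "value"))
  } else {
    dt <- data.table::data.table(chrom = character(), i = integer(),
                                 j = integer(), value = numeric())
  }
  if (length(chrom_len) == 0L && nrow(dt)) {
    chrom_len <- vapply(split(dt$j, dt$chrom), function(j) (max(j) + 1) * binsize, 0)
  }
  unknown <- setdiff(unique(dt$chrom), names(chrom_len))
  if (length(unknown)) stop("pixels on undeclared chromosomes: ",
                            paste(unknown, collapse = ", "))
  res <- list(list(binsize = binsize, chrom_len = chrom_len,
                   pixels = normalize_pixels(dt), weights = NULL))
  names(res) <- format(binsize, scientific = FALSE)
  new_contact_store("text", path, res)
}

open_contacts_cool <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("reading cooler files requires the rhdf5 package")
  }
  ls_all <- rhdf5::h5ls(path)
  if ("resolutions" %in% ls_all$name[ls_all$group == "/"]) {
    res_names <- unique(ls_all$name[ls_all$group == "/resolutions"])
    res <- lapply(res_names, function(r) read_cool_group(path, paste0("/resolutions/", r)))
    names(res) <- vapply(res, function(r) format(r$binsize, scientific = FALSE), "")
  } else {
    res <- list(read_cool_group(path, "/"))
    names(res) <- format(res[[1]]$binsize, scientific = FALSE)
  }
  new_contact_store("cool", path, res)
}

read_cool_group <- function(path, grp) {
  g <- function(x) rhdf5::h5read(path, paste0(sub("/$", "", grp), "/", x))
  chrom_names <- as.character(g("chroms/name"))
  chrom_len <- as.numeric(g("chroms/length"))
  names(chrom_len) <- chrom_names
  bchrom <- g("bins/chrom")
  bchrom <- if (is.numeric(bchrom)) chrom_names[as.integer(bchrom) + 1L]
            else as.character(bchrom)
  bstart <- as.numeric(g("bins/start"))
  bend <- as.numeric(g("bins/end"))
  binsize <- bend[1] - bstart[1]
  objs <- rhdf5::h5ls(path)
  bins_grp <- paste0(sub("/$", "", grp), "/bins")
  weights <- NULL
  if (any(objs$group == bins_grp & objs$name == "weight")) {
    w <- as.numeric(g("bins/weight"))
    weights <- split(w, factor(bchrom, levels = chrom_names))
  }
  p1 <- as.numeric(g("pixels/bin1_id")) + 1L
  p2 <- as.numeric(g("pixels/bin2_id")) + 1L
  cnt <- as.numeric(g("pixels/count"))
  intra <- bchrom[p1] == bchrom[p2]
  dt <- data.table::data.table(
    chrom = bchrom[p1][intra],
    i = as.integer(bstart[p1][intra] / binsize),
    j = as.integer(bstart[p2][intra] / binsize),
    value = cnt[intra])
  list(binsize = binsize, chrom_len = chrom_len,
       pixels = normalize_pixels(dt), weights = weights)
}

#' Query a contact store
#'
#' Returns the square contact matrix for the window `[start, end)` at the
#' requested bin size. `start` and `end` must lie on the store's bin grid.
#' Bins beyond the chromosome (negative, or past its end) give `NaN` rows and
#' columns; bins inside the chromosome with no stored pixel are 0. Matrices
#' are symmetric by construction.
#'
#' @param store A [open_contacts()] result.
#' @param chrom Chromosome name.
#' @param start,end Window in bp, multiples of `binsize`.
#' @param binsize Bin size in bp; must be one of `store$binsizes`, otherwise
#'   an error lists the available sizes.
#' @param balance Multiply by stored per-bin balancing weights (cooler
#'   `bins/weight`); weights of `NaN` propagate.
#' @return `(end-start)/binsize` square numeric matrix.
#' @export
query_contacts <- function(store, chrom, start, end, binsize, balance = FALSE) {
  stopifnot(inherits(store, "contact_store"))
  key <- format(as.numeric(binsize), scientific = FALSE)
  if (!key %in% names(store$resolutions)) {
    stop("binsize ", binsize, " not in store; available: ",
         paste(store$binsizes, collapse = ", "))
  }
  if (start %% binsize != 0 || end %% binsize != 0 || end <= start) {
    stop("start and end must be multiples of binsize with end > start")
  }
  res <- store$resolutions[[key]]
  side <- as.integer((end - start) / binsize)
  q0 <- start / binsize
  m <- matrix(0, side, side)
  qchrom <- chrom
  len <- res$chrom_len[qchrom]
  if (is.na(len)) return(matrix(NaN, side, side))
  nbins_chrom <- ceiling(len / binsize)
  qbins <- q0 + seq_len(side) - 1L
  valid <- qbins >= 0 & qbins < nbins_chrom
  px <- res$pixels[chrom == qchrom & i >= q0 & i < q0 + side &
                     j >= q0 & j < q0 + side]
  if (nrow(px)) {
    ri <- px$i - q0 + 1L; rj <- px$j - q0 + 1L
    m[cbind(ri, rj)] <- px$value
    m[cbind(rj, ri)] <- px$value
  }
  if (balance) {
    if (is.null(res$weights)) stop("store has no balancing weights")
    w <- rep(NaN, side)
    w[valid] <- res$weights[[chrom]][qbins[valid] + 1L]
    m <- m * outer(w, w)
  }
  m[!valid, ] <- NaN
  m[, !valid] <- NaN
  m
}

#' Write a contact store in the plain-text dialect
#'
#' @param pixels data.frame with columns `chrom`, `i`, `j`, `value`
#'   (per-chromosome bin indices; one triangle suffices).
#' @param path Output path.
#' @param binsize Bin size in bp.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return `path`, invisibly.
#' @export
write_contacts_text <- function(pixels, path, binsize, chrom_sizes) {
  hdr <- c(sprintf("# binsize: %s", format(binsize, scientific = FALSE)),
           sprintf("# chrom: %s %s", names(chrom_sizes),
                   format(chrom_sizes, scientific = FALSE, trim = TRUE)))
  writeLines(hdr, path)
  data.table::fwrite(pixels[, c("chrom", "i", "j", "value")], path,
                     sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write a minimal single-resolution cooler file
#'
#' Emits the cooler v3 core tables (`chroms`, `bins`, `pixels`) so that
#' synthetic matrices can be round-tripped through the cooler backend.
#'
#' @inheritParams write_contacts_text
#' @param assembly A [genome_assembly()] defining chromosome order and sizes.
#' @return `path`, invisibly.
#' @export
write_cool <- function(pixels, path, binsize, assembly) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("writing cooler files requires the rhdf5 package")
  }
  stopifnot(inherits(assembly, "genome_assembly"))
  sizes <- assembly$chrom_sizes
  nbins <- ceiling(sizes / binsize)
  offsets <- c(0, cumsum(nbins))[seq_along(nbins)]
  names(offsets) <- names(sizes)
  bchrom <- rep(seq_along(sizes) - 1L, nbins)
  bstart <- unlist(lapply(nbins, function(n) (seq_len(n) - 1) * binsize),
                   use.names = FALSE)
  bend <- pmin(bstart + binsize, rep(sizes, nbins))
  px <- data.table::as.data.table(pixels)
  px <- normalize_pixels(px)
  gid1 <- offsets[px$chrom] + px$i
  gid2 <- offsets[px$chrom] + px$j
  ord <- order(gid1, gid2)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (grp in c("chroms", "bins", "pixels")) rhdf5::h5createGroup(path, grp)
  rhdf5::h5write(names(sizes), path, "chroms/name")
  rhdf5::h5write(as.integer(sizes), path, "chroms/length")
  rhdf5::h5write(as.integer(bchrom), path, "bins/chrom")
  rhdf5::h5write(as.integer(bstart), path, "bins/start")
  rhdf5::h5write(as.integer(bend), path, "bins/end")
  rhdf5::h5write(as.integer(gid1[ord]), path, "pixels/bin1_id")
  rhdf5::h5write(as.integer(gid2[ord]), path, "pixels/bin2_id")
  rhdf5::h5write(as.numeric(px$value[ord]), path, "pixels/count")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @export
print.contact_store <- function(x, ...) {
  cat("<contact_store>", x$backend, "backend:", x$path, "- binsizes",
      paste(x$binsizes, collapse = ", "), "\n")
  invisible(x)
}
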