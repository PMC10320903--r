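#' Genome assemblies
#'
#' A genome assembly is a named, ordered set of chromosome lengths. It anchors
#' every region set: records on chromosomes absent from the assembly are
#' rejected at load time, and bins extending past a chromosome end are flagged
#' out of bounds.
#'
#' @param name Text label for the assembly (e.g. `"hg19"`, `"toy"`).
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#'   All lengths must be positive integers and names unique.
#' @return An object of class `genome_assembly` with elements `name` and
#'   `chrom_sizes`.
#' @examples
#' asm <- genome_assembly("toy", c(chr1 = 1e6, chr2 = 5e5))
#' chrom_length(asm, "chr2")
#' @export
genome_assembly <- function(name, chrom_sizes) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(chrom_sizes) == 0L) {
    stop("assembly must contain at least one chromosome")
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector")
  }
  if (anyDuplicated(names(chrom_sizes))) {
    stop("chromosome names must be unique")
  }
  sizes <- as.numeric(chrom_sizes)
  if (any(!is.finite(sizes)) || any(sizes <= 0) || any(sizes != floor(sizes))) {
    stop("every chromosome length must be a positive integer")
  }
  names(sizes) <- names(chrom_sizes)
  structure(list(name = name, chrom_sizes = sizes), class = "genome_assembly")
}

#' Read a chrom.sizes file
#'
#' Parses the standard two-column (chromosome name, length in bp) tab- or
#' whitespace-separated chrom.sizes format.
#'
#' @param path Path to the chrom.sizes file.
#' @param name Assembly label; defaults to the file name without extension.
#' @return A [genome_assembly()].
#' @export
read_chrom_sizes <- function(path, name = NULL) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = FALSE, col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  sizes <- df$length
  names(sizes) <- df$chrom
  genome_assembly(name, sizes)
}

#' Write a chrom.sizes file
#'
#' @param assembly A [genome_assembly()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  df <- data.frame(chrom = names(assembly$chrom_sizes),
                   length = format(assembly$chrom_sizes, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Chromosome length lookup
#'
#' @param assembly A [genome_assembly()].
#' @param chrom Chromosome name(s).
#' @return Numeric vector of lengths in bp; `NA` for unknown chromosomes.
#' @export
chrom_length <- function(assembly, chrom) {
  stopifnot(inherits(assembly, "genome_assembly"))
  unname(assembly$chrom_sizes[chrom])
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly>", x$name, "-", length(x$chrom_sizes), "chromosomes,",
      format(sum(x$chrom_sizes), big.mark = ","), "bp total\n")
  invisible(x)
}
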