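#' Genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths that
#' every interval and variant in a run is validated against. All internal
#' coordinates in this package are 0-based half-open; the layout lengths are
#' plain base-pair counts.
#'
#' @param chrom Character vector of unique chromosome names, in order.
#' @param length Integer vector of chromosome lengths in bp, all `> 0`.
#' @return A `genome_layout` data frame with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(5e6, 5e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != base::length(length)) stop("chrom and length differ in size")
  if (any(!is.finite(length)) || any(length <= 0)) stop("chromosome lengths must be positive")
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), %.3g Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  print(as.data.frame(x), ...)
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

#' Write / read a genome layout as a two-column TSV
#'
#' @param layout A [genome_layout()].
#' @param path File path.
#' @return `read_genome_layout` returns a `genome_layout`;
#'   `write_genome_layout` returns `path` invisibly.
#' @export
write_genome_layout <- function(layout, path) {
  utils::write.table(as.data.frame(layout), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_layout
#' @export
read_genome_layout <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  genome_layout(x$chrom, x$length)
}
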