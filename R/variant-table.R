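#' Variant tables
#'
#' The central container: a data frame of variant records plus a parallel
#' dosage matrix. Coordinates follow the internal 0-based half-open
#' convention: a deletion of length L anchored at VCF POS p spans
#' `[p, p + L)`; an insertion is a zero-width anchor `[p, p)` (its sequence
#' length is carried in `length`); a SNP spans `[p - 1, p)`.
#'
#' @param variants Data frame with at least `variant_id`, `chrom`, `pos`
#'   (1-based VCF position), `start`, `end` (0-based half-open), `vtype`
#'   (`"SNP"`, `"INS"` or `"DEL"`), `length` (bp), `qual`. INFO annotations
#'   (`QD`, `FS`, ...) are additional numeric columns; missing annotations
#'   are `NA`.
#' @param geno Integer matrix, variants x samples, entries in
#'   `{0, 1, 2, NA}` (ALT allele dosage; `NA` = missing genotype).
#' @return A `variant_table` object (list with elements `variants`, `geno`,
#'   `samples`).
#' @export
variant_table <- function(variants, geno = NULL) {
  need <- c("variant_id", "chrom", "pos", "start", "end", "vtype", "length", "qual")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(variants$variant_id)) stop("duplicate variant_id")
  if (!all(variants$vtype %in% c("SNP", "INS", "DEL"))) stop("vtype must be SNP/INS/DEL")
  bad_len <- variants$vtype != "SNP" & variants$length < 1
  if (any(bad_len)) stop("INS/DEL with length < 1")
  if (any(variants$end < variants$start)) stop("end < start")
  if (is.null(geno)) {
    geno <- matrix(integer(0), nrow = nrow(variants), ncol = 0)
  }
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(variants)) stop("geno rows != variant rows")
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  rownames(geno) <- variants$variant_id
  structure(list(variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 geno = geno,
                 samples = colnames(geno) %||% character()),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  tab <- table(x$variants$vtype)
  cat(sprintf("<variant_table> %d variants (%s), %d samples\n",
              nrow(x$variants),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              length(x$samples)))
  invisible(x)
}

#' Number of variants in a variant table
#' @param vt A [variant_table()].
#' @return Integer count.
#' @export
n_variants <- function(vt) nrow(vt$variants)

#' Subset a variant table by row index or logical mask
#' @param vt A [variant_table()].
#' @param i Integer or logical index over variants.
#' @return A [variant_table()].
#' @export
vt_subset <- function(vt, i) {
  variant_table(vt$variants[i, , drop = FALSE],
                vt$geno[i, , drop = FALSE])
}

#' Convert variant spans to an interval track
#'
#' Deletions keep their reference span, insertions become zero-width anchor
#' points, SNPs single-base intervals. `label` is the size class when
#' present, `sublabel` the variant type.
#'
#' @param vt A [variant_table()].
#' @return An [interval_track()] in variant order, carrying `variant_id`
#'   in an extra column.
#' @export
variant_track <- function(vt) {
  v <- vt$variants
  tr <- interval_track(v$chrom, v$start, v$end,
                       label = if ("size_class" %in% names(v)) v$size_class else NA,
                       sublabel = v$vtype, name = "variants")
  tr$variant_id <- v$variant_id
  tr
}
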