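#' Composite LD: squared dosage correlation
#'
#' r-squared between two variants computed as the squared Pearson
#' correlation of unphased genotype dosages over jointly non-missing
#' samples (composite LD, the default when phase is unavailable).
#' Undefined (`NA`) when fewer than 2 jointly non-missing samples remain
#' or either site is monomorphic among them. Symmetric and invariant under
#' allele relabeling (`d -> 2 - d`).
#'
#' @param a,b Dosage vectors (0/1/2, `NA` missing) of equal length.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @examples
#' dosage_r2(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2))  # 1
#' @export
dosage_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' LD category from r-squared
#'
#' `high` when `r2 >= 0.8`; `medium` when `0.2 <= r2 < 0.8`; `low` when
#' `r2 < 0.2`.
#'
#' @param r2 Numeric vector.
#' @return Character vector in `{"high", "medium", "low"}` (`NA` in,
#'   `NA` out).
#' @export
ld_category <- function(r2) {
  ifelse(is.na(r2), NA_character_,
         ifelse(r2 >= 0.8, "high", ifelse(r2 >= 0.2, "medium", "low")))
}

#' Tag variants by e/sQTL SNPs in LD
#'
#' For every INS/DEL, finds the e/sQTL-flagged SNPs within `window` bp of
#' its anchor, computes composite r-squared against each, and reports the
#' best-tagging SNP per QTL kind with its LD category. The variant's tissue
#' list is the union of tissues of all SNPs achieving the maximum
#' r-squared within a `1e-9` tolerance. Variants with no in-window
#' qualifying SNP (or no defined r-squared) are excluded and tallied in the
#' `untested` attribute.
#'
#' @param vt A [variant_table()] of the variants to tag (non-SNP records
#'   are used).
#' @param snps A [variant_table()] of SNP genotypes over the same samples.
#' @param qtl_snps An [interval_track()] of e/sQTL SNP positions
#'   (single-base intervals), `label` = kind (`"eQTL"`/`"sQTL"`),
#'   `sublabel` = tissue; a SNP present in several tissues/kinds appears
#'   on several rows.
#' @param window Search window in bp either side of the variant anchor
#'   (default 1 Mb).
#' @return Data frame `variant_id`, `qtl_kind`, `best_snp`, `max_r2`,
#'   `category`, `tissues` (";"-collapsed), `n_snps_tested`.
#' @export
tag_variants <- function(vt, snps, qtl_snps, window = 1e6) {
  qtl_snps <- as_track(qtl_snps)
  sv <- snps$variants
  # match track rows to SNP records by chromosome + 0-based position
  snp_key <- paste(sv$chrom, sv$start)
  trk_key <- paste(qtl_snps$chrom, qtl_snps$start)
  snp_row <- match(trk_key, snp_key)
  if (all(is.na(snp_row))) stop("no e/sQTL track position matches a SNP record")
  v <- vt$variants[vt$variants$vtype != "SNP", , drop = FALSE]
  gv <- vt$geno[vt$variants$vtype != "SNP", , drop = FALSE]
  rows <- list(); k <- 0L; untested <- 0L
  for (kind in unique(qtl_snps$label[!is.na(qtl_snps$label)])) {
    ti <- which(qtl_snps$label == kind & !is.na(snp_row))
    for (i in seq_len(nrow(v))) {
      anchor <- v$start[i]
      cand <- ti[qtl_snps$chrom[ti] == v$chrom[i] &
                   abs(qtl_snps$start[ti] - anchor) <= window]
      if (length(cand) == 0) { untested <- untested + 1L; next }
      rowset <- unique(snp_row[cand])
      r2 <- vapply(rowset, function(r) dosage_r2(gv[i, ], snps$geno[r, ]),
                   numeric(1))
      if (all(is.na(r2))) { untested <- untested + 1L; next }
      mx <- max(r2, na.rm = TRUE)
      best_rows <- rowset[!is.na(r2) & r2 >= mx - 1e-9]
      best_keys <- snp_key[best_rows]
      tissues <- sort(unique(qtl_snps$sublabel[cand][snp_key[snp_row[cand]] %in% best_keys]))
      k <- k + 1L
      rows[[k]] <- data.frame(variant_id = v$variant_id[i], qtl_kind = kind,
                              best_snp = sv$variant_id[best_rows[1]],
                              max_r2 = mx, category = ld_category(mx),
                              tissues = paste(tissues, collapse = ";"),
                              n_snps_tested = length(rowset),
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (k == 0) {
    data.frame(variant_id = character(), qtl_kind = character(),
               best_snp = character(), max_r2 = numeric(),
               category = character(), tissues = character(),
               n_snps_tested = integer())
  } else do.call(rbind, rows)
  attr(out, "untested") <- untested
  out
}

#' Tissue-resolved LD-tag summary
#'
#' Expands the tissue lists of [tag_variants()] calls and tabulates counts
#' and within-group proportions per tissue, QTL kind, size class and LD
#' category. Proportions sum to 1 over categories within each
#' (tissue, kind, size class) group.
#'
#' @param calls Output of [tag_variants()].
#' @param vt The tagged [variant_table()] (for size classes).
#' @return Data frame `tissue`, `qtl_kind`, `size_class`, `category`,
#'   `count`, `proportion`.
#' @export
tissue_summary <- function(calls, vt) {
  if (nrow(calls) == 0) {
    return(data.frame(tissue = character(), qtl_kind = character(),
                      size_class = character(), category = character(),
                      count = integer(), proportion = numeric()))
  }
  v <- vt$variants
  if (!"size_class" %in% names(v)) {
    v$size_class <- ifelse(v$vtype == "SNP", NA, classify_size(v$length))
  }
  sc <- v$size_class[match(calls$variant_id, v$variant_id)]
  tlist <- strsplit(calls$tissues, ";", fixed = TRUE)
  long <- data.frame(tissue = unlist(tlist),
                     qtl_kind = rep(calls$qtl_kind, lengths(tlist)),
                     size_class = rep(sc, lengths(tlist)),
                     category = rep(calls$category, lengths(tlist)))
  tab <- stats::aggregate(list(count = rep(1L, nrow(long))),
                          long[c("tissue", "qtl_kind", "size_class", "category")],
                          FUN = sum)
  grp <- paste(tab$tissue, tab$qtl_kind, tab$size_class)
  tot <- stats::ave(tab$count, grp, FUN = sum)
  tab$proportion <- tab$count / tot
  tab[order(tab$tissue, tab$qtl_kind, tab$size_class, tab$category), ]
}
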