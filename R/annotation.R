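#' Build precedence-ordered feature tracks from gene models
#'
#' Derives the region tracks used by [classify_region()]:
#' coding-exonic/splicing (CDS plus `splice_window` bp into each intron at
#' every exon junction of a coding transcript), 5' and 3' UTR, intronic
#' (coding-transcript introns), ncRNA (span of non-coding transcripts),
#' and upstream/downstream (`flank` bp either side of each gene span,
#' clipped to the chromosome).
#'
#' @param gm A `gene_model_set` from [read_gff_genes()].
#' @param layout A [genome_layout()] (for clipping flanks).
#' @param flank Upstream/downstream flank in bp (default 1000, the
#'   ANNOVAR convention).
#' @param splice_window Splice-site window in bp into the intron (default 2).
#' @return Named list of [interval_track()]s in precedence order.
#' @export
gene_feature_tracks <- function(gm, layout, flank = 1000, splice_window = 2) {
  coding_tx <- gm$transcripts$tx_id[gm$transcripts$coding]
  cint <- gm$introns[gm$introns$tx_id %in% coding_tx, , drop = FALSE]
  splice <- if (nrow(cint) > 0) {
    w <- pmin(splice_window, cint$end - cint$start)
    data.frame(chrom = rep(cint$chrom, 2),
               start = c(cint$start, cint$end - w),
               end = c(cint$start + w, cint$end))
  } else data.frame(chrom = character(), start = numeric(), end = numeric())
  exonic <- rbind(gm$cds[c("chrom", "start", "end")], splice)
  nc_tx <- gm$transcripts[!gm$transcripts$coding, , drop = FALSE]
  g <- gm$genes
  upd <- data.frame(chrom = rep(g$chrom, 2),
                    start = c(pmax(g$start - flank, 0), g$end),
                    end = c(g$start, pmin(g$end + flank, chrom_length(layout, g$chrom))))
  mk <- function(d, nm) interval_track(d$chrom, d$start, d$end, name = nm)
  list(exonic_splicing = mk(exonic, "exonic_splicing"),
       UTR5 = mk(gm$utr5, "UTR5"),
       UTR3 = mk(gm$utr3, "UTR3"),
       intronic = mk(cint, "intronic"),
       ncRNA = mk(nc_tx, "ncRNA"),
       upstream_downstream = mk(upd[upd$end > upd$start, , drop = FALSE],
                                "upstream_downstream"))
}

REGION_LEVELS <- c("exonic_splicing", "UTR5", "UTR3", "intronic", "ncRNA",
                   "upstream_downstream", "intergenic")

#' ANNOVAR-style genomic region classification
#'
#' Assigns every variant to exactly one of the six region groups: exonic
#' regions and splice sites, 5'/3' UTRs, intronic regions, noncoding-RNA
#' regions, upstream/downstream regulatory regions (within `flank` bp of a
#' gene), or intergenic. A variant touching several features takes the
#' highest-precedence one (exonic/splicing > UTR > intronic > ncRNA >
#' upstream/downstream > intergenic); a deletion spanning multiple
#' categories is classified by its highest-precedence touch. Insertions
#' are assessed at their anchor point. All genes whose span (plus flank)
#' the variant touches are listed.
#'
#' @param vt A [variant_table()] (SNPs are classified too if present).
#' @param gm A `gene_model_set`.
#' @param layout A [genome_layout()].
#' @param flank Upstream/downstream flank in bp (default 1000).
#' @param splice_window Splice window in bp (default 2).
#' @return Data frame `variant_id`, `region`, `gene_ids`
#'   (comma-collapsed, `""` when none).
#' @export
classify_region <- function(vt, gm, layout, flank = 1000, splice_window = 2) {
  tracks <- gene_feature_tracks(gm, layout, flank, splice_window)
  qt <- variant_track(vt)
  region <- rep("intergenic", nrow(qt))
  assigned <- rep(FALSE, nrow(qt))
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    if (nrow(tr) == 0) next
    hit <- unique(overlap_pairs(qt, tr)$query)
    sel <- hit[!assigned[hit]]
    region[sel] <- nm
    assigned[sel] <- TRUE
  }
  g <- gm$genes
  gene_track <- interval_track(g$chrom, pmax(g$start - flank, 0),
                               pmin(g$end + flank, chrom_length(layout, g$chrom)))
  gp <- overlap_pairs(qt, gene_track)
  gene_ids <- vapply(seq_len(nrow(qt)), function(i) {
    paste(g$gene_id[gp$reference[gp$query == i]], collapse = ",")
  }, "")
  data.frame(variant_id = vt$variants$variant_id, region = region,
             gene_ids = gene_ids, stringsAsFactors = FALSE)
}

#' Region percentages by size class and variant type
#'
#' @param calls Region calls from [classify_region()].
#' @param vt The classified [variant_table()].
#' @return Data frame with one row per (size_class, vtype), one column per
#'   region holding percentages that sum to 100 within rounding, plus `n`.
#' @export
region_summary <- function(calls, vt) {
  v <- vt$variants
  if (!"size_class" %in% names(v)) {
    v$size_class <- ifelse(v$vtype == "SNP", "SNP", classify_size(v$length))
  }
  i <- match(calls$variant_id, v$variant_id)
  d <- data.frame(size_class = v$size_class[i], vtype = v$vtype[i],
                  region = factor(calls$region, levels = REGION_LEVELS))
  if (nrow(d) == 0) {
    return(data.frame(size_class = character(), vtype = character()))
  }
  tab <- as.data.frame.matrix(
    table(paste(d$size_class, d$vtype, sep = ":"), d$region))
  n <- rowSums(tab)
  pct <- 100 * tab / n
  key <- strsplit(rownames(tab), ":", fixed = TRUE)
  out <- data.frame(size_class = vapply(key, `[`, "", 1),
                    vtype = vapply(key, `[`, "", 2),
                    n = n, pct, check.names = FALSE, row.names = NULL)
  out
}
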