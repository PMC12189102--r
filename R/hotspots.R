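#' Breakpoint counts in non-overlapping genome bins
#'
#' Chromosomes are tiled with non-overlapping bins of `bin_size` bp (the
#' terminal bin may be partial; it is kept and not length-normalised). Each
#' deletion contributes two breakpoints — one at its start, one at its end
#' junction (two increments, possibly to the same bin) — and each insertion
#' one at its anchor. SNPs are ignored.
#'
#' @param vt A [variant_table()].
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp (default 100,000).
#' @return A `bin_counts` data frame: `chrom`, `bin` (0-based index),
#'   `start`, `end`, `count`, covering every bin of every chromosome.
#' @export
count_breakpoints <- function(vt, layout, bin_size = 1e5) {
  v <- vt$variants[vt$variants$vtype != "SNP", , drop = FALSE]
  if (any(!(v$chrom %in% layout$chrom))) stop("variant on chromosome absent from layout")
  len <- chrom_length(layout, v$chrom)
  if (any(v$end > len) || any(v$start < 0)) stop("variant beyond chromosome length")

  bins <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    nb <- ceiling(layout$length[i] / bin_size)
    data.frame(chrom = layout$chrom[i], bin = seq_len(nb) - 1,
               start = (seq_len(nb) - 1) * bin_size,
               end = pmin(seq_len(nb) * bin_size, layout$length[i]),
               stringsAsFactors = FALSE)
  }))
  key <- paste(bins$chrom, bins$bin)

  is_del <- v$vtype == "DEL"
  bp_chrom <- c(v$chrom, v$chrom[is_del])
  # DEL: start junction and end junction (last deleted base's bin);
  # INS: anchor bin
  bp_pos <- c(ifelse(is_del, v$start, v$start), pmax(v$end[is_del] - 1, 0))
  bp_key <- paste(bp_chrom, floor(bp_pos / bin_size))
  cnt <- table(bp_key)
  bins$count <- as.integer(cnt[key])
  bins$count[is.na(bins$count)] <- 0L
  class(bins) <- c("bin_counts", "data.frame")
  attr(bins, "bin_size") <- bin_size
  bins
}

#' Call hotspot bins from breakpoint counts
#'
#' Bins are ranked genome-wide by breakpoint count; with
#' `k = max(1, floor(top_frac * n_bins))` the threshold is the k-th ranked
#' count and every bin at or above it is a hotspot (ties at the threshold
#' included, so the call is invariant to bin order). A count of at least 1
#' is always required; if every bin is empty an empty set is returned with
#' a warning.
#'
#' @param bins A `bin_counts` data frame from [count_breakpoints()].
#' @param top_frac Fraction of bins to call (default 0.01, i.e. top 1%).
#' @param vt Optional [variant_table()]; when given, member variant ids
#'   (those with a breakpoint in the hotspot bin) are attached as a
#'   list-column.
#' @return Data frame of hotspot bins with attribute `threshold_count`.
#' @export
call_hotspots <- function(bins, top_frac = 0.01, vt = NULL) {
  if (nrow(bins) < 1) stop("no bins")
  if (all(bins$count == 0)) {
    warning("all bins empty; no hotspots")
    out <- bins[0, , drop = FALSE]
    attr(out, "threshold_count") <- NA_real_
    return(out)
  }
  k <- max(1, floor(top_frac * nrow(bins)))
  thr <- max(sort(bins$count, decreasing = TRUE)[k], 1)
  out <- bins[bins$count >= thr, , drop = FALSE]
  out <- out[order(match(out$chrom, unique(bins$chrom)), out$bin), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold_count") <- thr
  attr(out, "bin_size") <- attr(bins, "bin_size")
  if (!is.null(vt)) {
    B <- attr(bins, "bin_size")
    v <- vt$variants[vt$variants$vtype != "SNP", , drop = FALSE]
    is_del <- v$vtype == "DEL"
    bp <- data.frame(id = c(v$variant_id, v$variant_id[is_del]),
                     key = paste(c(v$chrom, v$chrom[is_del]),
                                 floor(c(v$start, pmax(v$end[is_del] - 1, 0)) / B)))
    hot_key <- paste(out$chrom, out$bin)
    out$member_variants <- lapply(hot_key, function(k) unique(bp$id[bp$key == k]))
  }
  out
}

#' Hotspot x QTL overlap per trait category
#'
#' Overlap means at least one shared base between a hotspot bin span and a
#' QTL interval (half-open, so an interval starting exactly at a bin's end
#' does not overlap). Each QTL is counted once per trait category even if
#' several hotspots hit it; unlabeled QTLs are grouped under
#' `"Unassigned"`.
#'
#' @param hotspots Hotspot bins from [call_hotspots()].
#' @param qtl An [interval_track()] whose `label` is the trait category.
#' @return Data frame `category`, `n_hotspots_overlapping`, `n_qtls_hit`.
#' @export
hotspot_qtl_overlap <- function(hotspots, qtl) {
  qtl <- as_track(qtl)
  lab <- ifelse(is.na(qtl$label), "Unassigned", qtl$label)
  hs_track <- interval_track(hotspots$chrom, hotspots$start, hotspots$end,
                             name = "hotspots")
  hits <- overlap_pairs(hs_track, qtl)
  cats <- sort(unique(lab))
  out <- do.call(rbind, lapply(cats, function(cat) {
    h <- hits[lab[hits$reference] == cat, , drop = FALSE]
    data.frame(category = cat,
               n_hotspots_overlapping = length(unique(h$query)),
               n_qtls_hit = length(unique(h$reference)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(category = character(),
                                      n_hotspots_overlapping = integer(),
                                      n_qtls_hit = integer())
  out
}
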