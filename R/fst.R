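#' Weir-Cockerham per-site Fst from diploid genotypes
#'
#' The two-level Weir & Cockerham (1984) variance-components estimator for
#' diploid genotype data (the estimator computed by VCFtools
#' `--weir-fst-pop`): per site, `a` is the among-population component, `b`
#' the among-individual-within-population component (with the observed
#' heterozygosity correction), `c` the within-individual component, and
#' `Fst = a / (a + b + c)`. Estimates may be negative and are not clamped.
#' A site monomorphic across both populations has `a + b + c = 0` and is
#' flagged undefined. Missing genotypes are excluded from all counts.
#'
#' @param d1,d2 Integer dosage vectors (0/1/2, `NA` missing) for the two
#'   populations at one site.
#' @return List `a`, `b`, `c`, `fst`, `n1`, `n2`, `defined`.
#' @examples
#' wc_fst_site(rep(0, 10), rep(2, 10))$fst  # 1: complete fixation
#' @export
wc_fst_site <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
  n1 <- length(d1); n2 <- length(d2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 non-missing diploids per population")
  comp <- wc_components(sum(d1) / (2 * n1), mean(d1 == 1), n1,
                        sum(d2) / (2 * n2), mean(d2 == 1), n2)
  tot <- comp$a + comp$b + comp$c
  list(a = comp$a, b = comp$b, c = comp$c,
       fst = if (tot == 0) NA_real_ else comp$a / tot,
       n1 = n1, n2 = n2, defined = tot != 0)
}

## vectorised WC84 components for r = 2 populations
## p: ALT frequency, h: observed heterozygote frequency, n: diploid count
wc_components <- function(p1, h1, n1, p2, h2, n2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham Fst for every variant of a table, one population pair
#'
#' Vectorised over sites. Sites with fewer than 2 non-missing diploids in
#' either population, or monomorphic across both, are flagged undefined
#' (`defined = FALSE`) and should be excluded from window sums.
#'
#' @param vt A [variant_table()] with genotypes.
#' @param pops Data frame `sample`, `pop`.
#' @param pair Length-2 character vector naming the two populations.
#' @return Data frame: `variant_id`, `chrom`, `pos`, `start`, `a`, `b`,
#'   `c`, `fst`, `n1`, `n2`, `defined`.
#' @export
wc_fst <- function(vt, pops, pair) {
  stopifnot(length(pair) == 2)
  g <- vt$geno
  i <- match(colnames(g), pops$sample)
  if (anyNA(i)) stop("sample(s) missing from population table")
  g1 <- g[, pops$pop[i] == pair[1], drop = FALSE]
  g2 <- g[, pops$pop[i] == pair[2], drop = FALSE]
  if (ncol(g1) == 0 || ncol(g2) == 0) stop("empty population in pair")
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
  comp <- wc_components(p1, h1, n1, p2, h2, n2)
  tot <- comp$a + comp$b + comp$c
  enough <- n1 >= 2 & n2 >= 2
  defined <- enough & is.finite(tot) & tot != 0
  v <- vt$variants
  data.frame(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
             start = v$start,
             a = ifelse(enough, comp$a, NA), b = ifelse(enough, comp$b, NA),
             c = ifelse(enough, comp$c, NA),
             fst = ifelse(defined, comp$a / tot, NA),
             n1 = n1, n2 = n2, defined = defined,
             stringsAsFactors = FALSE)
}

#' Hudson frequency-based Fst
#'
#' The Hudson estimator in the Bhatia et al. form, for allele frequencies
#' alone (the path used for Large variants, whose Fst is computed from SV
#' frequencies rather than genotype variance components):
#' `num = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' `den = p1(1-p2) + p2(1-p1)`, `Fst = num/den`. Undefined (flagged `NA`)
#' when both populations are fixed for the same allele (`den = 0`).
#'
#' @param p1,p2 ALT allele frequencies in the two populations.
#' @param n1,n2 Numbers of sampled chromosomes (2 x diploids), `>= 2`.
#' @param components If `TRUE` return a data frame with `num`, `den`,
#'   `fst` (needed for genome-wide ratio-of-averages aggregation).
#' @return Numeric vector of per-site Fst, or the components data frame.
#' @examples
#' hudson_fst_freq(1, 40, 0, 40)  # 1: fixed difference
#' @export
hudson_fst_freq <- function(p1, n1, p2, n2, components = FALSE) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(den == 0, NA_real_, num / den)
  if (components) data.frame(num = num, den = den, fst = fst) else fst
}

#' Sliding-window Fst aggregation
#'
#' Windows of `window` bp advanced by `step` bp, anchored at position 0 of
#' each chromosome; the last partial window is kept. Two aggregates per
#' window: `fst_weighted = sum(a) / sum(a + b + c)` (ratio of sums, the
#' primary statistic) and `fst_mean` (mean of per-site ratios). Undefined
#' sites are excluded; windows with no usable site are omitted.
#'
#' @param sites Per-site results from [wc_fst()].
#' @param layout A [genome_layout()].
#' @param window Window size in bp (default 50,000).
#' @param step Step in bp (default 20,000).
#' @return Data frame `chrom`, `start`, `end`, `n_sites`, `fst_weighted`,
#'   `fst_mean`.
#' @export
windowed_fst <- function(sites, layout, window = 5e4, step = 2e4) {
  s <- sites[sites$defined, , drop = FALSE]
  out <- list(); k <- 0L
  for (chr in layout$chrom) {
    d <- s[s$chrom == chr, , drop = FALSE]
    if (nrow(d) == 0) next
    clen <- chrom_length(layout, chr)
    starts <- seq(0, max(0, clen - 1), by = step)
    starts <- starts[starts < clen]
    # assign each site to every window containing it
    # window j (start = j*step) contains pos iff j*step <= pos < j*step+window
    jmax <- floor(d$start / step)
    jmin <- pmax(ceiling((d$start - window + 1) / step), 0)
    idx <- rep(seq_len(nrow(d)), jmax - jmin + 1)
    win <- unlist(mapply(seq, jmin, jmax, SIMPLIFY = FALSE))
    keep <- win < length(starts)
    idx <- idx[keep]; win <- win[keep]
    if (length(idx) == 0) next
    agg_num <- tapply(d$a[idx], win, sum)
    agg_den <- tapply((d$a + d$b + d$c)[idx], win, sum)
    agg_mean <- tapply(d$fst[idx], win, mean)
    agg_n <- tapply(idx, win, length)
    j <- as.integer(names(agg_num))
    k <- k + 1L
    out[[k]] <- data.frame(chrom = chr, start = j * step,
                           end = pmin(j * step + window, clen),
                           n_sites = as.integer(agg_n),
                           fst_weighted = ifelse(agg_den == 0, NA, agg_num / agg_den),
                           fst_mean = agg_mean, stringsAsFactors = FALSE)
  }
  if (k == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_sites = integer(), fst_weighted = numeric(),
                      fst_mean = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top-fraction selection candidates with ties
#'
#' Ranks windows (Small/Medium variants) or individual variants (Large) by
#' Fst genome-wide and keeps the top fraction:
#' `k = max(1, floor(top_frac * n))`, threshold = the k-th ranked value,
#' everything at or above the threshold kept (ties included). `NA` values
#' are excluded from ranking.
#'
#' @param x Data frame of ranked units.
#' @param value_col Name of the column to rank on.
#' @param top_frac Fraction to keep (default 0.01).
#' @return The selected rows, with attribute `threshold`.
#' @export
top_selection_regions <- function(x, value_col = "fst_weighted", top_frac = 0.01) {
  v <- x[[value_col]]
  ok <- which(!is.na(v))
  if (length(ok) == 0) stop("no ranked units")
  k <- max(1, floor(top_frac * length(ok)))
  thr <- sort(v[ok], decreasing = TRUE)[k]
  out <- x[ok[v[ok] >= thr], , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Genes overlapping selection regions
#'
#' @param regions Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [top_selection_regions()].
#' @param gm A `gene_model_set`.
#' @return Character vector of gene ids with at least 1 bp of overlap.
#' @export
genes_in_regions <- function(regions, gm) {
  if (nrow(regions) == 0) return(character())
  g <- gm$genes
  reg <- interval_track(regions$chrom, regions$start, regions$end)
  gt <- interval_track(g$chrom, g$start, g$end)
  hits <- overlap_pairs(gt, reg)
  sort(unique(g$gene_id[hits$query]))
}

#' Genes shared across population-pair selection scans
#'
#' @param gene_lists Named list of per-pair gene id vectors.
#' @param min_pairs Minimum number of pairs a gene must appear in
#'   (default 2).
#' @return Data frame `gene_id`, `n_pairs`, `pairs`.
#' @export
shared_genes <- function(gene_lists, min_pairs = 2) {
  if (length(gene_lists) == 0) {
    return(data.frame(gene_id = character(), n_pairs = integer(),
                      pairs = character()))
  }
  long <- data.frame(
    gene_id = unlist(gene_lists, use.names = FALSE),
    pair = rep(names(gene_lists), lengths(gene_lists)))
  long <- unique(long)
  cnt <- table(long$gene_id)
  keep <- names(cnt)[cnt >= min_pairs]
  out <- data.frame(gene_id = keep,
                    n_pairs = as.integer(cnt[keep]),
                    pairs = vapply(keep, function(g) {
                      paste(sort(long$pair[long$gene_id == g]), collapse = ";")
                    }, ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_pairs, out$gene_id), , drop = FALSE]
}

#' Genome-wide Fst aggregates
#'
#' The estimates used for cohort-level reporting and parameter-recovery
#' checks: Weir-Cockerham as the ratio of summed variance components
#' `sum(a) / sum(a+b+c)`, Hudson as the ratio of averaged numerators and
#' denominators (the aggregation recommended for combining sites; per-site
#' ratio averaging is biased toward zero).
#'
#' @param wc Per-site results from [wc_fst()] (or `NULL`).
#' @param hudson Components data frame from
#'   `hudson_fst_freq(..., components = TRUE)` (or `NULL`).
#' @return Named list `wc_weighted`, `hudson` (either may be `NA`).
#' @export
genomewide_fst <- function(wc = NULL, hudson = NULL) {
  wcv <- if (!is.null(wc)) {
    d <- wc[wc$defined, , drop = FALSE]
    sum(d$a) / sum(d$a + d$b + d$c)
  } else NA_real_
  hv <- if (!is.null(hudson)) {
    d <- hudson[is.finite(hudson$num) & is.finite(hudson$den), , drop = FALSE]
    sum(d$num) / sum(d$den)
  } else NA_real_
  list(wc_weighted = wcv, hudson = hv)
}
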