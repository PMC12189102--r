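#' Size classification of insertions and deletions
#'
#' Variants are stratified into three size classes that drive every
#' downstream analysis: Small (1-10 bp), Medium (11-50 bp) and Large
#' (>50 bp, the structural-variant class).
#'
#' @param length Numeric vector of variant lengths in bp, all `>= 1`.
#' @return Character vector in `{"Small", "Medium", "Large"}`.
#' @examples
#' classify_size(c(1, 10, 11, 50, 51))
#' @export
classify_size <- function(length) {
  if (any(!is.finite(length)) || any(length < 1)) stop("length must be >= 1")
  ifelse(length <= 10, "Small", ifelse(length <= 50, "Medium", "Large"))
}

#' Hard-filter thresholds
#'
#' GATK-style site-level thresholds plus cohort-level missingness/MAF
#' bounds. A SNP is removed when `QD < 2.0`, `QUAL < 30.0`, `SOR > 3.0`,
#' `FS > 60.0`, `MQ < 40.0`, `MQRankSum < -12.5` or
#' `ReadPosRankSum < -8.0`; an indel when `QD < 2.0`, `QUAL < 30.0`,
#' `FS > 200.0` or `ReadPosRankSum < -20.0`. All inequalities are strict,
#' exactly as stated; a rule whose INFO key is absent from a record is
#' skipped, not failed (merged SV records carry no GATK annotations).
#'
#' @param ... Named overrides of any default listed above, plus
#'   `indel_missing_max` (0.1), `sv_missing_max` (0.3), `sv_maf_min`
#'   (0.01) and `proximity_bp` (10).
#' @return A named list of thresholds.
#' @export
filter_thresholds <- function(...) {
  t <- list(
    snp = list(QD_min = 2.0, QUAL_min = 30.0, SOR_max = 3.0, FS_max = 60.0,
               MQ_min = 40.0, MQRankSum_min = -12.5, ReadPosRankSum_min = -8.0),
    indel = list(QD_min = 2.0, QUAL_min = 30.0, FS_max = 200.0,
                 ReadPosRankSum_min = -20.0),
    indel_missing_max = 0.1,
    sv_missing_max = 0.3,
    sv_maf_min = 0.01,
    proximity_bp = 10
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(t)) t[[nm]] <- dots[[nm]]
    else if (nm %in% names(t$snp)) t$snp[[nm]] <- dots[[nm]]
    else if (nm %in% names(t$indel)) t$indel[[nm]] <- dots[[nm]]
    else stop("unknown threshold: ", nm)
  }
  stopifnot(t$proximity_bp >= 0)
  t
}

#' Apply GATK-style hard filters
#'
#' A record is removed iff at least one rule fires; each rule's firing count
#' is tallied independently (a record can count against several rules).
#' Rules referencing an INFO key the record lacks are skipped.
#'
#' @param vt A [variant_table()] with INFO columns where available.
#' @param thresholds A [filter_thresholds()] list.
#' @return A list with `variants` (the retained [variant_table()]) and
#'   `tally` (named integer vector of per-rule rejection counts).
#' @export
apply_hard_filters <- function(vt, thresholds = filter_thresholds()) {
  v <- vt$variants
  n <- nrow(v)
  is_snp <- v$vtype == "SNP"
  col <- function(key) if (key %in% names(v)) v[[key]] else rep(NA_real_, n)
  fires <- function(x, cmp, bound) !is.na(x) & cmp(x, bound)

  rules <- list(
    snp_QD = is_snp & fires(col("QD"), `<`, thresholds$snp$QD_min),
    snp_QUAL = is_snp & fires(v$qual, `<`, thresholds$snp$QUAL_min),
    snp_SOR = is_snp & fires(col("SOR"), `>`, thresholds$snp$SOR_max),
    snp_FS = is_snp & fires(col("FS"), `>`, thresholds$snp$FS_max),
    snp_MQ = is_snp & fires(col("MQ"), `<`, thresholds$snp$MQ_min),
    snp_MQRankSum = is_snp & fires(col("MQRankSum"), `<`, thresholds$snp$MQRankSum_min),
    snp_ReadPosRankSum = is_snp & fires(col("ReadPosRankSum"), `<`,
                                        thresholds$snp$ReadPosRankSum_min),
    indel_QD = !is_snp & fires(col("QD"), `<`, thresholds$indel$QD_min),
    indel_QUAL = !is_snp & fires(v$qual, `<`, thresholds$indel$QUAL_min),
    indel_FS = !is_snp & fires(col("FS"), `>`, thresholds$indel$FS_max),
    indel_ReadPosRankSum = !is_snp & fires(col("ReadPosRankSum"), `<`,
                                           thresholds$indel$ReadPosRankSum_min)
  )
  tally <- vapply(rules, sum, integer(1))
  removed <- Reduce(`|`, rules, rep(FALSE, n))
  list(variants = vt_subset(vt, !removed), tally = tally)
}

#' Proximity de-duplication of indels
#'
#' When one indel lies within `d` bp of another, the lower-QUAL one is
#' removed. Clusters of 3 or more are resolved greedily and
#' deterministically: indels are taken in priority order (QUAL descending,
#' then position ascending, then DEL before INS); each is accepted unless
#' its start position lies within `d` bp of an already accepted start. No
#' two survivors have start positions within `d` bp on the same chromosome.
#' Distances are measured between VCF POS anchors, chromosome by
#' chromosome.
#'
#' @param vt A [variant_table()] of indels.
#' @param d Proximity distance in bp (default 10).
#' @return The surviving [variant_table()].
#' @export
proximity_dedup <- function(vt, d = 10) {
  v <- vt$variants
  if (nrow(v) == 0) return(vt)
  keep <- logical(nrow(v))
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    o <- idx[order(-v$qual[idx], v$pos[idx], v$vtype[idx] != "DEL")]
    acc <- numeric(0)
    for (i in o) {
      p <- v$pos[i]
      if (length(acc) == 0 || min(abs(acc - p)) > d) {
        keep[i] <- TRUE
        acc <- c(acc, p)
      }
    }
  }
  vt_subset(vt, keep)
}

#' Per-variant genotype statistics
#'
#' Missing rate over samples, ALT allele frequency and minor allele
#' frequency over non-missing chromosomes, optionally per-population allele
#' frequencies. Variants with all genotypes missing are flagged undefined.
#'
#' @param vt A [variant_table()] with genotypes.
#' @param pops Optional data frame `sample`, `pop` for per-population
#'   frequencies.
#' @return Data frame with `variant_id`, `missing_rate`, `p_alt`, `maf`,
#'   `defined`, plus one `freq_<pop>` column per population when `pops`
#'   is given.
#' @export
genotype_stats <- function(vt, pops = NULL) {
  g <- vt$geno
  if (ncol(g) == 0) stop("variant table has no genotypes")
  n_miss <- rowSums(is.na(g))
  n_obs <- ncol(g) - n_miss
  p_alt <- rowSums(g, na.rm = TRUE) / (2 * n_obs)
  p_alt[n_obs == 0] <- NA_real_
  out <- data.frame(variant_id = vt$variants$variant_id,
                    missing_rate = n_miss / ncol(g),
                    p_alt = p_alt,
                    maf = pmin(p_alt, 1 - p_alt),
                    defined = n_obs > 0,
                    stringsAsFactors = FALSE)
  if (!is.null(pops)) {
    i <- match(colnames(g), pops$sample)
    if (anyNA(i)) stop("sample(s) missing from population table: ",
                       paste(colnames(g)[is.na(i)], collapse = ", "))
    for (p in unique(pops$pop)) {
      cols <- which(pops$pop[i] == p)
      gp <- g[, cols, drop = FALSE]
      np <- rowSums(!is.na(gp))
      f <- rowSums(gp, na.rm = TRUE) / (2 * np)
      f[np == 0] <- NA_real_
      out[[paste0("freq_", p)]] <- f
    }
  }
  out
}

#' Cohort-level missingness / MAF filter
#'
#' SNPs and indels (Small/Medium) are retained when their missing genotype
#' rate is strictly below `indel_missing_max`; structural variants (Large)
#' when their missing rate is strictly below `sv_missing_max` *and* their
#' MAF is strictly above `sv_maf_min`. All bounds are exclusive, following
#' the filtering language they implement ("< 0.1", "below 30%", "greater
#' than 0.01").
#'
#' @param vt A [variant_table()]; a `size_class` column is derived from
#'   `length` if absent.
#' @param thresholds A [filter_thresholds()] list.
#' @return The retained [variant_table()], with a `qc_report` attribute
#'   giving per-path removal counts.
#' @export
filter_cohort <- function(vt, thresholds = filter_thresholds()) {
  v <- vt$variants
  if (!"size_class" %in% names(v)) {
    v$size_class <- NA_character_
    nz <- v$vtype != "SNP"
    v$size_class[nz] <- classify_size(v$length[nz])
    vt$variants <- v
  }
  st <- genotype_stats(vt)
  large <- !is.na(v$size_class) & v$size_class == "Large"
  keep <- ifelse(large,
                 st$missing_rate < thresholds$sv_missing_max &
                   !is.na(st$maf) & st$maf > thresholds$sv_maf_min,
                 st$missing_rate < thresholds$indel_missing_max)
  out <- vt_subset(vt, keep)
  attr(out, "qc_report") <- c(
    removed_missing_small = sum(!keep & !large),
    removed_large = sum(!keep & large),
    retained = sum(keep))
  out
}
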