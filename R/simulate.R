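#' Synthetic cohort configuration
#'
#' Parameters of the Balding-Nichols synthetic cohort generator. The
#' defaults emulate the study system the pipeline targets: five indigenous
#' breeds of about 20 animals each, weak background differentiation
#' (F = 0.02, matching the low pairwise Fst range such cohorts show), a
#' variant length mixture spanning the Small/Medium/Large classes with
#' deletions slightly outnumbering insertions, a 1% subset of 100 kb bins
#' upweighted 20-fold as breakpoint hotspots, TE-derived variants
#' (LINE/L1 and a SINE/Core-RTE component whose lengths peak near 150 bp,
#' mostly named BOV-A2), a simple-repeat unit-length mixture peaking at
#' dinucleotides, a region mix dominated by intergenic and intronic
#' placements, six QTL trait categories, and tissue-labelled e/sQTL SNPs.
#'
#' @param seed Integer RNG seed; one global stream drives the whole run.
#' @param pops Population (breed) names.
#' @param n_per_pop Diploid individuals per population.
#' @param chroms,chrom_length Chromosome names and common length in bp.
#' @param n_snps,n_indels,n_svs Locus counts (indels split ~70/30 into
#'   Small/Medium; SVs are Large).
#' @param F Background Balding-Nichols differentiation per population.
#' @param F_sel Locus-specific F for planted selection loci.
#' @param n_selection_small,n_selection_large Planted selection loci among
#'   Small/Medium indels and among Large variants.
#' @param bin_size,hotspot_frac,hotspot_multiplier Hotspot planting: bin
#'   width, fraction of bins planted, breakpoint rate multiplier.
#' @param region_mix Named proportions over the region classes (must sum
#'   to 1).
#' @param te_frac_large Fraction of Large variants planted as TE-driven.
#' @param simple_frac Fraction of Medium variants planted as
#'   simple-repeat-driven.
#' @param decoy_frac Fraction of Medium+Large variants given partial
#'   (sub-threshold) repeat coverage.
#' @param te_class_mix Named proportions over TE classes for driven
#'   variants.
#' @param unit_mix Proportions over simple-repeat unit lengths 1-10.
#' @param n_qtl Number of QTL intervals (six trait categories).
#' @param n_tagged,n_untagged Planted LD-tagged (high r2 e/sQTL SNP
#'   nearby) and untagged (independent nearby SNP) variants.
#' @param tissues Tissue labels for the e/sQTL track.
#' @param missing_rate Per-genotype missing probability.
#' @param qc_fail_frac Fraction of SNP/indel records planted to violate
#'   one hard-filter rule.
#' @param flank Upstream/downstream flank used when spacing genes.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       pops = c("Wuling", "Dabieshan", "Yunba", "Yiling", "Zaobei"),
                       n_per_pop = 20,
                       chroms = c("chr1", "chr2"),
                       chrom_length = 5e6,
                       n_snps = 1500, n_indels = 1200, n_svs = 300,
                       F = 0.02, F_sel = 0.5,
                       n_selection_small = 3, n_selection_large = 2,
                       bin_size = 1e5, hotspot_frac = 0.01,
                       hotspot_multiplier = 20,
                       region_mix = c(intergenic = 0.70, intronic = 0.21,
                                      exonic_splicing = 0.015, UTR5 = 0.003,
                                      UTR3 = 0.004, ncRNA = 0.018,
                                      upstream_downstream = 0.05),
                       te_frac_large = 0.44, simple_frac = 0.06,
                       decoy_frac = 0.15,
                       te_class_mix = c("LINE/L1" = 0.45,
                                        "SINE/Core-RTE" = 0.30,
                                        "LTR/ERV1" = 0.15,
                                        "DNA/hAT-Charlie" = 0.10),
                       unit_mix = c(0.08, 0.30, 0.14, 0.11, 0.09,
                                    0.08, 0.07, 0.06, 0.04, 0.03),
                       n_qtl = 60,
                       n_tagged = 50, n_untagged = 15,
                       tissues = c("blood", "muscle", "mammary", "liver",
                                   "uterus", "conceptus", "kidney", "lung"),
                       missing_rate = 0.02, qc_fail_frac = 0.03,
                       flank = 1000) {
  stopifnot(F > 0, F < 1, F_sel > 0, F_sel < 1,
            hotspot_multiplier >= 1, missing_rate >= 0, missing_rate < 1)
  if (abs(sum(region_mix) - 1) > 1e-8) stop("region_mix must sum to 1")
  if (abs(sum(unit_mix) - 1) > 1e-8) stop("unit_mix must sum to 1")
  cfg <- as.list(environment())
  cfg$layout <- genome_layout(chroms, rep(chrom_length, length(chroms)))
  total <- n_snps + n_indels + n_svs
  if (total > sum(cfg$layout$length) / 50) stop("infeasible config: too many variants for the genome size")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-breed cohort with planted ground truth
#'
#' Generates a complete desk-scale input set — multi-sample VCF-shaped
#' variant table with genotypes, QTL and e/sQTL interval tracks, GFF3-style
#' gene models, RepeatMasker-style repeat annotations for the reference
#' and for inserted (ALT) sequences, and a sample-to-breed table — plus a
#' truth record for every planted feature, so each pipeline stage can be
#' validated closed-loop.
#'
#' Statistical model: ancestral allele frequency `p ~ U(0.05, 0.95)` per
#' locus; per-population frequency `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`
#' (Balding-Nichols, so expected Fst is approximately F); genotypes
#' `~ Binomial(2, p_k)`; genotypes set missing independently at
#' `missing_rate`. Variant positions follow the planted region mix; planted
#' hotspot bins receive extra breakpoints to reach the configured rate
#' multiplier. Identical configurations (including seed) give identical
#' output.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, all external-format files
#'   (VCF, BEDs, GFF3, two `.out` files, pops.tsv, genome.tsv) are written
#'   there and their paths recorded in the result.
#' @return A `sim_cohort` list: `variants` ([variant_table()]), `pops`,
#'   `layout`, `genes` (`gene_model_set`), `qtl`, `eqtl_snps`,
#'   `repeats_ref`, `repeats_alt` (tracks), `truth`, `cfg`, and `paths`
#'   when written.
#' @export
simulate_cohort <- function(cfg = sim_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  layout <- cfg$layout
  samples <- unlist(lapply(cfg$pops, function(p) sprintf("%s_%02d", p, seq_len(cfg$n_per_pop))))
  pops <- data.frame(sample = samples,
                     pop = rep(cfg$pops, each = cfg$n_per_pop),
                     stringsAsFactors = FALSE)

  gm <- sim_gene_models(cfg)
  pools <- region_pools(gm, layout, cfg$flank)

  ## ---- variant skeleton: types, lengths, planted repeat content ---------
  n_small <- round(cfg$n_indels * 0.7)
  n_medium <- cfg$n_indels - n_small
  len_small <- sample(1:10, n_small, replace = TRUE, prob = 1 / (1:10))
  len_medium <- sample(11:50, n_medium, replace = TRUE, prob = 1 / (11:50)^0.5)
  len_large <- pmin(pmax(round(exp(stats::rnorm(cfg$n_svs, log(130), 0.6))), 51), 800)
  vlen <- c(len_small, len_medium, len_large)
  nv <- length(vlen)
  vtype <- sample(c("DEL", "INS"), nv, replace = TRUE, prob = c(0.6, 0.4))
  sizecl <- classify_size(vlen)

  rep_plan <- rep("none", nv)
  med_idx <- which(sizecl == "Medium")
  lar_idx <- which(sizecl == "Large")
  rep_plan[sample(lar_idx, round(cfg$te_frac_large * length(lar_idx)))] <- "te"
  rep_plan[sample(med_idx, round(cfg$simple_frac * length(med_idx)))] <- "simple"
  free <- which(rep_plan == "none" & sizecl != "Small")
  rep_plan[sample(free, round(cfg$decoy_frac * length(free)))] <- "decoy"
  te_class <- rep(NA_character_, nv)
  te_class[rep_plan == "te"] <- sample(names(cfg$te_class_mix),
                                       sum(rep_plan == "te"), replace = TRUE,
                                       prob = cfg$te_class_mix)
  # SINE/Core-RTE driven variants get the 150 bp-peaked length profile
  sine <- which(!is.na(te_class) & te_class == "SINE/Core-RTE")
  vlen[sine] <- pmin(pmax(round(stats::rnorm(length(sine), 140, 10)), 60), 200)
  sizecl <- classify_size(vlen)

  ## ---- positions: region mix + hotspot planting --------------------------
  planted_region <- sample(names(cfg$region_mix), nv, replace = TRUE,
                           prob = cfg$region_mix)
  pos_spans <- matrix(NA_real_, nv, 2)
  chrom <- character(nv)
  for (i in seq_len(nv)) {
    need <- if (vtype[i] == "DEL") vlen[i] else 1
    hit <- place_in_pool(pools[[planted_region[i]]], need)
    if (is.null(hit)) {
      planted_region[i] <- "intergenic"
      hit <- place_in_pool(pools$intergenic, need)
      if (is.null(hit)) stop("intergenic pool exhausted")
    }
    chrom[i] <- hit$chrom
    pos_spans[i, ] <- c(hit$start, if (vtype[i] == "DEL") hit$start + vlen[i] else hit$start)
  }

  # hotspot bins: bins fully inside the intergenic pool, hotspot_frac of all
  bins <- do.call(rbind, lapply(seq_len(nrow(layout)), function(ci) {
    nb <- ceiling(layout$length[ci] / cfg$bin_size)
    data.frame(chrom = layout$chrom[ci], bin = seq_len(nb) - 1)
  }))
  n_bins <- nrow(bins)
  eligible_bins <- which(vapply(seq_len(nrow(bins)), function(j) {
    bs <- bins$bin[j] * cfg$bin_size
    pool <- pools$intergenic
    any(pool$chrom == bins$chrom[j] & pool$start <= bs &
          pool$end >= bs + cfg$bin_size)
  }, logical(1)))
  if (length(eligible_bins) == 0) eligible_bins <- seq_len(n_bins)
  n_hot <- max(1, round(cfg$hotspot_frac * n_bins))
  hot_rows <- sample(eligible_bins, min(n_hot, length(eligible_bins)))
  hot_bins <- bins[hot_rows, , drop = FALSE]

  base_rate <- (nv + sum(vtype == "DEL")) / n_bins  # expected breakpoints/bin
  n_extra_per_bin <- max(1, round(base_rate * (cfg$hotspot_multiplier - 1) / 2))
  extra <- list()
  for (j in seq_len(nrow(hot_bins))) {
    bs <- hot_bins$bin[j] * cfg$bin_size
    # keep extras well inside the bin so DEL end-breakpoints stay in-bin
    s <- bs + sort(sample.int(cfg$bin_size - 2000, n_extra_per_bin)) + 1000
    L <- sample(1:10, n_extra_per_bin, replace = TRUE)
    ty <- sample(c("DEL", "INS"), n_extra_per_bin, replace = TRUE)
    extra[[j]] <- data.frame(chrom = hot_bins$chrom[j], start = s,
                             end = ifelse(ty == "DEL", s + L, s),
                             vtype = ty, length = L, stringsAsFactors = FALSE)
  }
  extra <- do.call(rbind, extra)

  ## ---- assemble INS/DEL records ------------------------------------------
  iv <- data.frame(chrom = c(chrom, extra$chrom),
                   start = c(pos_spans[, 1], extra$start),
                   end = c(pos_spans[, 2], extra$end),
                   vtype = c(vtype, extra$vtype),
                   length = c(vlen, extra$length),
                   planted_region = c(planted_region, rep("intergenic", nrow(extra))),
                   rep_plan = c(rep_plan, rep("none", nrow(extra))),
                   te_class = c(te_class, rep(NA, nrow(extra))),
                   hotspot_extra = c(rep(FALSE, nv), rep(TRUE, nrow(extra))),
                   stringsAsFactors = FALSE)
  iv$size_class <- classify_size(iv$length)
  iv$variant_id <- sprintf("iv%05d", seq_len(nrow(iv)))

  ## ---- SNPs ---------------------------------------------------------------
  snp <- data.frame(chrom = sample(layout$chrom, cfg$n_snps, replace = TRUE,
                                   prob = layout$length))
  snp$start <- floor(stats::runif(cfg$n_snps) * (chrom_length(layout, snp$chrom) - 2)) + 1
  snp <- snp[!duplicated(paste(snp$chrom, snp$start)), , drop = FALSE]
  snp$end <- snp$start + 1
  snp$vtype <- rep("SNP", nrow(snp)); snp$length <- rep(1, nrow(snp))
  snp$variant_id <- sprintf("snp%05d", seq_len(nrow(snp)))

  ## ---- e/sQTL SNPs planted in (or out of) LD with target variants --------
  n_tag_total <- cfg$n_tagged + cfg$n_untagged
  targets <- sample(which(!iv$hotspot_extra), n_tag_total)
  tagged <- targets[seq_len(cfg$n_tagged)]
  untagged <- targets[cfg$n_tagged + seq_len(cfg$n_untagged)]
  esnp <- data.frame(chrom = iv$chrom[targets],
                     start = pmin(pmax(iv$start[targets] +
                                         round(stats::runif(n_tag_total, -2e5, 2e5)), 1),
                                  chrom_length(cfg$layout, iv$chrom[targets]) - 2))
  # keep every SNP position unique so chrom+pos keys are unambiguous
  taken <- paste(snp$chrom, snp$start)
  for (j in seq_len(nrow(esnp))) {
    while (paste(esnp$chrom[j], esnp$start[j]) %in% taken) {
      esnp$start[j] <- esnp$start[j] + 1
    }
    taken <- c(taken, paste(esnp$chrom[j], esnp$start[j]))
  }
  esnp$end <- esnp$start + 1
  esnp$vtype <- rep("SNP", n_tag_total); esnp$length <- rep(1, n_tag_total)
  esnp$variant_id <- sprintf("esnp%04d", seq_len(n_tag_total))
  esnp$kind <- sample(c("eQTL", "sQTL"), n_tag_total, replace = TRUE)
  esnp$tissue <- sample(cfg$tissues, n_tag_total, replace = TRUE)

  ## ---- genotypes ----------------------------------------------------------
  all_ids <- c(iv$variant_id, snp$variant_id, esnp$variant_id)
  n_loci <- length(all_ids)
  F_locus <- rep(cfg$F, n_loci)
  sel_small <- sample(which(iv$size_class %in% c("Small", "Medium") & !iv$hotspot_extra),
                      cfg$n_selection_small)
  sel_large <- sample(which(iv$size_class == "Large"), cfg$n_selection_large)
  F_locus[c(sel_small, sel_large)] <- cfg$F_sel
  names(F_locus) <- all_ids

  anc_p <- stats::runif(n_loci, 0.05, 0.95)
  K <- length(cfg$pops)
  pop_freq <- matrix(NA_real_, n_loci, K, dimnames = list(all_ids, cfg$pops))
  for (k in seq_len(K)) {
    pop_freq[, k] <- stats::rbeta(n_loci, anc_p * (1 - F_locus) / F_locus,
                                  (1 - anc_p) * (1 - F_locus) / F_locus)
  }
  # planted sweeps must be differentiated to be recoverable: redraw the
  # selection-locus frequencies (same Beta model) until the populations
  # actually separate
  for (i in which(F_locus > cfg$F)) {
    tries <- 0
    while (diff(range(pop_freq[i, ])) < 0.4 && tries < 100) {
      pop_freq[i, ] <- stats::rbeta(K, anc_p[i] * (1 - F_locus[i]) / F_locus[i],
                                    (1 - anc_p[i]) * (1 - F_locus[i]) / F_locus[i])
      tries <- tries + 1
    }
  }
  geno <- matrix(NA_integer_, n_loci, length(samples),
                 dimnames = list(all_ids, samples))
  for (k in seq_len(K)) {
    cols <- which(pops$pop == cfg$pops[k])
    geno[, cols] <- stats::rbinom(n_loci * length(cols), 2, pop_freq[, k])
  }

  # planted LD: tagged e/sQTL SNPs copy their target's dosages with a small
  # per-sample error; untagged SNPs keep independent draws
  err <- 0.03
  tag_rows <- match(esnp$variant_id[seq_len(cfg$n_tagged)], all_ids)
  src_rows <- match(iv$variant_id[tagged], all_ids)
  for (j in seq_along(tag_rows)) {
    d <- geno[src_rows[j], ]
    flip <- stats::runif(length(d)) < err
    d[flip] <- stats::rbinom(sum(flip), 2, mean(d) / 2)
    geno[tag_rows[j], ] <- d
  }
  if (cfg$missing_rate > 0) {
    geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA_integer_
  }

  ## ---- QUAL / INFO --------------------------------------------------------
  v <- rbind(iv[c("variant_id", "chrom", "start", "end", "vtype", "length")],
             snp[c("variant_id", "chrom", "start", "end", "vtype", "length")],
             esnp[c("variant_id", "chrom", "start", "end", "vtype", "length")])
  v$pos <- ifelse(v$vtype == "SNP", v$start + 1, v$start)
  nrow_v <- nrow(v)
  v$qual <- round(30 + stats::rexp(nrow_v, 1 / 40), 2)
  gatk <- v$vtype == "SNP" | v$length <= 50
  v$QD <- ifelse(gatk, round(pmax(stats::rnorm(nrow_v, 20, 6), 0.1), 2), NA)
  v$FS <- ifelse(gatk, round(stats::rexp(nrow_v, 1 / 5), 2), NA)
  v$SOR <- ifelse(gatk & v$vtype == "SNP", round(pmax(stats::rnorm(nrow_v, 1.2, 0.4), 0.05), 2), NA)
  v$MQ <- ifelse(gatk & v$vtype == "SNP", round(stats::rnorm(nrow_v, 55, 3), 2), NA)
  v$MQRankSum <- ifelse(gatk & v$vtype == "SNP", round(stats::rnorm(nrow_v, 0, 1.5), 2), NA)
  v$ReadPosRankSum <- ifelse(gatk, round(stats::rnorm(nrow_v, 0, 1.5), 2), NA)
  fail <- sample(which(gatk), round(cfg$qc_fail_frac * sum(gatk)))
  fail_rule <- sample(c("QD", "QUAL", "FS"), length(fail), replace = TRUE)
  v$QD[fail[fail_rule == "QD"]] <- round(stats::runif(sum(fail_rule == "QD"), 0.1, 1.9), 2)
  v$qual[fail[fail_rule == "QUAL"]] <- round(stats::runif(sum(fail_rule == "QUAL"), 5, 29.9), 2)
  v$FS[fail[fail_rule == "FS"]] <- round(stats::runif(sum(fail_rule == "FS"), 201, 400), 2)
  qc_fail_ids <- v$variant_id[fail]

  v <- with_ref_alt(v)
  o <- order(match(v$chrom, layout$chrom), v$pos, v$variant_id)
  v <- v[o, , drop = FALSE]
  rownames(v) <- NULL
  vt <- variant_table(v, geno[v$variant_id, , drop = FALSE])

  ## ---- repeat annotations -------------------------------------------------
  reps <- sim_repeats(iv, cfg)

  ## ---- QTL track ----------------------------------------------------------
  cats <- c("Exterior", "Health", "Meat_and_Carcass", "Milk", "Production",
            "Reproduction")
  qlen <- round(stats::runif(cfg$n_qtl, 2e4, 1.5e5))
  qchr <- sample(layout$chrom, cfg$n_qtl, replace = TRUE, prob = layout$length)
  qstart <- floor(stats::runif(cfg$n_qtl) * (chrom_length(layout, qchr) - qlen))
  qtl <- interval_track(qchr, qstart, qstart + qlen,
                        label = sample(cats, cfg$n_qtl, replace = TRUE),
                        name = "qtl")

  eqtl_track <- interval_track(esnp$chrom, esnp$start, esnp$end,
                               label = esnp$kind, sublabel = esnp$tissue,
                               name = "eqtl_snps")

  truth <- list(
    region = stats::setNames(iv$planted_region, iv$variant_id),
    repeat_plan = iv[c("variant_id", "rep_plan", "te_class")],
    planted_fraction = attr(reps, "planted_fraction"),
    planted_unit = attr(reps, "planted_unit"),
    hotspot_bins = hot_bins,
    hotspot_extra_ids = iv$variant_id[iv$hotspot_extra],
    F_locus = F_locus, anc_p = stats::setNames(anc_p, all_ids),
    pop_freq = pop_freq,
    selection_ids = iv$variant_id[c(sel_small, sel_large)],
    selection_small_ids = iv$variant_id[sel_small],
    selection_large_ids = iv$variant_id[sel_large],
    tagged_ids = iv$variant_id[tagged],
    untagged_ids = iv$variant_id[untagged],
    qc_fail_ids = qc_fail_ids,
    seed = cfg$seed)

  sim <- structure(list(variants = vt, pops = pops, layout = layout,
                        genes = gm, qtl = qtl, eqtl_snps = eqtl_track,
                        repeats_ref = reps$ref, repeats_alt = reps$alt,
                        truth = truth, cfg = cfg),
                   class = "sim_cohort")
  if (!is.null(out_dir)) sim$paths <- write_cohort(sim, out_dir)
  sim
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d variants, %d samples in %d populations, seed %d\n",
              n_variants(x$variants), nrow(x$pops),
              length(unique(x$pops$pop)), x$truth$seed))
  invisible(x)
}

## weighted placement of a span of length L fully inside one pool interval
place_in_pool <- function(pool, L) {
  fit <- pool$end - pool$start - L
  ok <- which(fit >= 0)
  if (length(ok) == 0) return(NULL)
  w <- fit[ok] + 1
  j <- ok[sample.int(length(ok), 1, prob = w)]
  list(chrom = pool$chrom[j],
       start = pool$start[j] + floor(stats::runif(1) * (fit[j] + 1)))
}

## gene models placed left-to-right with generous gaps so every planted
## region class has a pure (single-class) pool
sim_gene_models <- function(cfg) {
  layout <- cfg$layout
  genes <- tx <- exons <- cds <- utr5 <- utr3 <- list()
  gi <- 0L
  for (ci in seq_len(nrow(layout))) {
    cursor <- 5e4
    clen <- layout$length[ci]
    repeat {
      # mostly regular spacing, with occasional gene deserts so that whole
      # 100 kb bins are purely intergenic (hotspot planting needs them)
      gap <- if (stats::runif(1) < 0.25) round(stats::runif(1, 2.5e5, 4.5e5))
             else round(stats::runif(1, 3e4, 8e4))
      cursor <- cursor + gap
      coding <- stats::runif(1) < 0.85
      n_ex <- sample(if (coding) 4:6 else 2:3, 1)
      ex_len <- round(stats::runif(n_ex, 250, 500))
      in_len <- round(stats::runif(max(n_ex - 1, 0), 800, 4000))
      glen <- sum(ex_len) + sum(in_len)
      if (cursor + glen + cfg$flank > clen - 5e4) break
      gi <- gi + 1L
      gid <- sprintf("gene%03d", gi)
      tid <- sprintf("tx%03d", gi)
      strand <- sample(c("+", "-"), 1)
      es <- cursor + c(0, cumsum(ex_len[-n_ex] + in_len))
      ee <- es + ex_len
      genes[[gi]] <- data.frame(gene_id = gid, chrom = layout$chrom[ci],
                                start = cursor, end = cursor + glen,
                                strand = strand)
      tx[[gi]] <- data.frame(tx_id = tid, gene_id = gid,
                             chrom = layout$chrom[ci], start = cursor,
                             end = cursor + glen, strand = strand,
                             coding = coding)
      exons[[gi]] <- data.frame(tx_id = tid, chrom = layout$chrom[ci],
                                start = es, end = ee)
      if (coding) {
        u5 <- 150; u3 <- 200  # UTRs carved from the terminal exons
        if (strand == "+") {
          utr5[[gi]] <- data.frame(tx_id = tid, chrom = layout$chrom[ci],
                                   start = es[1], end = es[1] + u5)
          utr3[[gi]] <- data.frame(tx_id = tid, chrom = layout$chrom[ci],
                                   start = ee[n_ex] - u3, end = ee[n_ex])
          cs <- es; ce <- ee
          cs[1] <- es[1] + u5; ce[n_ex] <- ee[n_ex] - u3
        } else {
          utr5[[gi]] <- data.frame(tx_id = tid, chrom = layout$chrom[ci],
                                   start = ee[n_ex] - u5, end = ee[n_ex])
          utr3[[gi]] <- data.frame(tx_id = tid, chrom = layout$chrom[ci],
                                   start = es[1], end = es[1] + u3)
          cs <- es; ce <- ee
          ce[n_ex] <- ee[n_ex] - u5; cs[1] <- es[1] + u3
        }
        cds[[gi]] <- data.frame(tx_id = tid, chrom = layout$chrom[ci],
                                start = cs, end = ce)
      }
      cursor <- cursor + glen
    }
  }
  cat0 <- function(l) if (length(l) == 0) NULL else do.call(rbind, l)
  gm <- list(genes = cat0(genes), transcripts = cat0(tx),
             exons = cat0(exons), cds = cat0(cds),
             utr5 = cat0(utr5) %||% data.frame(tx_id = character(), chrom = character(), start = numeric(), end = numeric()),
             utr3 = cat0(utr3) %||% data.frame(tx_id = character(), chrom = character(), start = numeric(), end = numeric()))
  gm$introns <- derive_introns(gm$exons)
  class(gm) <- "gene_model_set"
  gm
}

## pure single-class placement pools derived from the constructed models
region_pools <- function(gm, layout, flank) {
  tx <- gm$transcripts
  coding_tx <- tx$tx_id[tx$coding]
  cint <- gm$introns[gm$introns$tx_id %in% coding_tx, , drop = FALSE]
  shrink <- function(d, by) {
    out <- data.frame(chrom = d$chrom, start = d$start + by, end = d$end - by)
    out[out$end > out$start, , drop = FALSE]
  }
  nc_tx <- tx[!tx$coding, , drop = FALSE]
  g <- gm$genes
  upd <- data.frame(chrom = rep(g$chrom, 2),
                    start = c(pmax(g$start - flank, 0), g$end),
                    end = c(g$start, pmin(g$end + flank, chrom_length(layout, g$chrom))))
  flanked <- interval_track(g$chrom, pmax(g$start - flank, 0),
                            pmin(g$end + flank, chrom_length(layout, g$chrom)))
  interg <- shrink(as.data.frame(complement_track(flanked, layout)), 10)
  list(exonic_splicing = gm$cds[c("chrom", "start", "end")],
       UTR5 = gm$utr5[c("chrom", "start", "end")],
       UTR3 = gm$utr3[c("chrom", "start", "end")],
       intronic = shrink(cint[c("chrom", "start", "end")], 2),
       ncRNA = nc_tx[c("chrom", "start", "end")],
       upstream_downstream = shrink(upd, 1),
       intergenic = interg)
}

## REF/ALT strings; symbolic alleles for events > 100 bp
with_ref_alt <- function(v) {
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  n <- nrow(v)
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    if (v$vtype[i] == "SNP") {
      ref[i] <- sample(bases, 1)
      alt[i] <- sample(setdiff(bases, ref[i]), 1)
    } else if (v$length[i] > 100) {
      ref[i] <- sample(bases, 1)
      alt[i] <- paste0("<", v$vtype[i], ">")
    } else if (v$vtype[i] == "DEL") {
      ref[i] <- rand_seq(v$length[i] + 1)
      alt[i] <- substr(ref[i], 1, 1)
    } else {
      alt[i] <- rand_seq(v$length[i] + 1)
      ref[i] <- substr(alt[i], 1, 1)
    }
  }
  v$ref <- ref; v$alt <- alt
  v
}

## repeat annotations: driven variants covered > 0.8 by one element (plus an
## occasional overlapping second hit to exercise union semantics), decoys
## covered < 0.6, background elements kept clear of variant spans
sim_repeats <- function(iv, cfg) {
  ref <- list(); alt <- list(); planted_fraction <- numeric(0)
  planted_unit <- integer(0)
  for (i in seq_len(nrow(iv))) {
    plan <- iv$rep_plan[i]
    if (plan == "none") next
    L <- iv$length[i]
    if (plan == "decoy") {
      f <- stats::runif(1, 0.1, 0.55)
      cls <- sample(c(names(cfg$te_class_mix), "Simple_repeat"), 1)
      nm <- if (cls == "Simple_repeat") "(TG)n" else "rep_bg"
      rows <- data.frame(off = 0, len = max(round(f * L), 1), class = cls, name = nm)
    } else {
      f <- stats::runif(1, 0.85, 0.98)
      cov_len <- max(round(f * L), 1)
      off <- sample.int(L - cov_len + 1, 1) - 1
      if (plan == "simple") {
        unit <- sample(1:10, 1, prob = cfg$unit_mix)
        planted_unit[iv$variant_id[i]] <- unit
        nm <- sprintf("(%s)n", paste(sample(c("A", "C", "G", "T"), unit, replace = TRUE),
                                     collapse = ""))
        rows <- data.frame(off = off, len = cov_len, class = "Simple_repeat", name = nm)
      } else {
        cls <- iv$te_class[i]
        nm <- if (cls == "SINE/Core-RTE") {
          if (stats::runif(1) < 0.98) "BOV-A2" else "BOV-A1"
        } else sub(".*/", "", cls)
        rows <- data.frame(off = off, len = cov_len, class = cls, name = nm)
        if (stats::runif(1) < 0.3 && cov_len > 10) {
          # second, smaller element overlapping the first (union must not
          # double-count); keep it inside the first so coverage is unchanged
          o2 <- off + sample.int(cov_len - 5, 1) - 1
          l2 <- min(sample(5:20, 1), off + cov_len - o2)
          rows <- rbind(rows, data.frame(off = o2, len = l2, class = cls,
                                         name = paste0(nm, "_frag")))
        }
      }
      planted_fraction[iv$variant_id[i]] <- cov_len / L
    }
    if (iv$vtype[i] == "DEL") {
      ref[[length(ref) + 1]] <- data.frame(chrom = iv$chrom[i],
                                           start = iv$start[i] + rows$off,
                                           end = iv$start[i] + rows$off + rows$len,
                                           label = rows$class, sublabel = rows$name)
    } else {
      alt[[length(alt) + 1]] <- data.frame(chrom = iv$variant_id[i],
                                           start = rows$off,
                                           end = rows$off + rows$len,
                                           label = rows$class, sublabel = rows$name)
    }
  }
  cat0 <- function(l, nm) {
    if (length(l) == 0) return(interval_track(name = nm))
    d <- do.call(rbind, l)
    interval_track(d$chrom, d$start, d$end, label = d$label,
                   sublabel = d$sublabel, name = nm)
  }
  ref_t <- cat0(ref, "repeats_ref")
  # background elements on the reference, away from medium/large spans
  nbg <- 300
  bchr <- sample(cfg$layout$chrom, nbg, replace = TRUE)
  blen <- round(stats::runif(nbg, 80, 400))
  bs <- floor(stats::runif(nbg) * (chrom_length(cfg$layout, bchr) - blen))
  bg <- interval_track(bchr, bs, bs + blen,
                       label = sample(names(cfg$te_class_mix), nbg, replace = TRUE),
                       sublabel = "bg")
  spans <- iv[iv$size_class != "Small" & iv$vtype == "DEL", , drop = FALSE]
  if (nrow(spans) > 0) {
    clash <- overlap_pairs(bg, interval_track(spans$chrom, spans$start, spans$end))
    if (nrow(clash) > 0) bg <- bg[-unique(clash$query), , drop = FALSE]
  }
  ref_t <- interval_track(c(ref_t$chrom, bg$chrom), c(ref_t$start, bg$start),
                          c(ref_t$end, bg$end), label = c(ref_t$label, bg$label),
                          sublabel = c(ref_t$sublabel, bg$sublabel),
                          name = "repeats_ref")
  out <- list(ref = ref_t, alt = cat0(alt, "repeats_alt"))
  attr(out, "planted_fraction") <- planted_fraction
  attr(out, "planted_unit") <- planted_unit
  out
}

#' Write a simulated cohort to external-format files
#'
#' Materialises VCF, QTL/e-sQTL BED, GFF3, reference and ALT RepeatMasker
#' `.out`, pops.tsv and genome.tsv so the production readers are exercised
#' end-to-end.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    qtl = file.path(dir, "qtl.bed"),
    eqtl = file.path(dir, "eqtl_snps.bed"),
    gff = file.path(dir, "genes.gff3"),
    rm_ref = file.path(dir, "repeats_ref.out"),
    rm_alt = file.path(dir, "repeats_alt.out"),
    pops = file.path(dir, "pops.tsv"),
    genome = file.path(dir, "genome.tsv"))
  write_vcf(sim$variants, paths$vcf, sim$layout)
  write_bed(sim$qtl, paths$qtl)
  write_bed(sim$eqtl_snps, paths$eqtl)
  write_gff3(sim$genes, paths$gff)
  write_repeatmasker_out(sim$repeats_ref, paths$rm_ref)
  write_repeatmasker_out(sim$repeats_alt, paths$rm_alt)
  utils::write.table(sim$pops, paths$pops, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_genome_layout(sim$layout, paths$genome)
  paths
}

#' Paired dosages from a two-locus haplotype model
#'
#' Draws `2n` haplotypes i.i.d. from the supplied two-locus haplotype
#' frequencies and pairs them into `n` diploids, returning the two dosage
#' vectors. Used to validate composite r-squared against the classical
#' haplotype-based `r2 = D^2 / (pA pa pB pb)`.
#'
#' @param p_hap Numeric length 4, frequencies of haplotypes
#'   (1,1), (1,0), (0,1), (0,0); must sum to 1.
#' @param n Number of diploid individuals.
#' @param seed Optional seed.
#' @return List `a`, `b` of dosage vectors of length `n`.
#' @export
make_ld_block <- function(p_hap, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(p_hap) == 4, abs(sum(p_hap) - 1) < 1e-8, all(p_hap >= 0))
  hap <- sample.int(4, 2 * n, replace = TRUE, prob = p_hap)
  a_allele <- c(1L, 1L, 0L, 0L)[hap]
  b_allele <- c(1L, 0L, 1L, 0L)[hap]
  idx <- matrix(seq_len(2 * n), nrow = 2)
  list(a = a_allele[idx[1, ]] + a_allele[idx[2, ]],
       b = b_allele[idx[1, ]] + b_allele[idx[2, ]])
}
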