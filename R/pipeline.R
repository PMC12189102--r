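#' Run the full analysis pipeline on one configuration
#'
#' Orchestrates simulate -> ingest -> qc -> annotate -> hotspots ->
#' enrichment -> repeats -> fst -> ld as one configured run. The synthetic
#' cohort is written to disk and read back through the production parsers,
#' so every external-format reader is on the validated path. Stages run in
#' dependency order; a failure halts the run. Every output file is
#' checksummed (md5) into a machine-readable run manifest together with the
#' configuration snapshot, seeds and the methodological decisions
#' (estimator names, tie rules, randomization strategy), which makes any
#' silent change in an intermediate file detectable and lets two runs be
#' compared checksum-by-checksum.
#'
#' @param config A list (or path to a YAML file) with optional entries:
#'   `seed` (default 1), `sim` (argument list for [sim_config()]),
#'   `n_perm` (default 100), `fst_pairs` (list of 2-vectors; default all
#'   population pairs), `window`, `step`, `top_frac`, `ld_window`,
#'   `flank`.
#' @param out_dir Output directory for all stage files.
#' @return The run manifest (list), invisibly; all stage outputs are under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  n_perm <- config$n_perm %||% 100
  window <- config$window %||% 5e4
  step <- config$step %||% 2e4
  top_frac <- config$top_frac %||% 0.01
  ld_window <- config$ld_window %||% 1e6
  flank <- config$flank %||% 1000
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stages <- list()
  tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  ## simulate + materialise
  cfg <- do.call(sim_config, c(list(seed = seed), config$sim %||% list()))
  sim <- simulate_cohort(cfg, out_dir = file.path(out_dir, "cohort"))
  stages$simulate <- unlist(sim$paths)

  ## ingest through the production readers
  layout <- read_genome_layout(sim$paths$genome)
  vt <- read_vcf(sim$paths$vcf, layout = layout)
  pops <- utils::read.table(sim$paths$pops, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!setequal(pops$sample, vt$samples)) {
    stop("sample sets differ between VCF and population table")
  }
  qtl <- read_bed(sim$paths$qtl)
  eqtl <- read_bed(sim$paths$eqtl)
  gm <- read_gff_genes(sim$paths$gff)
  rm_ref <- read_repeatmasker_out(sim$paths$rm_ref)
  rm_alt <- read_repeatmasker_out(sim$paths$rm_alt)

  ## qc
  thr <- filter_thresholds()
  hf <- apply_hard_filters(vt, thr)
  indel_mask <- hf$variants$variants$vtype != "SNP" &
    hf$variants$variants$length <= 50
  indels <- proximity_dedup(vt_subset(hf$variants, indel_mask), thr$proximity_bp)
  rest <- vt_subset(hf$variants, !indel_mask)
  qc <- filter_cohort(merge_variant_tables(indels, rest), thr)
  qc$variants$size_class <- ifelse(qc$variants$vtype == "SNP", "SNP",
                                   classify_size(qc$variants$length))
  stages$qc <- tsv(data.frame(rule = names(hf$tally), removed = hf$tally),
                   "qc_hard_filter_tally.tsv")
  stages$qc_table <- tsv(qc$variants[c("variant_id", "chrom", "pos", "vtype",
                                       "length", "size_class", "qual")],
                         "qc_variants.tsv")

  ## region annotation
  nonsnp <- vt_subset(qc, qc$variants$vtype != "SNP")
  regions <- classify_region(nonsnp, gm, layout, flank = flank)
  rsum <- region_summary(regions, nonsnp)
  stages$annotate <- tsv(regions, "region_calls.tsv")
  stages$annotate_summary <- tsv(rsum, "region_summary.tsv")

  ## hotspots
  bins <- count_breakpoints(nonsnp, layout)
  hs <- call_hotspots(bins, top_frac = top_frac)
  hq <- hotspot_qtl_overlap(hs, qtl)
  stages$hotspots <- tsv(hs, "hotspots.tsv")
  write_bed(interval_track(hs$chrom, hs$start, hs$end,
                           label = as.character(hs$count)),
            file.path(out_dir, "hotspots.bed"))
  stages$hotspots_bed <- file.path(out_dir, "hotspots.bed")
  stages$hotspot_qtl <- tsv(hq, "hotspot_qtl_overlap.tsv")

  ## enrichment
  enr <- enrichment_table(nonsnp, qtl, layout, n_perm = n_perm,
                          seed = seed + 1000)
  stages$enrichment <- tsv(enr, "enrichment.tsv")

  ## repeats
  rcalls <- repeat_calls(nonsnp, rm_ref, rm_alt)
  spectrum <- simple_repeat_spectrum(rcalls, nonsnp)
  profile <- te_length_profile(rcalls, nonsnp)
  stages$repeats <- tsv(rcalls, "repeat_calls.tsv")
  stages$repeats_spectrum <- tsv(spectrum[spectrum$count > 0, , drop = FALSE],
                                 "simple_repeat_spectrum.tsv")
  stages$repeats_profile <- tsv(profile, "te_length_profile.tsv")

  ## fst scans
  pairs <- config$fst_pairs %||% utils::combn(unique(pops$pop), 2, simplify = FALSE)
  small_med <- vt_subset(qc, qc$variants$vtype != "SNP" &
                           qc$variants$size_class %in% c("Small", "Medium"))
  large <- vt_subset(qc, qc$variants$size_class == "Large")
  fst_rows <- list(); sel_genes <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "_vs_")
    wc <- wc_fst(small_med, pops, pr)
    win <- windowed_fst(wc, layout, window = window, step = step)
    topw <- top_selection_regions(win, "fst_weighted", top_frac)
    st <- genotype_stats(large, pops)
    f1 <- st[[paste0("freq_", pr[1])]]; f2 <- st[[paste0("freq_", pr[2])]]
    n1 <- 2 * sum(pops$pop == pr[1]); n2 <- 2 * sum(pops$pop == pr[2])
    ok <- !is.na(f1) & !is.na(f2)
    hud <- hudson_fst_freq(f1[ok], n1, f2[ok], n2, components = TRUE)
    lsites <- data.frame(large$variants[ok, c("variant_id", "chrom", "start")],
                         fst = hud$fst)
    lsites$end <- large$variants$end[ok]
    topl <- top_selection_regions(lsites[!is.na(lsites$fst), ], "fst", top_frac)
    gw <- genomewide_fst(wc, hud)
    fst_rows[[key]] <- data.frame(
      pair = key, n_sites_small_medium = sum(wc$defined),
      fst_wc_weighted = gw$wc_weighted, fst_hudson_large = gw$hudson,
      n_windows = nrow(win), n_top_windows = nrow(topw),
      n_top_large = nrow(topl), stringsAsFactors = FALSE)
    sel_genes[[key]] <- union(
      genes_in_regions(topw, gm),
      genes_in_regions(data.frame(chrom = topl$chrom, start = topl$start,
                                  end = pmax(topl$end, topl$start + 1)), gm))
  }
  fst_summary <- do.call(rbind, fst_rows)
  shared <- shared_genes(sel_genes)
  stages$fst <- tsv(fst_summary, "fst_summary.tsv")
  stages$fst_shared_genes <- tsv(shared, "fst_shared_genes.tsv")

  ## ld tagging
  snps <- vt_subset(qc, qc$variants$vtype == "SNP")
  tags <- tag_variants(nonsnp, snps, eqtl, window = ld_window)
  tsum <- tissue_summary(tags, nonsnp)
  stages$ld <- tsv(tags, "ld_tags.tsv")
  stages$ld_tissues <- tsv(tsum, "ld_tissue_summary.tsv")

  ## manifest
  files <- unlist(stages, use.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("svscape")),
    seed = seed,
    config = config,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    stages = names(stages),
    decisions = list(
      breakpoints = "DEL contributes 2 breakpoints (start and end junction), INS 1 (anchor)",
      ranking = "genome-wide top-fraction with ties included at the threshold",
      dedup = "greedy QUAL-descending, ties by position then DEL before INS",
      fst = "Weir-Cockerham (1984) ratio-of-sums for genotypes; Hudson/Bhatia ratio-of-averages for SV frequencies; negative per-site estimates retained",
      ld = "composite (dosage-correlation) r2 over jointly non-missing samples",
      randomization = "uniform per-chromosome, length-preserving"),
    checksums = as.list(tools::md5sum(files))
  )
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Concatenate two variant tables
#'
#' Row-binds records and genotype matrices; the sample sets must match.
#' The result keeps genome order (layout order not required; sorted by
#' chromosome then position).
#'
#' @param a,b [variant_table()]s over the same samples.
#' @return A [variant_table()].
#' @export
merge_variant_tables <- function(a, b) {
  if (!identical(a$samples, b$samples)) stop("sample sets differ")
  common <- intersect(names(a$variants), names(b$variants))
  v <- rbind(a$variants[common], b$variants[common])
  g <- rbind(a$geno, b$geno)
  o <- order(v$chrom, v$pos, v$variant_id)
  variant_table(v[o, , drop = FALSE], g[o, , drop = FALSE])
}
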