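#' Overlap statistic between a query and a reference track
#'
#' `mode = "count"`: number of query elements with at least 1 bp of overlap
#' with the (merged) reference; a zero-width query element (insertion
#' anchor) overlaps iff its anchor point lies inside a reference interval.
#' `mode = "bp"`: total number of query bases covered by the merged
#' reference (zero-width elements contribute 0).
#'
#' @param query An [interval_track()] or [variant_table()].
#' @param reference An [interval_track()].
#' @param mode `"count"` or `"bp"`.
#' @return A single number.
#' @examples
#' q <- interval_track(c("c", "c"), c(0, 20), c(10, 30))
#' r <- interval_track("c", 5, 25)
#' overlap_stat(q, r, "count")  # 2
#' overlap_stat(q, r, "bp")     # 10
#' @export
overlap_stat <- function(query, reference, mode = c("count", "bp")) {
  mode <- match.arg(mode)
  if (inherits(query, "variant_table")) query <- variant_track(query)
  query <- as_track(query)
  cov <- merged_coverage_fun(merge_intervals(reference))
  total <- 0
  for (chr in unique(query$chrom)) {
    cc <- cov[[chr]]
    if (is.null(cc)) next
    qi <- query$chrom == chr
    s <- query$start[qi]; e <- query$end[qi]
    if (mode == "count") {
      e1 <- pmax(e, s + 1)  # anchor point semantics
      total <- total + sum(coverage_at(cc, e1) - coverage_at(cc, s) > 0)
    } else {
      total <- total + sum(coverage_at(cc, e) - coverage_at(cc, s))
    }
  }
  total
}

#' Randomize a track: the permutation null
#'
#' Every element is independently re-placed uniformly at random on its
#' original chromosome with its length preserved (the `randomizeRegions`
#' null of region-overlap permutation testing, not circular rotation).
#' Placements may overlap each other. With a `mask` track, placements
#' overlapping the mask are rejection-sampled.
#'
#' @param query An [interval_track()].
#' @param layout A [genome_layout()].
#' @param mask Optional [interval_track()] of excluded regions.
#' @param seed Optional integer; when given, `set.seed(seed)` first.
#' @return An [interval_track()] with the same widths, chromosomes and
#'   order as `query`.
#' @export
randomize_track <- function(query, layout, mask = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  query <- as_track(query)
  n <- nrow(query)
  if (n == 0) return(query)
  w <- query$end - query$start
  clen <- chrom_length(layout, query$chrom)
  span <- clen - pmax(w, 1)  # start drawn from 0..span (inclusive)
  if (any(span < 0)) stop("element longer than its chromosome")
  new_start <- floor(stats::runif(n) * (span + 1))
  new_start <- pmin(new_start, span)  # guard the measure-zero edge
  if (!is.null(mask)) {
    mcov <- merged_coverage_fun(merge_intervals(mask))
    for (tries in 1:1000) {
      bad <- vapply(seq_len(n), function(i) {
        cc <- mcov[[query$chrom[i]]]
        if (is.null(cc)) return(FALSE)
        s <- new_start[i]; e <- s + max(w[i], 1)
        (coverage_at(cc, e) - coverage_at(cc, s)) > 0
      }, logical(1))
      if (!any(bad)) break
      if (tries == 1000) stop("could not place element(s) outside mask")
      nb <- sum(bad)
      new_start[bad] <- pmin(floor(stats::runif(nb) * (span[bad] + 1)), span[bad])
    }
  }
  interval_track(query$chrom, new_start, new_start + w,
                 label = query$label, sublabel = query$sublabel,
                 name = track_name(query))
}

#' Permutation Z-score overlap test
#'
#' The observed overlap statistic is compared with its distribution over
#' `n_perm` randomizations of the query ([randomize_track()]):
#' `z = (observed - mean) / sd`, with `z > 0` read as enrichment and
#' `z < 0` as depletion. The empirical p-value is one-sided in the
#' direction of departure with the +1 correction,
#' `p = (1 + #{perm at least as extreme}) / (n_perm + 1)`, so it is never
#' zero. When the permutation sd is 0 the result is flagged degenerate and
#' `z` is undefined.
#'
#' @param query An [interval_track()] or [variant_table()].
#' @param reference An [interval_track()].
#' @param layout A [genome_layout()].
#' @param n_perm Number of permutations (default 100).
#' @param mode Overlap statistic, `"count"` or `"bp"`.
#' @param seed Integer seed for the permutation stream (mandatory for
#'   reproducibility; if `NULL` one is drawn and recorded).
#' @param mask Optional mask passed to [randomize_track()].
#' @return A `perm_result` list: `statistic`, `observed`, `perm_values`,
#'   `perm_mean`, `perm_sd`, `z`, `p_empirical`, `direction`, `degenerate`,
#'   `n_perm`, `seed`.
#' @export
permutation_z <- function(query, reference, layout, n_perm = 100,
                          mode = c("count", "bp"), seed = NULL, mask = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 2) stop("n_perm must be >= 2")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  if (inherits(query, "variant_table")) query <- variant_track(query)
  observed <- overlap_stat(query, reference, mode)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    overlap_stat(randomize_track(query, layout, mask = mask), reference, mode)
  }, numeric(1))
  m <- mean(perm); s <- stats::sd(perm)
  degenerate <- !is.finite(s) || s == 0
  upper <- observed >= m
  cnt <- if (upper) sum(perm >= observed) else sum(perm <= observed)
  structure(list(statistic = if (mode == "count") "n_overlaps" else "bp_overlap",
                 observed = observed, perm_values = perm,
                 perm_mean = m, perm_sd = s,
                 z = if (degenerate) NA_real_ else (observed - m) / s,
                 p_empirical = (1 + cnt) / (n_perm + 1),
                 direction = if (upper) "enrichment" else "depletion",
                 degenerate = degenerate, n_perm = n_perm, seed = seed,
                 randomization = "uniform per-chromosome, length-preserving"),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s: observed=%.4g, perm %0.4g +/- %.4g, z=%s, p=%.4g (%s, n_perm=%d)\n",
              x$statistic, x$observed, x$perm_mean, x$perm_sd,
              if (x$degenerate) "undefined" else sprintf("%.3f", x$z),
              x$p_empirical, x$direction, x$n_perm))
  invisible(x)
}

#' Grouped enrichment table
#'
#' Runs [permutation_z()] for every (size class x variant type) group of a
#' variant table against every label of a reference track, the layout a
#' region-overlap screen is usually reported as.
#'
#' @param vt A [variant_table()] (non-SNP records are used; a `size_class`
#'   column is derived if absent).
#' @param track Reference [interval_track()]; one test per distinct
#'   `label` (plus `"all"` for the whole track when it has labels).
#' @param layout A [genome_layout()].
#' @param n_perm,mode,seed Passed to [permutation_z()] (per-test seeds are
#'   derived from `seed`).
#' @return Data frame: one row per (size_class, vtype, track_label) with
#'   observed, perm_mean, perm_sd, z, p_empirical, direction.
#' @export
enrichment_table <- function(vt, track, layout, n_perm = 100,
                             mode = "count", seed = 1) {
  v <- vt$variants
  if (!"size_class" %in% names(v)) {
    v$size_class <- ifelse(v$vtype == "SNP", NA, classify_size(v$length))
  }
  track <- as_track(track)
  labs <- unique(track$label)
  labs <- labs[!is.na(labs)]
  if (length(labs) == 0) labs <- "all"
  groups <- unique(v[v$vtype != "SNP", c("size_class", "vtype")])
  rows <- list(); k <- 0L; test_i <- 0L
  for (gi in seq_len(nrow(groups))) {
    sel <- v$size_class == groups$size_class[gi] & v$vtype == groups$vtype[gi]
    sub <- vt_subset(vt, which(sel))
    for (lab in labs) {
      ref <- if (identical(lab, "all")) track else track[!is.na(track$label) & track$label == lab, , drop = FALSE]
      test_i <- test_i + 1L
      pr <- permutation_z(sub, as_track(ref), layout, n_perm = n_perm,
                          mode = mode, seed = seed + test_i)
      k <- k + 1L
      rows[[k]] <- data.frame(size_class = groups$size_class[gi],
                              vtype = groups$vtype[gi], track_label = lab,
                              n_query = n_variants(sub),
                              observed = pr$observed, perm_mean = pr$perm_mean,
                              perm_sd = pr$perm_sd, z = pr$z,
                              p_empirical = pr$p_empirical,
                              direction = pr$direction,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
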