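#' Repeat (TE / simple-repeat) content of insertions and deletions
#'
#' For each Medium or Large INS/DEL, the fraction of the variant length
#' covered by annotated repeat bases is computed with union (merged
#' interval) semantics: overlapping repeat hits are counted once. Deletions
#' are assessed on their reference span against the reference RepeatMasker
#' annotation; insertions on their own inserted sequence, which requires a
#' parallel `.out` annotation of the ALT sequences (query name = variant
#' id, coordinates along the inserted sequence). Insertions without ALT
#' annotation are skipped and tallied.
#'
#' A variant is repeat-driven when the covered fraction strictly exceeds
#' `min_frac` (default 0.8: "more than 80%" of the variant length).
#' Transposable-element and simple-repeat membership are mutually
#' exclusive, resolved by which category contributes more bases; the driver
#' is the single element (class) contributing the most bases, ties broken
#' lexicographically and flagged. Small variants are outside this module's
#' scope and are excluded up front.
#'
#' @param vt A [variant_table()] (non-SNP records; Small class excluded).
#' @param ref_repeats Reference-genome repeat [interval_track()] from
#'   [read_repeatmasker_out()].
#' @param alt_repeats Optional ALT-sequence repeat track keyed by variant
#'   id, for insertions.
#' @param min_frac Driving threshold on the covered fraction (strict `>`).
#' @return A data frame of repeat calls: `variant_id`, `te_fraction`,
#'   `driver_class`, `driver_name`, `is_te_driven`, `is_simple_repeat`,
#'   `unit_length`, `tie`. Attribute `skipped` tallies excluded records.
#' @export
repeat_calls <- function(vt, ref_repeats, alt_repeats = NULL, min_frac = 0.8) {
  v <- vt$variants
  if (!"size_class" %in% names(v)) {
    v$size_class <- ifelse(v$vtype == "SNP", NA, classify_size(v$length))
  }
  eligible <- v$vtype %in% c("INS", "DEL") & v$size_class %in% c("Medium", "Large")
  skipped <- c(small_or_snp = sum(!eligible), ins_without_alt_annotation = 0L)
  rows <- vector("list", sum(eligible))
  k <- 0L
  for (i in which(eligible)) {
    if (v$length[i] < 1) stop("variant with length < 1: ", v$variant_id[i])
    if (v$vtype[i] == "DEL") {
      span <- c(v$start[i], v$end[i]); chr <- v$chrom[i]; reps <- ref_repeats
    } else {
      if (is.null(alt_repeats)) {
        skipped["ins_without_alt_annotation"] <- skipped["ins_without_alt_annotation"] + 1L
        next
      }
      span <- c(0, v$length[i]); chr <- v$variant_id[i]; reps <- alt_repeats
    }
    k <- k + 1L
    rows[[k]] <- te_fraction_span(v$variant_id[i], chr, span[1], span[2],
                                  v$length[i], reps, min_frac)
  }
  out <- if (k == 0) empty_repeat_calls() else do.call(rbind, rows[seq_len(k)])
  attr(out, "skipped") <- skipped
  out
}

empty_repeat_calls <- function() {
  data.frame(variant_id = character(), te_fraction = numeric(),
             driver_class = character(), driver_name = character(),
             is_te_driven = logical(), is_simple_repeat = logical(),
             unit_length = integer(), tie = logical())
}

SIMPLE_CLASSES <- c("Simple_repeat", "Low_complexity")

te_fraction_span <- function(id, chrom, s, e, vlen, reps, min_frac) {
  ri <- which(reps$chrom == chrom & reps$start < e & reps$end > s)
  if (length(ri) == 0) {
    return(data.frame(variant_id = id, te_fraction = 0,
                      driver_class = "none", driver_name = NA_character_,
                      is_te_driven = FALSE, is_simple_repeat = FALSE,
                      unit_length = NA_integer_, tie = FALSE))
  }
  is_ <- pmax(reps$start[ri], s)
  ie_ <- pmin(reps$end[ri], e)
  contrib <- ie_ - is_
  cls <- ifelse(is.na(reps$label[ri]), "Unknown", reps$label[ri])
  simple <- cls %in% SIMPLE_CLASSES
  union_bp <- function(sel) {
    if (!any(sel)) return(0)
    union_length(is_[sel], ie_[sel])
  }
  frac <- union_bp(rep(TRUE, length(ri))) / vlen
  te_bp <- union_bp(!simple)
  sr_bp <- union_bp(simple)
  category <- if (sr_bp > te_bp) "simple" else "te"
  # driver: single element contributing the most bases (raw intersections)
  best <- max(contrib)
  cands <- which(contrib == best)
  tie <- length(cands) > 1
  pick <- cands[order(cls[cands], reps$sublabel[ri][cands])][1]
  driven <- frac > min_frac
  unit <- if (simple[pick]) simple_repeat_unit(reps$sublabel[ri][pick]) else NA_integer_
  data.frame(variant_id = id, te_fraction = frac,
             driver_class = cls[pick],
             driver_name = reps$sublabel[ri][pick],
             is_te_driven = driven && category == "te",
             is_simple_repeat = driven && category == "simple",
             unit_length = unit, tie = tie, stringsAsFactors = FALSE)
}

## total length of the union of intervals [s_i, e_i)
union_length <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  grp <- cumsum(c(TRUE, s[-1] > cummax(e[-length(e)])))
  sum(tapply(e, grp, max) - tapply(s, grp, min))
}

#' Repeat-covered fraction of a single variant
#'
#' Convenience wrapper around the union-coverage computation for one
#' variant row; see [repeat_calls()] for semantics.
#'
#' @param variant One-row slice of `vt$variants` (a DEL; for an INS pass
#'   the ALT-sequence track and the variant id as chromosome key).
#' @param repeats Repeat [interval_track()].
#' @param min_frac Driving threshold (strict `>`).
#' @return One-row repeat-call data frame.
#' @export
te_fraction <- function(variant, repeats, min_frac = 0.8) {
  if (variant$length < 1) stop("variant with length < 1")
  chr <- if (variant$vtype == "INS") variant$variant_id else variant$chrom
  span <- if (variant$vtype == "INS") c(0, variant$length) else c(variant$start, variant$end)
  te_fraction_span(variant$variant_id, chr, span[1], span[2], variant$length,
                   as_track(repeats), min_frac)
}

#' Parse a simple-repeat unit length from a RepeatMasker name
#'
#' `"(TG)n"` has unit length 2, `"(ATCGA)n"` unit length 5. Names not of
#' this form return `NA`.
#'
#' @param name Character vector of repeat names.
#' @return Integer vector of unit lengths (1-10 expected), `NA` when
#'   unparseable.
#' @export
simple_repeat_unit <- function(name) {
  m <- regmatches(name, regexec("^\\(([ACGTacgt]+)\\)n$", name))
  vapply(m, function(x) if (length(x) == 2) nchar(x[2]) else NA_integer_,
         integer(1))
}

#' Simple-repeat unit-length spectrum
#'
#' Counts of simple-repeat-driven variants per unit length (1-10) by
#' variant type and size class. Calls whose repeat name cannot be parsed
#' are excluded and tallied in the `unparseable` attribute.
#'
#' @param calls Repeat calls from [repeat_calls()].
#' @param vt The [variant_table()] the calls were made on.
#' @return Data frame `unit_length`, `vtype`, `size_class`, `count`.
#' @export
simple_repeat_spectrum <- function(calls, vt) {
  v <- vt$variants
  if (!"size_class" %in% names(v)) {
    v$size_class <- ifelse(v$vtype == "SNP", NA, classify_size(v$length))
  }
  sr <- calls[calls$is_simple_repeat, , drop = FALSE]
  unit <- sr$unit_length
  unparseable <- sum(is.na(unit))
  sr <- sr[!is.na(unit), , drop = FALSE]
  i <- match(sr$variant_id, v$variant_id)
  tab <- as.data.frame(table(unit_length = factor(sr$unit_length, levels = 1:10),
                             vtype = v$vtype[i], size_class = v$size_class[i]),
                       responseName = "count")
  tab$unit_length <- as.integer(as.character(tab$unit_length))
  attr(tab, "unparseable") <- unparseable
  tab
}

#' Variant-length histograms per driving repeat class
#'
#' @param calls Repeat calls from [repeat_calls()] (TE-driven calls are
#'   used).
#' @param vt The [variant_table()] the calls were made on.
#' @param bin_width Histogram bin width in bp (default 10).
#' @return Data frame `driver_class`, `bin_start`, `bin_end`, `count`.
#' @export
te_length_profile <- function(calls, vt, bin_width = 10) {
  te <- calls[calls$is_te_driven, , drop = FALSE]
  if (nrow(te) == 0) {
    return(data.frame(driver_class = character(), bin_start = numeric(),
                      bin_end = numeric(), count = integer()))
  }
  len <- vt$variants$length[match(te$variant_id, vt$variants$variant_id)]
  bin <- floor(len / bin_width) * bin_width
  tab <- as.data.frame(table(driver_class = te$driver_class, bin_start = bin),
                       responseName = "count")
  tab <- tab[tab$count > 0, , drop = FALSE]
  tab$bin_start <- as.numeric(as.character(tab$bin_start))
  tab$bin_end <- tab$bin_start + bin_width
  tab$driver_class <- as.character(tab$driver_class)
  rownames(tab) <- NULL
  tab[c("driver_class", "bin_start", "bin_end", "count")]
}

#' Driver class among contributing repeat elements
#'
#' The driver is the single element contributing the most bases to the
#' variant span; ties are broken lexicographically on class then name and
#' flagged.
#'
#' @param elements Data frame with columns `class`, `name`, `bases`.
#' @return List with `driver_class`, `driver_name`, `tie`.
#' @export
classify_driver <- function(elements) {
  if (nrow(elements) == 0) stop("no contributing elements")
  best <- max(elements$bases)
  cands <- which(elements$bases == best)
  pick <- cands[order(elements$class[cands], elements$name[cands])][1]
  list(driver_class = elements$class[pick],
       driver_name = elements$name[pick],
       tie = length(cands) > 1)
}
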