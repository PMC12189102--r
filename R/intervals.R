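#' Labelled interval tracks
#'
#' The package's one interval container: a data frame of 0-based half-open
#' intervals `[start, end)` with an optional `label` (e.g. QTL trait
#' category, repeat class) and `sublabel` (e.g. tissue, repeat name).
#' External formats (BED, GFF3, RepeatMasker .out, VCF) are converted to
#' this convention once at ingest.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric, 0-based half-open. `start <= end`; zero-width
#'   intervals are allowed (insertion anchor points).
#' @param label,sublabel Optional character annotations, recycled.
#' @param name Track name, kept as an attribute.
#' @return An `interval_track` data frame.
#' @examples
#' interval_track("chr1", 0, 100, label = "Health")
#' @export
interval_track <- function(chrom = character(), start = numeric(),
                           end = numeric(), label = NA_character_,
                           sublabel = NA_character_, name = "track") {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (n > 0) {
    if (!all(c(length(chrom), length(start), length(end)) %in% c(1L, n))) {
      stop("chrom/start/end lengths differ")
    }
    chrom <- rep_len(chrom, n); start <- rep_len(start, n)
    end <- rep_len(end, n)
  }
  if (any(start < 0)) stop("negative start coordinate")
  if (any(end < start)) stop("interval with end < start")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    label = rep_len(as.character(label), n),
                    sublabel = rep_len(as.character(sublabel), n),
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("interval_track", "data.frame")
  out
}

as_track <- function(x, ...) UseMethod("as_track")

#' @export
as_track.interval_track <- function(x, ...) x

#' @export
as_track.data.frame <- function(x, ...) {
  interval_track(x$chrom, x$start, x$end,
                 label = if ("label" %in% names(x)) x$label else NA,
                 sublabel = if ("sublabel" %in% names(x)) x$sublabel else NA)
}

track_name <- function(x) attr(x, "name") %||% "track"

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- interval arithmetic -------------------------------------------------
## Merged-track queries are the hot path of the permutation test, so coverage
## lookups are done with findInterval on merged boundaries rather than per-call
## IRanges objects. Pair enumeration (which query hit which reference) goes
## through IRanges::findOverlaps.

#' Merge overlapping or adjacent intervals of a track
#'
#' @param track An [interval_track()]. Labels are dropped.
#' @return An `interval_track` of disjoint intervals sorted by (chrom, start).
#' @export
merge_intervals <- function(track) {
  track <- as_track(track)
  keep <- track$end > track$start
  track <- track[keep, , drop = FALSE]
  if (nrow(track) == 0) return(interval_track(name = track_name(track)))
  pieces <- lapply(split(track, track$chrom), function(d) {
    o <- order(d$start, d$end)
    s <- d$start[o]; e <- d$end[o]
    grp <- cumsum(c(TRUE, s[-1] > cummax(e[-length(e)])))
    data.frame(chrom = d$chrom[1],
               start = tapply(s, grp, min),
               end = tapply(e, grp, max))
  })
  m <- do.call(rbind, pieces)
  interval_track(m$chrom, m$start, m$end, name = track_name(track))
}

## Coverage function per chromosome from a merged track:
## F(x) = number of covered bases in [0, x)
merged_coverage_fun <- function(merged) {
  by_chr <- split(merged[c("start", "end")], merged$chrom)
  lapply(by_chr, function(d) {
    o <- order(d$start)
    s <- d$start[o]; e <- d$end[o]
    list(s = s, e = e, cum = c(0, cumsum(e - s)))
  })
}

coverage_at <- function(cov, x) {
  # cov: one chromosome's list(s, e, cum); x: vector of positions
  k <- findInterval(x, cov$s)
  out <- numeric(length(x))
  hit <- k >= 1
  kk <- k[hit]
  out[hit] <- cov$cum[kk] + pmin(pmax(x[hit] - cov$s[kk], 0), cov$e[kk] - cov$s[kk])
  out
}

## Overlap pair enumeration between two tracks (>= 1 shared bp, half-open).
## Zero-width query intervals are treated as points [a, a+1) so that an
## insertion anchor "a" hits any interval with start <= a < end.
overlap_pairs <- function(query, reference) {
  query <- as_track(query); reference <- as_track(reference)
  if (nrow(query) == 0 || nrow(reference) == 0) {
    return(data.frame(query = integer(), reference = integer()))
  }
  qs <- query$start; qe <- pmax(query$end, query$start + 1)
  out <- list(); k <- 0L
  for (chr in intersect(unique(query$chrom), unique(reference$chrom))) {
    qi <- which(query$chrom == chr)
    ri <- which(reference$chrom == chr)
    # IRanges is 1-based closed: [start+1, end]
    q <- IRanges::IRanges(qs[qi] + 1, qe[qi])
    r <- IRanges::IRanges(reference$start[ri] + 1, reference$end[ri])
    hits <- IRanges::findOverlaps(q, r)
    if (length(hits) > 0) {
      k <- k + 1L
      out[[k]] <- data.frame(query = qi[S4Vectors_from(hits)],
                             reference = ri[S4Vectors_to(hits)])
    }
  }
  if (k == 0L) data.frame(query = integer(), reference = integer())
  else do.call(rbind, out)
}

## thin indirection so the IRanges accessors are in one place
S4Vectors_from <- function(hits) methods::slot(hits, "from")
S4Vectors_to <- function(hits) methods::slot(hits, "to")

## Complement of a merged track within a layout (the "intergenic" operation).
complement_track <- function(track, layout) {
  m <- merge_intervals(track)
  out <- lapply(seq_len(nrow(layout)), function(i) {
    chr <- layout$chrom[i]; len <- layout$length[i]
    d <- m[m$chrom == chr, , drop = FALSE]
    if (nrow(d) == 0) return(data.frame(chrom = chr, start = 0, end = len))
    s <- c(0, d$end); e <- c(d$start, len)
    keep <- e > s
    data.frame(chrom = chr, start = s[keep], end = e[keep])
  })
  out <- do.call(rbind, out)
  interval_track(out$chrom, out$start, out$end, name = "complement")
}

#' Read a BED file into an interval track
#'
#' BED is 0-based half-open, which is also the package's internal convention,
#' so coordinates pass through unchanged. Column 4 (if present) becomes the
#' `label`, column 5 the `sublabel`; further columns are ignored.
#'
#' @param path Path to a BED3+ file (plain text, tab- or space-separated).
#' @param name Track name; defaults to the file name.
#' @return An [interval_track()].
#' @export
read_bed <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) return(interval_track(name = name))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(!is.finite(start) | !is.finite(end) | start >= end)
  if (length(bad) > 0) {
    stop("malformed BED coordinate at line ", bad[1], " of ", path)
  }
  label <- ifelse(nf >= 4, vapply(fields, function(f) f[4] %||% NA_character_, ""), NA)
  sublabel <- ifelse(nf >= 5, vapply(fields, function(f) if (length(f) >= 5) f[5] else NA_character_, ""), NA)
  interval_track(chrom, start, end, label = label, sublabel = sublabel, name = name)
}

#' Write an interval track as BED
#'
#' Coordinates are written exactly as stored (0-based half-open), so
#' `read_bed(write_bed(x))` round-trips bit-exactly.
#'
#' @param track An [interval_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  track <- as_track(track)
  has_sub <- any(!is.na(track$sublabel))
  has_lab <- has_sub || any(!is.na(track$label))
  cols <- list(track$chrom, format_bp(track$start), format_bp(track$end))
  if (has_lab) cols <- c(cols, list(ifelse(is.na(track$label), ".", track$label)))
  if (has_sub) cols <- c(cols, list(ifelse(is.na(track$sublabel), ".", track$sublabel)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
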