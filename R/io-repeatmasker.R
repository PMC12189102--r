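#' Read a RepeatMasker .out annotation file
#'
#' Parses the standard RepeatMasker `.out` layout (two header lines plus a
#' blank line, then whitespace-separated columns). Query coordinates, which
#' RepeatMasker reports 1-based inclusive, are converted to the internal
#' 0-based half-open convention. The repeat class/family (column 11, e.g.
#' `"LINE/L1"`, `"SINE/Core-RTE"`, `"Simple_repeat"`) becomes the track
#' `label`; the repeat name (column 10, e.g. `"BOV-A2"`, `"(TG)n"`) the
#' `sublabel`.
#'
#' Rows with too few columns are skipped with a warning.
#'
#' @param path Path to a `.out` file.
#' @return An [interval_track()] keyed by query sequence name.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  # header: 2 column-name lines + 1 blank; be tolerant and drop any leading
  # lines that do not start with a numeric SW score
  body <- lines[grepl("^\\s*\\d", lines)]
  if (length(body) == 0) return(interval_track(name = basename(path)))
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  short <- nf < 11
  if (any(short)) {
    warning(sum(short), " truncated row(s) skipped in ", basename(path))
    fields <- fields[!short]
  }
  if (length(fields) == 0) return(interval_track(name = basename(path)))
  col <- function(i) vapply(fields, `[`, "", i)
  qname <- col(5)
  qbegin <- as.numeric(col(6))
  qend <- as.numeric(col(7))
  repname <- col(10)
  repclass <- col(11)
  interval_track(qname, qbegin - 1, qend, label = repclass,
                 sublabel = repname, name = basename(path))
}

#' Write an interval track in RepeatMasker .out layout
#'
#' Counterpart of [read_repeatmasker_out()], used by the synthetic cohort
#' generator so fixtures exercise the production parser. Scores and
#' divergence columns are filled with placeholder values.
#'
#' @param track An [interval_track()] with `label` = repeat class/family and
#'   `sublabel` = repeat name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(track, path) {
  track <- as_track(track)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching  repeat           position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family   begin  end    (left)  ID",
    ""), con)
  if (nrow(track) > 0) {
    w <- track$end - track$start
    writeLines(sprintf(
      "%5d %6.1f %4.1f %4.1f  %s %10d %10d (%d) + %s %s %6d %6d (%d) %d",
      1000L, 10.0, 0.0, 0.0, track$chrom,
      as.integer(track$start + 1), as.integer(track$end), 0L,
      ifelse(is.na(track$sublabel), "rep", track$sublabel),
      ifelse(is.na(track$label), "Unknown", track$label),
      1L, as.integer(w), 0L, seq_len(nrow(track))), con)
  }
  invisible(path)
}
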