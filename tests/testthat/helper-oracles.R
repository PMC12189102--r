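# Independent oracles: deliberately separate, naive transcriptions of the
# definitions, kept free of any code path they are used to check.

# Weir & Cockerham (1984) two-population components, transcribed term by
# term from the published formulas for one biallelic site.
wc_oracle <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
  r <- 2
  n <- c(length(d1), length(d2))
  p <- c(sum(d1) / (2 * n[1]), sum(d2) / (2 * n[2]))
  h <- c(sum(d1 == 1) / n[1], sum(d2 == 1) / n[2])
  n_bar <- mean(n)
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / sum(n)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) * (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc,
       fst = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

hudson_oracle <- function(p1, n1, p2, n2) {
  within1 <- p1 * (1 - p1) / (n1 - 1)
  within2 <- p2 * (1 - p2) / (n2 - 1)
  N <- (p1 - p2)^2 - within1 - within2
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  if (D == 0) NA_real_ else N / D
}

# Exhaustive characterization of the greedy proximity-dedup survivor set:
# the unique subset S that is (i) conflict-free (all pairwise start
# distances > d) and (ii) greedily consistent (every indel not in S lies
# within d of a higher-priority member of S, and no member of S lies within
# d of a higher-priority member of S). Checked over all 2^n subsets.
dedup_oracle <- function(pos, qual, vtype, d) {
  n <- length(pos)
  prio <- order(-qual, pos, vtype != "DEL") # prio[1] = highest priority
  rank <- integer(n); rank[prio] <- seq_len(n)
  valid <- function(S) {
    inS <- logical(n); inS[S] <- TRUE
    if (length(S) >= 2) {
      pr <- combn(S, 2)
      if (any(abs(pos[pr[1, ]] - pos[pr[2, ]]) <= d)) return(FALSE)
    }
    for (i in seq_len(n)) {
      higher <- inS & rank < rank[i]
      conflicted <- any(higher & abs(pos - pos[i]) <= d)
      if (inS[i] && conflicted) return(FALSE)
      if (!inS[i] && !conflicted) return(FALSE)
    }
    TRUE
  }
  hits <- list()
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (valid(S)) hits[[length(hits) + 1]] <- S
  }
  stopifnot(length(hits) == 1) # the characterization is unique
  sort(hits[[1]])
}

# squared Pearson correlation written out longhand
r2_oracle <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  (num / den)^2
}

# per-base union coverage of repeat intervals over a span
union_coverage_oracle <- function(span_start, span_end, rep_start, rep_end) {
  bases <- seq(span_start, span_end - 1)
  covered <- rep(FALSE, length(bases))
  for (j in seq_along(rep_start)) {
    covered <- covered | (bases >= rep_start[j] & bases < rep_end[j])
  }
  sum(covered)
}

# per-base precedence-vote region classification over a toy gene model
region_oracle <- function(s, e, vtype, gm, chrom_len, flank = 1000,
                          splice = 2) {
  lv <- c("exonic_splicing", "UTR5", "UTR3", "intronic", "ncRNA",
          "upstream_downstream", "intergenic")
  base_class <- rep("intergenic", chrom_len)
  paint <- function(d, cls) {
    for (j in seq_len(nrow(d))) {
      idx <- seq(d$start[j] + 1, d$end[j]) # 1-based vector positions
      cur <- base_class[idx]
      base_class[idx] <<- ifelse(match(cls, lv) < match(cur, lv), cls, cur)
    }
  }
  g <- gm$genes
  paint(data.frame(start = pmax(g$start - flank, 0),
                   end = pmin(g$end + flank, chrom_len)), "upstream_downstream")
  nc <- gm$transcripts[!gm$transcripts$coding, , drop = FALSE]
  if (nrow(nc) > 0) paint(nc, "ncRNA")
  coding_tx <- gm$transcripts$tx_id[gm$transcripts$coding]
  ci <- gm$introns[gm$introns$tx_id %in% coding_tx, , drop = FALSE]
  if (nrow(ci) > 0) paint(ci, "intronic")
  if (nrow(gm$utr3) > 0) paint(gm$utr3, "UTR3")
  if (nrow(gm$utr5) > 0) paint(gm$utr5, "UTR5")
  if (nrow(gm$cds) > 0) paint(gm$cds, "exonic_splicing")
  if (nrow(ci) > 0) {
    w <- pmin(splice, ci$end - ci$start)
    paint(data.frame(start = c(ci$start, ci$end - w),
                     end = c(ci$start + w, ci$end)), "exonic_splicing")
  }
  # variant touches bases [s, e) (anchor point -> single base at s)
  touch <- if (vtype == "INS" || e == s) s else seq(s, e - 1)
  classes <- base_class[touch + 1]
  lv[min(match(classes, lv))]
}
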