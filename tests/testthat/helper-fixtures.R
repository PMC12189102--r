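# Shared fixture builders. Everything is generated in code; nothing binary.

toy_layout <- function(len = 1e6, chroms = "chr1") {
  genome_layout(chroms, rep(len, length(chroms)))
}

# quick variant table: computes spans from pos/vtype/length
mk_vt <- function(chrom, pos, vtype, length = 1, qual = 50, geno = NULL,
                  id = NULL, ...) {
  n <- max(base::length(chrom), base::length(pos), base::length(vtype))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  vtype <- rep_len(vtype, n); length <- rep_len(length, n)
  qual <- rep_len(qual, n)
  start <- ifelse(vtype == "SNP", pos - 1, pos)
  end <- ifelse(vtype == "DEL", pos + length, ifelse(vtype == "SNP", pos, pos))
  v <- data.frame(variant_id = id %||% sprintf("v%03d", seq_len(n)),
                  chrom = chrom, pos = pos, start = start, end = end,
                  vtype = vtype, length = length, qual = qual,
                  stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) v[[nm]] <- extra[[nm]]
  variant_table(v, geno)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one small cohort shared across tests (built lazily, once)
.fixture_env <- new.env()
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_cohort(sim_config(
      seed = 42, n_per_pop = 8, n_snps = 400, n_indels = 500, n_svs = 150,
      n_tagged = 25, n_untagged = 8))
  }
  .fixture_env$sim
}

# random toy gene model set on a short chromosome, for annotation oracles
rand_gene_models <- function(chrom_len = 10000, n_genes = 2) {
  genes <- tx <- exons <- cds <- utr5 <- utr3 <- list()
  cursor <- sample(200:600, 1)
  for (gi in seq_len(n_genes)) {
    coding <- runif(1) < 0.7
    n_ex <- sample(2:3, 1)
    ex_len <- sample(80:200, n_ex, replace = TRUE)
    in_len <- sample(60:300, max(n_ex - 1, 0), replace = TRUE)
    glen <- sum(ex_len) + sum(in_len)
    if (cursor + glen > chrom_len - 1500) break
    gid <- sprintf("g%d", gi); tid <- sprintf("t%d", gi)
    es <- cursor + c(0, cumsum(ex_len[-n_ex] + in_len))
    ee <- es + ex_len
    genes[[gi]] <- data.frame(gene_id = gid, chrom = "c", start = cursor,
                              end = cursor + glen, strand = "+")
    tx[[gi]] <- data.frame(tx_id = tid, gene_id = gid, chrom = "c",
                           start = cursor, end = cursor + glen,
                           strand = "+", coding = coding)
    exons[[gi]] <- data.frame(tx_id = tid, chrom = "c", start = es, end = ee)
    if (coding) {
      u5 <- min(40, ex_len[1] - 10); u3 <- min(50, ex_len[n_ex] - 10)
      utr5[[gi]] <- data.frame(tx_id = tid, chrom = "c", start = es[1],
                               end = es[1] + u5)
      utr3[[gi]] <- data.frame(tx_id = tid, chrom = "c",
                               start = ee[n_ex] - u3, end = ee[n_ex])
      cs <- es; ce <- ee
      cs[1] <- es[1] + u5; ce[n_ex] <- ee[n_ex] - u3
      cds[[gi]] <- data.frame(tx_id = tid, chrom = "c", start = cs, end = ce)
    }
    cursor <- cursor + glen + sample(2500:4000, 1)
  }
  empty <- data.frame(tx_id = character(), chrom = character(),
                      start = numeric(), end = numeric())
  cat0 <- function(l) if (length(l) == 0) empty else do.call(rbind, l)
  gm <- list(genes = do.call(rbind, genes), transcripts = do.call(rbind, tx),
             exons = cat0(exons), cds = cat0(cds), utr5 = cat0(utr5),
             utr3 = cat0(utr3))
  gm$introns <- svscape:::derive_introns(gm$exons)
  class(gm) <- "gene_model_set"
  gm
}
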