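test_that("region classification follows feature precedence", {
  layout <- genome_layout("c", 10000)
  # one coding gene: exons [1000,1400) and [2000,2400), UTRs at the ends
  gm <- list(
    genes = data.frame(gene_id = "g1", chrom = "c", start = 1000, end = 2400,
                       strand = "+"),
    transcripts = data.frame(tx_id = "t1", gene_id = "g1", chrom = "c",
                             start = 1000, end = 2400, strand = "+",
                             coding = TRUE),
    exons = data.frame(tx_id = "t1", chrom = "c", start = c(1000, 2000),
                       end = c(1400, 2400)),
    cds = data.frame(tx_id = "t1", chrom = "c", start = c(1100, 2000),
                     end = c(1400, 2300)),
    utr5 = data.frame(tx_id = "t1", chrom = "c", start = 1000, end = 1100),
    utr3 = data.frame(tx_id = "t1", chrom = "c", start = 2300, end = 2400))
  gm$introns <- svscape:::derive_introns(gm$exons)
  class(gm) <- "gene_model_set"

  vt <- mk_vt("c", c(1200, 500, 1700, 1050, 2350, 5000, 1401),
              c("SNP", "SNP", "SNP", "SNP", "SNP", "SNP", "SNP"))
  calls <- classify_region(vt, gm, layout)
  expect_equal(calls$region,
               c("exonic_splicing",      # inside CDS
                 "upstream_downstream",  # 500 bp upstream of TSS
                 "intronic",             # mid-intron
                 "UTR5", "UTR3",
                 "intergenic",           # far away
                 "exonic_splicing"))     # 2 bp splice window into the intron
  expect_equal(calls$gene_ids[1], "g1")
  expect_equal(calls$gene_ids[6], "")

  # DEL spanning exon and intron takes the higher-precedence touch
  del <- mk_vt("c", 1390, "DEL", length = 100, qual = 50)
  expect_equal(classify_region(del, gm, layout)$region, "exonic_splicing")
})

test_that("variant overlapping exon of one gene and intron of another is exonic", {
  layout <- genome_layout("c", 10000)
  gm <- list(
    genes = data.frame(gene_id = c("gA", "gB"), chrom = "c",
                       start = c(1000, 900), end = c(1500, 2500),
                       strand = "+"),
    transcripts = data.frame(tx_id = c("tA", "tB"), gene_id = c("gA", "gB"),
                             chrom = "c", start = c(1000, 900),
                             end = c(1500, 2500), strand = "+",
                             coding = TRUE),
    exons = data.frame(tx_id = c("tA", "tA", "tB", "tB"), chrom = "c",
                       start = c(1000, 1300, 900, 2400),
                       end = c(1100, 1500, 1000, 2500)),
    cds = data.frame(tx_id = c("tA", "tA", "tB", "tB"), chrom = "c",
                     start = c(1000, 1300, 900, 2400),
                     end = c(1100, 1500, 1000, 2500)),
    utr5 = data.frame(tx_id = character(), chrom = character(),
                      start = numeric(), end = numeric()),
    utr3 = data.frame(tx_id = character(), chrom = character(),
                      start = numeric(), end = numeric()))
  gm$introns <- svscape:::derive_introns(gm$exons)
  class(gm) <- "gene_model_set"
  # position 1350: exon of gA, intron of gB
  vt <- mk_vt("c", 1350, "SNP")
  calls <- classify_region(vt, gm, layout)
  expect_equal(calls$region, "exonic_splicing")
  expect_setequal(strsplit(calls$gene_ids, ",")[[1]], c("gA", "gB"))
})

test_that("classification agrees with the per-base precedence oracle", {
  set.seed(21)
  for (rep in 1:30) {
    gm <- rand_gene_models()
    layout <- genome_layout("c", 10000)
    n <- 40
    vtype <- sample(c("SNP", "INS", "DEL"), n, replace = TRUE)
    len <- ifelse(vtype == "DEL", sample(1:300, n, TRUE), sample(1:60, n, TRUE))
    pos <- sample(1:(10000 - 400), n)
    vt <- mk_vt("c", pos, vtype, length = len, qual = 50)
    calls <- classify_region(vt, gm, layout)
    v <- vt$variants
    want <- vapply(seq_len(n), function(i) {
      region_oracle(v$start[i], v$end[i], v$vtype[i], gm, 10000)
    }, "")
    expect_equal(calls$region, want)
  }
})

test_that("region summary rows sum to 100%", {
  sim <- small_sim()
  nonsnp <- vt_subset(sim$variants, sim$variants$variants$vtype != "SNP")
  calls <- classify_region(nonsnp, sim$genes, sim$layout)
  expect_equal(nrow(calls), n_variants(nonsnp))       # exactly one region each
  expect_true(all(calls$region %in% svscape:::REGION_LEVELS))
  rs <- region_summary(calls, nonsnp)
  sums <- rowSums(rs[, setdiff(names(rs), c("size_class", "vtype", "n"))])
  expect_true(all(abs(sums - 100) < 0.01))

  # all-intergenic degenerate case
  far <- mk_vt("c", 5000, "SNP")
  gm0 <- rand_gene_models()
  rs0 <- region_summary(data.frame(variant_id = "v001", region = "intergenic"),
                        far)
  expect_equal(rs0$intergenic, 100)

  # empty input gives an empty table
  empty <- region_summary(data.frame(variant_id = character(),
                                     region = character()),
                          vt_subset(far, 0))
  expect_equal(nrow(empty), 0)
})

test_that("planted region mix is recovered exactly for planted variants", {
  sim <- small_sim()
  nonsnp <- vt_subset(sim$variants, sim$variants$variants$vtype != "SNP")
  calls <- classify_region(nonsnp, sim$genes, sim$layout)
  truth <- sim$truth$region[calls$variant_id]
  expect_equal(calls$region, unname(truth))
})
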