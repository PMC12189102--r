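test_that("dosage r2: exact cases, oracle agreement, invariances", {
  d <- c(0L, 1L, 2L, 0L, 1L, 2L)
  expect_equal(dosage_r2(d, d), 1)
  # worked example against the longhand Pearson computation
  a <- c(0L, 0L, 1L, 1L, 2L, 2L); b <- c(0L, 1L, 0L, 1L, 2L, 2L)
  expect_equal(dosage_r2(a, b), r2_oracle(a, b), tolerance = 1e-12)
  # symmetry and allele-relabeling invariance
  expect_equal(dosage_r2(a, b), dosage_r2(b, a))
  expect_equal(dosage_r2(a, b), dosage_r2(2L - a, b))
  expect_equal(dosage_r2(a, b), dosage_r2(a, 2L - b))
  # monomorphic or too-few-sample sites are undefined
  expect_true(is.na(dosage_r2(rep(1L, 6), a)))
  expect_true(is.na(dosage_r2(c(0L, NA, NA, NA, NA, NA), a)))
  # missing genotypes: only jointly non-missing samples used
  am <- a; am[1] <- NA
  expect_equal(dosage_r2(am, b), r2_oracle(am, b), tolerance = 1e-12)
})

test_that("independently generated loci have near-zero r2", {
  set.seed(41)
  n <- 1e4
  r2 <- replicate(20, dosage_r2(rbinom(n, 2, 0.4), rbinom(n, 2, 0.6)))
  expect_lt(mean(r2), 0.01)
})

test_that("LD categories: closed/half-open boundaries as printed", {
  expect_equal(ld_category(c(0.8, 0.799999, 0.2, 0.199999, 1, 0)),
               c("high", "medium", "medium", "low", "high", "low"))
})

test_that("dosage r2 converges to haplotype r2 = D^2/(pA pa pB pb)", {
  set.seed(42)
  # haplotype frequencies with known D
  pA <- 0.6; pB <- 0.45; D <- 0.12
  p_hap <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
             (1 - pA) * (1 - pB) + D)
  want <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  blk <- make_ld_block(p_hap, 4e4)
  expect_lt(abs(dosage_r2(blk$a, blk$b) - want), 0.02)

  # maximal-D block: r2 -> 1
  blk2 <- make_ld_block(c(0.5, 0, 0, 0.5), 5000, seed = 7)
  expect_equal(dosage_r2(blk2$a, blk2$b), 1)
  # independent loci: mean r2 small
  blk3 <- make_ld_block(c(0.25, 0.25, 0.25, 0.25), 1e4, seed = 8)
  expect_lt(dosage_r2(blk3$a, blk3$b), 0.01)
  # seeded determinism
  expect_identical(make_ld_block(p_hap, 100, seed = 3),
                   make_ld_block(p_hap, 100, seed = 3))
})

test_that("tag_variants finds the best e/sQTL SNP within the window", {
  set.seed(43)
  n <- 40
  vd <- rbinom(n, 2, 0.5)
  samples <- paste0("s", 1:n)
  g <- rbind(v1 = vd, v2 = rbinom(n, 2, 0.5))
  colnames(g) <- samples
  vt <- mk_vt("c", c(50000, 300000), "DEL", length = 60, qual = 50,
              geno = g, id = c("v1", "v2"))
  # SNP a: perfect LD with v1, 10 kb away; SNP b: independent
  sg <- rbind(sA = vd, sB = rbinom(n, 2, 0.5))
  colnames(sg) <- samples
  snps <- mk_vt("c", c(60001, 70001), "SNP", geno = sg, id = c("sA", "sB"))
  track <- interval_track("c", c(60000, 60000, 70000), c(60001, 60001, 70001),
                          label = c("eQTL", "eQTL", "sQTL"),
                          sublabel = c("muscle", "blood", "liver"))
  tags <- tag_variants(vt, snps, track, window = 1e6)
  t1 <- tags[tags$variant_id == "v1" & tags$qtl_kind == "eQTL", ]
  expect_equal(t1$best_snp, "sA")
  expect_equal(t1$max_r2, 1)
  expect_equal(t1$category, "high")
  # tissue union over SNPs achieving the maximum
  expect_equal(t1$tissues, "blood;muscle")

  # out-of-window variants are excluded with a tally
  tags2 <- tag_variants(vt, snps, track, window = 15000)
  expect_false("v2" %in% tags2$variant_id)
  expect_gt(attr(tags2, "untested"), 0)
})

test_that("tissue summary proportions sum to 1 within groups", {
  sim <- small_sim()
  nonsnp <- vt_subset(sim$variants, sim$variants$variants$vtype != "SNP")
  snps <- vt_subset(sim$variants, sim$variants$variants$vtype == "SNP")
  tags <- tag_variants(nonsnp, snps, sim$eqtl_snps, window = 5e5)
  expect_true(all(tags$category %in% c("high", "medium", "low")))
  ts <- tissue_summary(tags, nonsnp)
  grp <- paste(ts$tissue, ts$qtl_kind, ts$size_class)
  sums <- tapply(ts$proportion, grp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # planted tag pairs (dosages copied with 3% per-sample error over 40
  # samples) sit far above the planted-untagged controls; most clear the
  # high-LD cut despite the small-sample noise in r2
  planted <- sim$truth$tagged_ids
  hit <- tags[tags$variant_id %in% planted, ]
  best <- tapply(hit$max_r2, hit$variant_id, max)
  expect_gt(mean(best >= 0.8), 0.8)
  expect_gt(min(best), 0.5)
  un <- tags[tags$variant_id %in% sim$truth$untagged_ids, ]
  ubest <- tapply(un$max_r2, un$variant_id, max)
  expect_lt(mean(ubest), 0.2)
})
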