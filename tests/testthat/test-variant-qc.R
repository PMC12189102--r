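test_that("size classes partition lengths at the stated boundaries", {
  expect_equal(classify_size(c(1, 10, 11, 50, 51, 5000)),
               c("Small", "Small", "Medium", "Medium", "Large", "Large"))
  # every length maps to exactly one class
  cls <- classify_size(1:500)
  expect_true(all(cls %in% c("Small", "Medium", "Large")))
  expect_error(classify_size(0), ">= 1")
})

test_that("hard filters fire per rule, skip missing INFO, tally rejections", {
  vt <- mk_vt("c", c(100, 200, 300, 400), c("SNP", "SNP", "DEL", "DEL"),
              length = c(1, 1, 5, 5), qual = c(50, 31, 60, 60),
              QD = c(1.9, NA, 5, NA), FS = c(10, NA, 200.0, NA))
  res <- apply_hard_filters(vt)
  # SNP with QD = 1.9 removed; SNP with no INFO but QUAL 31 retained;
  # indel with FS exactly 200.0 retained (rule is strict >)
  expect_equal(res$variants$variants$variant_id, c("v002", "v003", "v004"))
  expect_equal(unname(res$tally["snp_QD"]), 1L)
  expect_equal(sum(res$tally), 1L)

  # boundary: indel FS just above threshold is removed
  vt2 <- mk_vt("c", 100, "DEL", length = 5, qual = 60, FS = 200.01)
  expect_equal(n_variants(apply_hard_filters(vt2)$variants), 0)
})

test_that("proximity dedup resolves chains greedily by QUAL", {
  vt <- mk_vt("c", c(100, 105, 112), "DEL", length = 2,
              qual = c(50, 60, 40))
  out <- proximity_dedup(vt, 10)
  expect_equal(out$variants$pos, 105)

  # gap of 20 > 10: both survive regardless of QUAL
  vt2 <- mk_vt("c", c(100, 120), "INS", length = 2, qual = c(10, 90))
  expect_equal(n_variants(proximity_dedup(vt2, 10)), 2)

  # empty in, empty out
  expect_equal(n_variants(proximity_dedup(vt_subset(vt, 0), 10)), 0)

  # different chromosomes never conflict
  vt3 <- mk_vt(c("c1", "c2"), c(100, 105), "DEL", length = 2, qual = c(5, 6))
  expect_equal(n_variants(proximity_dedup(vt3, 10)), 2)
})

test_that("proximity dedup is idempotent and leaves no close pair", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    vt <- mk_vt("c", sample(1:200, n), sample(c("DEL", "INS"), n, TRUE),
                length = sample(1:20, n, TRUE),
                qual = round(runif(n, 20, 90), 1))
    once <- proximity_dedup(vt, 10)
    twice <- proximity_dedup(once, 10)
    expect_identical(twice$variants, once$variants)
    pos <- sort(once$variants$pos)
    if (length(pos) > 1) expect_true(all(diff(pos) > 10))
  }
})

test_that("genotype stats: maf over non-missing chromosomes, strict filters", {
  # 50 diploids, one heterozygote: maf = 1/100 = 0.01, which fails "> 0.01"
  g <- matrix(0L, 1, 50, dimnames = list("v001", paste0("s", 1:50)))
  g[1, 1] <- 1L
  vt <- mk_vt("c", 1000, "DEL", length = 60, qual = 50, geno = g)
  st <- genotype_stats(vt)
  expect_equal(st$maf, 0.01)
  expect_equal(n_variants(filter_cohort(vt)), 0)

  # all hom-alt: maf = 0
  g2 <- matrix(2L, 1, 10, dimnames = list("v001", paste0("s", 1:10)))
  vt2 <- mk_vt("c", 1000, "INS", length = 5, qual = 50, geno = g2)
  expect_equal(genotype_stats(vt2)$maf, 0)

  # 3 of 10 missing: missing_rate = 0.3 fails the strict "below 30%" SV rule
  g3 <- matrix(c(rep(1L, 7), rep(NA, 3)), 1, 10,
               dimnames = list("v001", paste0("s", 1:10)))
  vt3 <- mk_vt("c", 1000, "DEL", length = 80, qual = 50, geno = g3)
  expect_equal(genotype_stats(vt3)$missing_rate, 0.3)
  expect_equal(n_variants(filter_cohort(vt3)), 0)

  # SV passing both bounds is retained
  g4 <- matrix(c(rep(1L, 5), rep(0L, 15)), 1, 20,
               dimnames = list("v001", paste0("s", 1:20)))
  vt4 <- mk_vt("c", 1000, "DEL", length = 80, qual = 50, geno = g4)
  expect_equal(n_variants(filter_cohort(vt4)), 1)

  # indel with missing_rate exactly 0.1 removed (strict < 0.1)
  g5 <- matrix(c(rep(1L, 9), NA), 1, 10, dimnames = list("v001", paste0("s", 1:10)))
  vt5 <- mk_vt("c", 1000, "DEL", length = 5, qual = 50, geno = g5)
  expect_equal(n_variants(filter_cohort(vt5)), 0)

  # per-population frequencies
  pops <- data.frame(sample = paste0("s", 1:10),
                     pop = rep(c("A", "B"), each = 5))
  g6 <- matrix(c(rep(2L, 5), rep(0L, 5)), 1, 10,
               dimnames = list("v001", paste0("s", 1:10)))
  vt6 <- mk_vt("c", 1000, "DEL", length = 5, qual = 50, geno = g6)
  st6 <- genotype_stats(vt6, pops)
  expect_equal(st6$freq_A, 1)
  expect_equal(st6$freq_B, 0)

  # all-missing variant flagged undefined
  g7 <- matrix(NA_integer_, 1, 4, dimnames = list("v001", paste0("s", 1:4)))
  vt7 <- mk_vt("c", 1000, "DEL", length = 5, qual = 50, geno = g7)
  expect_false(genotype_stats(vt7)$defined)
})

test_that("cohort filtering is monotone: no retained variant violates a bound", {
  sim <- small_sim()
  vt <- sim$variants
  out <- filter_cohort(vt)
  st <- genotype_stats(out)
  sc <- out$variants$size_class
  large <- !is.na(sc) & sc == "Large"
  expect_true(all(st$missing_rate[!large] < 0.1))
  expect_true(all(st$missing_rate[large] < 0.3))
  expect_true(all(st$maf[large] > 0.01))
  expect_lte(n_variants(out), n_variants(vt))
})
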