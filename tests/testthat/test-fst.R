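test_that("Weir-Cockerham per-site estimator: fixation, symmetry, identity", {
  # complete fixation between populations
  expect_equal(wc_fst_site(rep(0L, 10), rep(2L, 10))$fst, 1)
  # identical samples in both populations: no among-pop variance, fst <= 0
  d <- c(2L, 1L, 0L, 1L)
  expect_lte(wc_fst_site(d, d)$fst, 0)
  # symmetric under swapping populations
  d1 <- c(2L, 1L, 2L, 0L, 1L); d2 <- c(0L, 1L, 0L, 0L, 1L)
  f12 <- wc_fst_site(d1, d2); f21 <- wc_fst_site(d2, d1)
  expect_equal(f12$fst, f21$fst)
  expect_equal(f12$a, f21$a)
  # monomorphic across both populations: undefined and flagged
  mono <- wc_fst_site(rep(0L, 5), rep(0L, 5))
  expect_false(mono$defined)
  expect_true(is.na(mono$fst))
  # too few non-missing diploids is an error
  expect_error(wc_fst_site(c(1L, NA, NA), c(0L, 1L, 2L)), ">= 2")
})

test_that("wc_fst_site and vectorised wc_fst match the direct oracle", {
  set.seed(31)
  for (rep in 1:200) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    d1 <- rbinom(n1, 2, runif(1, 0.05, 0.95))
    d2 <- rbinom(n2, 2, runif(1, 0.05, 0.95))
    want <- wc_oracle(d1, d2)
    got <- wc_fst_site(d1, d2)
    expect_equal(got$a, want$a, tolerance = 1e-12)
    expect_equal(got$b, want$b, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
    if (!is.na(want$fst)) expect_equal(got$fst, want$fst, tolerance = 1e-12)
  }
  # the matrix path gives the same components as the scalar path, with
  # missing genotypes excluded
  set.seed(32)
  g <- matrix(sample(c(0:2, NA), 50 * 20, TRUE, prob = c(.3, .3, .3, .1)),
              50, 20, dimnames = list(sprintf("v%03d", 1:50), paste0("s", 1:20)))
  vt <- mk_vt("c", seq(100, by = 100, length.out = 50), "SNP", geno = g)
  pops <- data.frame(sample = paste0("s", 1:20), pop = rep(c("A", "B"), each = 10))
  res <- wc_fst(vt, pops, c("A", "B"))
  for (i in seq_len(50)) {
    d1 <- g[i, 1:10]; d2 <- g[i, 11:20]
    if (sum(!is.na(d1)) < 2 || sum(!is.na(d2)) < 2) next
    want <- wc_oracle(d1, d2)
    expect_equal(res$a[i], want$a, tolerance = 1e-12)
    if (res$defined[i]) expect_equal(res$fst[i], want$fst, tolerance = 1e-12)
  }
})

test_that("Hudson frequency Fst: exact values, limits, oracle agreement", {
  expect_equal(hudson_fst_freq(1, 40, 0, 40), 1)
  expect_equal(hudson_fst_freq(0, 40, 1, 40), 1)
  # p1 = p2 at large n: estimator tends to 0
  expect_equal(hudson_fst_freq(0.3, 1e7, 0.3, 1e7), 0, tolerance = 1e-5)
  # both fixed for the same allele: undefined
  expect_true(is.na(hudson_fst_freq(0, 10, 0, 10)))
  expect_error(hudson_fst_freq(1.2, 10, 0.5, 10), "frequencies")
  set.seed(33)
  for (rep in 1:200) {
    p1 <- runif(1); p2 <- runif(1)
    n1 <- sample(4:200, 1); n2 <- sample(4:200, 1)
    expect_equal(hudson_fst_freq(p1, n1, p2, n2),
                 hudson_oracle(p1, n1, p2, n2), tolerance = 1e-12)
  }
})

test_that("windowed Fst equals brute-force per-window recomputation", {
  set.seed(34)
  layout <- genome_layout("c", 3e5)
  n <- 100
  g <- matrix(rbinom(n * 40, 2, runif(n * 40, 0.1, 0.9)), n, 40,
              dimnames = list(sprintf("v%03d", 1:n), paste0("s", 1:40)))
  vt <- mk_vt("c", sort(sample(1:(3e5 - 10), n)), "DEL", length = 5, geno = g)
  pops <- data.frame(sample = paste0("s", 1:40), pop = rep(c("A", "B"), each = 20))
  sites <- wc_fst(vt, pops, c("A", "B"))
  win <- windowed_fst(sites, layout, window = 5e4, step = 2e4)
  expect_true(all(win$n_sites >= 1))
  d <- sites[sites$defined, ]
  for (j in seq_len(nrow(win))) {
    inw <- d$start >= win$start[j] & d$start < win$start[j] + 5e4
    expect_equal(win$n_sites[j], sum(inw))
    expect_equal(win$fst_weighted[j],
                 sum(d$a[inw]) / sum(d$a[inw] + d$b[inw] + d$c[inw]))
    expect_equal(win$fst_mean[j], mean(d$fst[inw]))
  }
  # a window holding a single site reports that site's fst
  one <- windowed_fst(sites[1, ], layout)
  expect_equal(unique(one$fst_weighted), sites$fst[1])
  # additivity: one window covering everything equals pooled components
  all_in <- windowed_fst(sites, genome_layout("c", 3e5), window = 3e5,
                         step = 3e5)
  expect_equal(all_in$fst_weighted[1], sum(d$a) / sum(d$a + d$b + d$c))
})

test_that("top selection regions use the floor(k) + ties rule", {
  x <- data.frame(chrom = "c", start = 1:500 * 100, end = 1:500 * 100 + 50,
                  fst_weighted = seq(0.5, 0.002, length.out = 500))
  top <- top_selection_regions(x, "fst_weighted", 0.01)
  expect_equal(nrow(top), 5)
  x$fst_weighted <- c(rep(0.5, 8), seq(0.4, 0.01, length.out = 492))
  expect_equal(nrow(top_selection_regions(x, "fst_weighted", 0.01)), 8)
})

test_that("genes in regions and shared genes across pairs", {
  gm <- list(genes = data.frame(gene_id = c("g1", "g2", "g3"), chrom = "c",
                                start = c(100, 5000, 9000),
                                end = c(200, 5100, 9100), strand = "+"))
  reg <- data.frame(chrom = "c", start = c(150, 4000), end = c(300, 5050))
  expect_equal(genes_in_regions(reg, gm), c("g1", "g2"))
  expect_equal(genes_in_regions(reg[0, ], gm), character())

  sh <- shared_genes(list(p1 = c("g1", "g2"), p2 = c("g2", "g3"),
                          p3 = c("g2")))
  expect_equal(sh$gene_id, "g2")
  expect_equal(sh$n_pairs, 3L)
  expect_equal(nrow(shared_genes(list(p1 = "g1", p2 = "g3"))), 0)
})

test_that("genome-wide aggregates recover the generating F", {
  cfg <- sim_config(seed = 77, pops = c("P1", "P2"), n_per_pop = 30,
                    n_snps = 0, n_indels = 1500, n_svs = 500,
                    n_selection_small = 0, n_selection_large = 0,
                    n_tagged = 0, n_untagged = 0, F = 0.05,
                    missing_rate = 0)
  sim <- simulate_cohort(cfg)
  pops <- sim$pops
  wc <- wc_fst(sim$variants, pops, c("P1", "P2"))
  st <- genotype_stats(sim$variants, pops)
  ok <- !is.na(st$freq_P1) & !is.na(st$freq_P2)
  hud <- hudson_fst_freq(st$freq_P1[ok], 60, st$freq_P2[ok], 60,
                         components = TRUE)
  gw <- genomewide_fst(wc, hud)
  # 2000 loci: looser bound than the 5000-locus recovery check elsewhere
  expect_lt(abs(gw$wc_weighted - 0.05), 0.015)
  expect_lt(abs(gw$hudson - 0.05), 0.015)
})
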