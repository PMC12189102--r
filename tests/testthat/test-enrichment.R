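test_that("overlap_stat counts elements and bases, half-open with anchors", {
  q <- interval_track(c("c", "c"), c(0, 20), c(10, 30))
  r <- interval_track("c", 5, 25)
  expect_equal(overlap_stat(q, r, "count"), 2)
  expect_equal(overlap_stat(q, r, "bp"), 10)

  # disjoint tracks
  r2 <- interval_track("c", 100, 200)
  expect_equal(overlap_stat(q, r2, "count"), 0)
  expect_equal(overlap_stat(q, r2, "bp"), 0)

  # insertion anchor: point-in-interval, contributes 0 bp
  ins <- mk_vt("c", 5, "INS", length = 40, qual = 50)
  r3 <- interval_track("c", 0, 10)
  expect_equal(overlap_stat(ins, r3, "count"), 1)
  expect_equal(overlap_stat(ins, r3, "bp"), 0)
  # anchor exactly at the (exclusive) end does not overlap
  ins2 <- mk_vt("c", 10, "INS", length = 40, qual = 50)
  expect_equal(overlap_stat(ins2, r3, "count"), 0)

  # overlapping reference intervals are merged before bp counting
  q2 <- interval_track("c", 0, 100)
  r4 <- interval_track("c", c(10, 30), c(50, 70))
  expect_equal(overlap_stat(q2, r4, "bp"), 60)
})

test_that("overlap_stat agrees with IRanges on random tracks", {
  set.seed(5)
  for (rep in 1:25) {
    nq <- sample(1:30, 1); nr <- sample(1:30, 1)
    qs <- sample(0:500, nq); qe <- qs + sample(1:50, nq, TRUE)
    rs <- sample(0:500, nr); re <- rs + sample(1:50, nr, TRUE)
    q <- interval_track("c", qs, qe); r <- interval_track("c", rs, re)
    ir_q <- IRanges::IRanges(qs + 1, qe)
    ir_r <- IRanges::reduce(IRanges::IRanges(rs + 1, re))
    expect_equal(overlap_stat(q, r, "count"),
                 sum(IRanges::countOverlaps(ir_q, ir_r) > 0))
    # bp is per query element (query elements are not merged)
    bp_want <- sum(vapply(seq_along(ir_q), function(i) {
      sum(IRanges::width(IRanges::intersect(ir_q[i], ir_r)))
    }, numeric(1)))
    expect_equal(overlap_stat(q, r, "bp"), bp_want)
  }
})

test_that("randomize_track preserves chromosome and length, is seeded", {
  layout <- genome_layout(c("c1", "c2"), c(1e6, 2e6))
  q <- interval_track(c("c1", "c1", "c2"), c(0, 100, 5000),
                      c(50, 400, 5000))  # includes a zero-width anchor
  r1 <- randomize_track(q, layout, seed = 7)
  r2 <- randomize_track(q, layout, seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$chrom, q$chrom)
  expect_equal(r1$end - r1$start, q$end - q$start)
  expect_true(all(r1$start >= 0))
  expect_true(all(r1$end <= chrom_length(layout, r1$chrom)))

  # masked placement avoids the mask
  mask <- interval_track("c1", 0, 9e5)
  rm <- randomize_track(q[1:2, ], layout, mask = mask, seed = 1)
  expect_true(all(rm$start >= 9e5))
  # element longer than its chromosome is an error
  expect_error(randomize_track(interval_track("c1", 0, 2e6), layout), "longer")
})

test_that("randomized starts are uniform over the chromosome", {
  layout <- genome_layout("c", 1e6)
  q <- interval_track("c", 0, 1000)
  set.seed(123)
  starts <- vapply(1:10000, function(i) randomize_track(q, layout)$start,
                   numeric(1))
  # chi-square GOF over deciles of the feasible start range
  brk <- seq(0, 1e6 - 1000, length.out = 11)
  cnt <- table(cut(starts, brk, include.lowest = TRUE))
  expect_gt(stats::chisq.test(cnt)$p.value, 0.01)
})

test_that("permutation_z equals a brute-force loop with the same seed", {
  layout <- genome_layout("c", 1e5)
  set.seed(2)
  qs <- sample(0:9e4, 15); rs <- sample(0:9e4, 20)
  q <- interval_track("c", qs, qs + sample(10:500, 15, TRUE), name = "q")
  r <- interval_track("c", rs, rs + sample(100:2000, 20, TRUE), name = "r")
  pr <- permutation_z(q, r, layout, n_perm = 25, mode = "count", seed = 99)
  set.seed(99)
  brute <- vapply(1:25, function(i) {
    overlap_stat(randomize_track(q, layout), r, "count")
  }, numeric(1))
  expect_equal(pr$perm_values, brute)
  expect_equal(pr$observed, overlap_stat(q, r, "count"))
  expect_equal(pr$z, (pr$observed - mean(brute)) / sd(brute))
  expect_equal(pr$p_empirical,
               (1 + if (pr$observed >= mean(brute)) sum(brute >= pr$observed)
                    else sum(brute <= pr$observed)) / 26)
})

test_that("planted enrichment and depletion give correctly signed z", {
  layout <- genome_layout("c", 1e6)
  set.seed(3)
  # enrichment: query identical to a sparse reference
  ref <- interval_track("c", seq(0, 9e5, by = 1e5), seq(0, 9e5, by = 1e5) + 2000)
  pr <- permutation_z(ref, ref, layout, n_perm = 50, seed = 4)
  expect_gt(pr$z, 3)
  expect_equal(pr$direction, "enrichment")

  # depletion: query constructed outside a dense reference
  dense <- interval_track("c", 0, 8e5)
  outside <- interval_track("c", seq(800100, 990000, by = 10000),
                            seq(800100, 990000, by = 10000) + 50)
  pd <- permutation_z(outside, dense, layout, n_perm = 50, seed = 5)
  expect_lt(pd$z, -3)
  expect_equal(pd$direction, "depletion")

  # degenerate: reference covers everything, sd = 0, z undefined, p reported
  all_ref <- interval_track("c", 0, 1e6)
  dg <- permutation_z(outside, all_ref, layout, n_perm = 20, seed = 6)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$z))
  expect_true(is.finite(dg$p_empirical))
})
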