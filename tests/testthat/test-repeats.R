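test_that("te_fraction: union coverage, strict 80% boundary", {
  # DEL of length 100 covered [0, 81) -> 0.81, driven
  vt <- mk_vt("c", 1000, "DEL", length = 100, qual = 50)
  reps <- interval_track("c", 1000, 1081, label = "LINE/L1", sublabel = "L1")
  call <- te_fraction(vt$variants[1, ], reps)
  expect_equal(call$te_fraction, 0.81)
  expect_true(call$is_te_driven)

  # coverage exactly 80 of 100 -> 0.80 is NOT "more than 80%"
  reps80 <- interval_track("c", 1000, 1080, label = "LINE/L1", sublabel = "L1")
  call80 <- te_fraction(vt$variants[1, ], reps80)
  expect_equal(call80$te_fraction, 0.80)
  expect_false(call80$is_te_driven)

  # two overlapping LINE hits [0,60) and [40,90): union 90, not 110
  reps2 <- interval_track("c", c(1000, 1040), c(1060, 1090),
                          label = "LINE/L1", sublabel = c("L1a", "L1b"))
  expect_equal(te_fraction(vt$variants[1, ], reps2)$te_fraction, 0.9)

  # no overlap at all
  reps3 <- interval_track("c", 5000, 5100, label = "LINE/L1", sublabel = "L1")
  call3 <- te_fraction(vt$variants[1, ], reps3)
  expect_equal(call3$te_fraction, 0)
  expect_equal(call3$driver_class, "none")
})

test_that("union coverage equals per-base counting on random toys", {
  set.seed(9)
  for (rep in 1:100) {
    L <- sample(20:200, 1)
    s0 <- sample(0:1000, 1)
    vt <- mk_vt("c", s0, "DEL", length = L, qual = 50)
    nr <- sample(1:6, 1)
    rs <- s0 - 20 + sample(0:(L + 40), nr, replace = TRUE)
    re <- rs + sample(1:80, nr, replace = TRUE)
    reps <- interval_track("c", pmax(rs, 0), pmax(re, 1), label = "LINE/L1",
                           sublabel = "L1")
    got <- te_fraction(vt$variants[1, ], reps)$te_fraction
    want <- union_coverage_oracle(s0, s0 + L, reps$start, reps$end) / L
    expect_equal(got, want)
  }
})

test_that("driver classification: most bases wins, ties lexicographic", {
  expect_equal(classify_driver(data.frame(class = c("LINE/L1", "SINE/Core-RTE"),
                                          name = c("L1", "BOV-A2"),
                                          bases = c(70, 20)))$driver_class,
               "LINE/L1")
  tie <- classify_driver(data.frame(class = c("SINE/Core-RTE", "LINE/L1"),
                                    name = c("BOV-A2", "L1"),
                                    bases = c(50, 50)))
  expect_equal(tie$driver_class, "LINE/L1")  # lexicographically first
  expect_true(tie$tie)
})

test_that("simple repeat unit lengths parse from RepeatMasker names", {
  expect_equal(simple_repeat_unit(c("(TG)n", "(ATCGA)n", "(A)n", "L1_BT")),
               c(2L, 5L, 1L, NA_integer_))
})

test_that("INS content uses ALT-sequence annotation; small variants excluded", {
  vt <- mk_vt("c", c(100, 300, 500), c("INS", "INS", "DEL"),
              length = c(200, 30, 5), qual = 50, id = c("i1", "i2", "d1"))
  alt <- interval_track("i1", 0, 190, label = "SINE/Core-RTE", sublabel = "BOV-A2")
  ref <- interval_track("c", 0, 1, label = "LINE/L1", sublabel = "L1")
  calls <- repeat_calls(vt, ref, alt_repeats = alt)
  expect_equal(calls$variant_id, c("i1", "i2"))  # small DEL excluded
  expect_equal(calls$te_fraction[1], 0.95)
  expect_true(calls$is_te_driven[1])
  expect_equal(calls$te_fraction[2], 0)  # i2 has no ALT annotation rows

  # without an ALT .out, insertions are skipped with a tally
  calls2 <- repeat_calls(vt, ref)
  expect_equal(nrow(calls2), 0)
  expect_equal(unname(attr(calls2, "skipped")["ins_without_alt_annotation"]), 2L)
})

test_that("planted repeat content is recovered closed-loop", {
  sim <- small_sim()
  calls <- repeat_calls(sim$variants, sim$repeats_ref, sim$repeats_alt)
  plan <- sim$truth$repeat_plan
  m <- merge(calls, plan, by = "variant_id")
  te <- m[m$rep_plan == "te", ]
  sr <- m[m$rep_plan == "simple", ]
  no <- m[m$rep_plan %in% c("none", "decoy"), ]
  expect_gt(mean(te$is_te_driven), 0.95)
  expect_gt(mean(sr$is_simple_repeat), 0.95)
  expect_lt(mean(no$is_te_driven | no$is_simple_repeat), 0.05)
  # driven variants recover their planted class
  ok <- te$is_te_driven
  expect_true(all(te$driver_class[ok] == te$te_class[ok]))
  # is_te_driven is monotone in te_fraction
  expect_true(all(m$te_fraction[m$is_te_driven | m$is_simple_repeat] > 0.8))
  expect_true(all(!(m$is_te_driven & m$is_simple_repeat)))

  # unit-length spectrum reproduces the planted units exactly
  spec <- simple_repeat_spectrum(calls, sim$variants)
  by_unit <- tapply(spec$count, spec$unit_length, sum)
  planted_units <- table(factor(sim$truth$planted_unit, levels = 1:10))
  recovered_ids <- calls$variant_id[calls$is_simple_repeat]
  expect_equal(unname(as.integer(by_unit)),
               unname(as.integer(table(factor(
                 sim$truth$planted_unit[names(sim$truth$planted_unit) %in% recovered_ids],
                 levels = 1:10)))))

  # SINE/Core-RTE length profile peaks in the 120-150 bp range
  prof <- te_length_profile(calls, sim$variants, bin_width = 10)
  sine <- prof[prof$driver_class == "SINE/Core-RTE", ]
  modal <- sine$bin_start[which.max(sine$count)]
  expect_gte(modal, 120)
  expect_lte(modal, 150)
})
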