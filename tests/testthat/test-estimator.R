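test_that("the rate is mutants per transformant per doubling", {
  rec <- make_record(sucrose = 10, plain = 1e6, doublings = 20)
  est <- lof_rate(rec)
  expect_equal(est$rate_per_doubling, 10 / 1e6 / 20)
  expect_equal(est$rate_per_doubling, 5e-7)
  expect_false(est$bdl_flag)
  # exactness: the rate times its denominators recovers the mutant count
  expect_equal(est$rate_per_doubling * est$transformant_cfu_net *
                 est$doublings, est$mutant_cfu_net)
})

test_that("per-bp and percent-per-kb conversions follow the x1000 x100 rule", {
  expect_equal(per_bp_to_percent_per_kb(7.9e-9), 0.00079)
  expect_equal(percent_per_kb_to_per_bp(0.58), 5.8e-6)
  # round trip is the identity
  x <- c(1e-9, 7.9e-9, 5.8e-6, 0.3)
  expect_equal(percent_per_kb_to_per_bp(per_bp_to_percent_per_kb(x)), x)
  rec <- make_record(sucrose = 10, plain = 1e6, doublings = 20)
  est <- lof_rate(rec, region_length_bp = 1533)
  expect_equal(est$rate_per_bp, est$rate_per_doubling / 1533)
  expect_equal(est$rate_percent_per_kb, est$rate_per_bp * 1e5)
})

test_that("zero net sucrose counts get the 0.5-CFU floor and a BDL flag", {
  est <- lof_rate(make_record(sucrose = 0, plain = 1e5, doublings = 10))
  expect_true(est$bdl_flag)
  expect_equal(est$mutant_cfu_net, 0.5)
  expect_equal(est$rate_per_doubling, 0.5 / 1e5 / 10)
  expect_gt(est$rate_per_doubling, 0)
  # control exceeding the sample clamps to zero and then floors
  est2 <- lof_rate(make_record(sucrose = 2, plain = 1e5, nc_sucrose = 5,
                               doublings = 10))
  expect_true(est2$bdl_flag)
  expect_equal(est2$rate_per_doubling, est$rate_per_doubling)
})

test_that("degenerate replicates are rejected", {
  expect_error(lof_rate(make_record(sucrose = 5, plain = 0, doublings = 10)),
               class = "sutox_degenerate_replicate")
  expect_error(lof_rate(make_record(sucrose = 5, plain = 10, nc_plain = 10,
                                    doublings = 10)),
               class = "sutox_degenerate_replicate")
  expect_error(lof_rate(make_record(sucrose = 5, plain = 100,
                                    doublings = 0)),
               class = "sutox_degenerate_replicate")
})

test_that("rate is monotone in mutants, transformants and doublings", {
  base <- lof_rate(make_record(sucrose = 10, plain = 1e5, doublings = 10))
  more_mut <- lof_rate(make_record(sucrose = 20, plain = 1e5,
                                   doublings = 10))
  more_trn <- lof_rate(make_record(sucrose = 10, plain = 2e5,
                                   doublings = 10))
  more_dbl <- lof_rate(make_record(sucrose = 10, plain = 1e5,
                                   doublings = 20))
  expect_gt(more_mut$rate_per_doubling, base$rate_per_doubling)
  expect_lt(more_trn$rate_per_doubling, base$rate_per_doubling)
  expect_lt(more_dbl$rate_per_doubling, base$rate_per_doubling)
})

test_that("rate is invariant to a shared dilution of all plates", {
  for (dil in c(10, 100, 1000)) {
    a <- lof_rate(make_record(sucrose = 12, plain = 3000, nc_sucrose = 2,
                              nc_plain = 5, doublings = 15))
    b <- lof_rate(make_record(sucrose = 12, plain = 3000, nc_sucrose = 2,
                              nc_plain = 5, doublings = 15, dil = dil))
    expect_equal(b$rate_per_doubling, a$rate_per_doubling)
    # and to a shared plated fraction
    cc <- lof_rate(make_record(sucrose = 12, plain = 3000, nc_sucrose = 2,
                               nc_plain = 5, doublings = 15, frac = 0.25))
    expect_equal(cc$rate_per_doubling, a$rate_per_doubling)
  }
})

test_that("estimate_rates vectorizes lof_rate over a schema table", {
  df <- rbind(make_assay_row(rep = "r1", sucrose = 10, plain = 1000,
                             doublings = 10),
              make_assay_row(rep = "r2", sucrose = 0, plain = 1000,
                             doublings = 10))
  est <- estimate_rates(df)
  expect_equal(nrow(est), 2)
  expect_equal(est$rate_per_doubling[1], 10 / 1000 / 10)
  expect_true(est$bdl_flag[2])
  expect_equal(est$rate_per_doubling[2], 0.5 / 1000 / 10)
})

test_that("fold changes are group means over the reference mean", {
  est <- make_rate_table(list(MBI = c(1, 1, 1) * 0.00079,
                              Q5 = c(1, 1, 1) * 0.066,
                              Taq = c(2, 2.6) * 1.15))
  fc <- fold_changes(est, "MBI")
  expect_equal(fc[["MBI"]], 1)
  expect_equal(fc[["Q5"]], 0.066 / 0.00079)
  expect_equal(round(fc[["Q5"]]), 84)
  expect_equal(fc[["Taq"]], mean(c(2, 2.6) * 1.15) / 0.00079)
  expect_error(fold_changes(est, "nope"), class = "sutox_invalid_input")
})

test_that("well-separated groups give tiny Dunnett p, agreeing with a
           permutation oracle; equal means give p near 1", {
  set.seed(42)
  sep <- make_rate_table(list(
    ref = 1 + rnorm(3, sd = 0.01),
    hi = 10 + rnorm(3, sd = 0.01),     # >10 within-group SDs away
    hi2 = 25 + rnorm(3, sd = 0.01)))
  cmp <- compare_groups(sep, "ref")
  expect_lt(cmp$anova_p, 1e-4)
  expect_true(all(cmp$per_group_adjusted_p < 1e-4))
  expect_equal(cmp$fold_changes[["ref"]], 1)
  set.seed(43)
  p_perm <- perm_maxt_p(sep, "ref", B = 500)
  expect_true(all(p_perm <= 0.05))
  # null case: equal means, nonzero variance
  set.seed(44)
  null <- make_rate_table(list(ref = 5 + rnorm(4), other = 5 + rnorm(4)))
  cmp0 <- compare_groups(null, "ref")
  expect_gt(cmp0$per_group_adjusted_p[["other"]], 0.2)
  p0 <- perm_maxt_p(null, "ref", B = 500)
  expect_gt(p0[["other"]], 0.2)
})

test_that("comparison rejects degenerate or underpowered designs", {
  const <- make_rate_table(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_error(compare_groups(const, "a"),
               class = "sutox_degenerate_input")
  tiny <- make_rate_table(list(a = c(1, 2), b = 3))
  expect_error(compare_groups(tiny, "a"),
               class = "sutox_insufficient_replicates")
  one <- make_rate_table(list(a = c(1, 2)))
  expect_error(compare_groups(one, "a"), class = "sutox_invalid_input")
})

test_that("group summaries count replicates and BDL events", {
  df <- rbind(make_assay_row(group = "A", rep = "r1", sucrose = 10),
              make_assay_row(group = "A", rep = "r2", sucrose = 0),
              make_assay_row(group = "B", rep = "r1", sucrose = 40))
  s <- summarize_groups(estimate_rates(df), reference_group = "A")
  expect_equal(s$n, c(2, 1))
  expect_equal(s$n_bdl, c(1, 0))
  expect_equal(s$fold_change[s$group == "A"], 1)
})
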