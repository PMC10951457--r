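test_that("zero mutation rate yields pure exponential wild-type growth", {
  cfg <- sim_config(method = "pcr", true_rate_per_bp = 0, n_cycles = 12,
                    initial_molecules = 3, transformants_mean = 10)
  set.seed(1)
  out <- simulate_replication(cfg)
  expect_equal(out$mutant, 0)
  expect_equal(out$wildtype, 3 * 2^12)
  expect_equal(out$realized_doublings, 12)
})

test_that("LOF is absorbing: a certain-mutation copy event converts both
           daughters and mutants never revert", {
  cfg <- sim_config(method = "pcr", true_rate_per_bp = 1,
                    region_length_bp = 1, n_cycles = 1,
                    initial_molecules = 1, transformants_mean = 10)
  set.seed(1)
  out <- simulate_replication(cfg)
  expect_equal(out$wildtype, 0)
  expect_equal(out$mutant, 2)
  # further cycles only amplify mutants
  cfg5 <- sim_config(method = "pcr", true_rate_per_bp = 1,
                     region_length_bp = 1, n_cycles = 5,
                     initial_molecules = 1, transformants_mean = 10)
  set.seed(1)
  out5 <- simulate_replication(cfg5)
  expect_equal(out5$wildtype, 0)
  expect_equal(out5$mutant, 2^5)
})

test_that("population counts stay non-negative integers that conserve the
           branching totals", {
  cfg <- sim_config(method = "rca", true_rate_per_bp = 1e-5, n_cycles = 15,
                    initial_molecules = 7, per_cycle_efficiency = 0.7,
                    transformants_mean = 10)
  for (s in 1:20) {
    set.seed(s)
    out <- simulate_replication(cfg)
    total <- out$wildtype + out$mutant
    expect_true(out$wildtype >= 0 && out$mutant >= 0)
    expect_equal(total, round(total))
    expect_true(total >= 7 && total <= 7 * 2^15)
    expect_equal(out$realized_doublings, log2(total / 7))
  }
})

test_that("simulated mean mutant fraction matches the closed-form
           expectation within Monte-Carlo error", {
  cfg <- sim_config(method = "pcr", true_rate_per_bp = 3e-6,
                    n_cycles = 10, initial_molecules = 20,
                    transformants_mean = 10)
  expected <- expected_mutant_fraction(cfg)
  set.seed(2024)
  fracs <- replicate(1000, {
    out <- simulate_replication(cfg)
    out$mutant / (out$mutant + out$wildtype)
  })
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * se)
})

test_that("the closed-form oracle enforces its restricted domain", {
  expect_equal(expected_mutant_fraction(
    sim_config(true_rate_per_bp = 0, n_cycles = 10)), 0)
  q <- 1 - (1 - 1e-6)^1533
  expect_equal(expected_mutant_fraction(
    sim_config(true_rate_per_bp = 1e-6, n_cycles = 20)),
    1 - (1 - q)^20)
  expect_error(expected_mutant_fraction(
    sim_config(true_rate_per_bp = 1e-6, per_cycle_efficiency = 0.9)),
    class = "sutox_unsupported_configuration")
  expect_error(expected_mutant_fraction(
    sim_config(true_rate_per_bp = 5e-4, n_cycles = 5)),
    class = "sutox_unsupported_configuration")
})

test_that("plating draws have the right means and honor the sampling guard", {
  cfg <- sim_config(method = "pcr", transformants_mean = 1e6,
                    background_mean_sucrose = 0, background_mean_plain = 0)
  set.seed(7)
  draws <- replicate(1000, {
    p <- simulate_plating(wildtype = 1e8 - 1e4, mutant = 1e4, cfg)
    c(p$sucrose_cfu, p$plain_cfu)
  })
  # sucrose mean ~ transformants_mean x mutant fraction = 100
  se_suc <- sd(draws[1, ]) / sqrt(ncol(draws))
  expect_lt(abs(mean(draws[1, ]) - 100), 3 * se_suc)
  se_plain <- sd(draws[2, ]) / sqrt(ncol(draws))
  expect_lt(abs(mean(draws[2, ]) - 1e6), 3 * se_plain)
  # guard: expected transformants above 1% of the population
  expect_error(simulate_plating(wildtype = 5e7, mutant = 0, cfg),
               class = "sutox_sampling_guard")
  expect_error(simulate_plating(0, 0, cfg), class = "sutox_invalid_input")
})

test_that("a run that would blow past the population cap aborts with advice", {
  cfg <- sim_config(method = "pcr", n_cycles = 40, initial_molecules = 1000,
                    transformants_mean = 10)
  set.seed(1)
  expect_error(simulate_replication(cfg), class = "sutox_resolution_limit")
})

test_that("simulate_assay is deterministic given config and seed", {
  cfg <- sim_config(n_cycles = 12, n_replicates = 3,
                    transformants_mean = 1e4, seed = 99)
  a <- simulate_assay(cfg)
  b <- simulate_assay(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$realized_doublings, b$realized_doublings)
  c2 <- simulate_assay(sim_config(n_cycles = 12, n_replicates = 3,
                                  transformants_mean = 1e4, seed = 100))
  expect_false(identical(a$records, c2$records))
})

test_that("emitted records reproduce realized doublings through the mass
           back-computation", {
  for (method in c("in_vivo", "pcr")) {
    cfg <- sim_config(method = method, n_cycles = 14, n_replicates = 2,
                      initial_molecules = 1, transformants_mean = 100,
                      seed = 5)
    sim <- simulate_assay(cfg)
    est <- estimate_rates(sim$records)
    expect_equal(est$doublings, sim$realized_doublings, tolerance = 1e-9)
  }
})

test_that("a mutation-free, background-free assay is entirely BDL at the
           half-count floor", {
  cfg <- sim_config(method = "pcr", true_rate_per_bp = 0, n_cycles = 16,
                    initial_molecules = 100, transformants_mean = 1e4,
                    background_mean_sucrose = 0, background_mean_plain = 0,
                    n_replicates = 6, seed = 11)
  est <- estimate_rates(simulate_assay(cfg)$records)
  expect_true(all(est$bdl_flag))
  expect_true(all(est$mutant_cfu_net == 0.5))
  expect_true(all(est$rate_per_doubling > 0))
  expect_equal(est$rate_per_doubling,
               0.5 / est$transformant_cfu_net / est$doublings)
})

test_that("the estimator recovers the true per-doubling LOF probability
           from simulated assays", {
  mu <- 1.3046e-6                       # q = mu over 1,533 bp ~ 2e-3
  cfg <- sim_config(method = "rca", true_rate_per_bp = mu, n_cycles = 20,
                    initial_molecules = 500, transformants_mean = 1e6,
                    background_mean_sucrose = 0, background_mean_plain = 0,
                    n_replicates = 10, seed = 7)
  sim <- simulate_assay(cfg)
  est <- estimate_rates(sim$records)
  q_true <- sim$truth$per_copy_lof_prob
  expect_lt(abs(mean(est$rate_per_doubling) - q_true) / q_true, 0.05)
})
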