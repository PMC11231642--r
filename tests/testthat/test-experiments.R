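test_that("single-module nearest-neighbour runs are constant", {
  dt <- cities13()
  r <- run_experiment(experiment_config("single-nn", runs = 10,
                                        master_seed = 7), dt)
  expect_true(all(r$best_per_run == 8131))
  expect_equal(r$sd, 0)
  expect_equal(r$mean, 8131)
  expect_equal(r$optimum, 7293)
  expect_equal(r$fraction_optimal, 0)
})

test_that("experiments are reproducible and flag the runs=1 degenerate SD", {
  dt <- random_distance_table(8, c(10, 300), seed = 61)
  cfg <- experiment_config("bank-position", bank_size = 64, runs = 5,
                           master_seed = 99)
  a <- run_experiment(cfg, dt)
  b <- run_experiment(cfg, dt)
  expect_identical(a$best_per_run, b$best_per_run)
  one <- run_experiment(experiment_config("bank-position", bank_size = 64,
                                          runs = 1, master_seed = 99), dt)
  expect_false(one$sd_defined)
  expect_equal(one$sd, 0)
  expect_equal(one$mean, one$best_per_run)
})

test_that("per-run bank best never exceeds the deterministic total", {
  dt <- cities13()
  r <- run_experiment(experiment_config("bank-position", bank_size = 128,
                                        runs = 20, master_seed = 5), dt)
  expect_true(all(r$best_per_run <= 8131))
  expect_true(all(r$best_per_run >= r$optimum))
})

test_that("bigger banks do better in expectation", {
  dt <- cities13()
  small <- run_experiment(experiment_config("bank-position",
                                            bank_size = 1024, runs = 40,
                                            master_seed = 11), dt)
  big <- run_experiment(experiment_config("bank-position",
                                          bank_size = 4096, runs = 40,
                                          master_seed = 12), dt)
  expect_lt(mean(big$best_per_run), mean(small$best_per_run))
  expect_gte(big$fraction_optimal, small$fraction_optimal)
})

test_that("a weight sweep reproduces the collapse and the mid-range optimum", {
  dt <- cities13()
  sw <- weight_sweep(c(1, 4, 30), dt, bank_size = 256, master_seed = 3,
                     runs = 3)
  det <- tour_totals(dt, 1, 1, "deterministic-nn")$best_total
  # weight 30: no randomness anywhere, bank equals nearest-neighbour
  expect_equal(sw$best[sw$weight == 30 & sw$variant == "bank-position"],
               det)
  expect_equal(sw$best[sw$weight == 30 & sw$variant == "single-random"],
               det)
  # mid-range weights beat the near-uniform weight 1 for the bank
  expect_lt(sw$best[sw$weight == 4 & sw$variant == "bank-position"],
            sw$best[sw$weight == 1 & sw$variant == "bank-position"])
})

test_that("the Welch one-tailed test matches its closed form", {
  # identical samples: symmetric null
  x <- c(1, 2, 3, 4)
  r <- welch_one_tailed(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 0.5)

  # vs a zero-variance sample: equals the one-sample t-test closed form
  set.seed(71)
  a <- rnorm(30, 95, 4)
  b <- rep(100, 30)
  r2 <- welch_one_tailed(a, b)
  tstat <- (mean(a) - 100) / (sd(a) / sqrt(30))
  expect_equal(r2$statistic, tstat, tolerance = 1e-12)
  expect_equal(r2$p.value, pt(tstat, 29), tolerance = 1e-12)

  # general case: agrees with the Welch-Satterthwaite closed form
  set.seed(72)
  y <- rnorm(25, 10, 2)
  z <- rnorm(40, 11, 5)
  r3 <- welch_one_tailed(y, z)
  se2 <- var(y) / 25 + var(z) / 40
  tref <- (mean(y) - mean(z)) / sqrt(se2)
  dfref <- se2^2 / ((var(y) / 25)^2 / 24 + (var(z) / 40)^2 / 39)
  expect_equal(r3$statistic, tref, tolerance = 1e-10)
  expect_equal(r3$df, dfref, tolerance = 1e-10)
  expect_equal(r3$p.value, pt(tref, dfref), tolerance = 1e-10)

  expect_error(welch_one_tailed(rep(1, 5), rep(2, 5)), "zero variance")
})
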