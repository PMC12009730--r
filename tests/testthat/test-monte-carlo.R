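test_that("body-weight sampling follows the population weights", {
  expect_identical(sample_body_weight(bw_point_table(70), 50),
                   rep(70, 50))
  two <- tibble::tibble(weight_kg = c(60, 90),
                        population_weight = c(1, 3))
  set.seed(5)
  draws <- sample_body_weight(two, 1e5)
  # binomial oracle: P(90) = 0.75, SE = sqrt(.75*.25/1e5) ~ 0.0014
  expect_lt(abs(mean(draws == 90) - 0.75), 0.01)
  # closed-form expectation of any fixture table
  tab <- tibble::tibble(weight_kg = c(50, 70, 95, 120),
                        population_weight = c(5, 10, 4, 1))
  set.seed(6)
  d <- sample_body_weight(tab, 1e5)
  expected <- sum(tab$weight_kg * tab$population_weight) /
    sum(tab$population_weight)
  expect_lt(abs(mean(d) - expected), 3 * sd(d) / sqrt(1e5))
  expect_error(sample_body_weight(tab[0, ], 1), "table")
})

test_that("exposure-factor sampling is an empirical bootstrap", {
  # a singleton pool is NOT treated as 1:n
  expect_identical(sample_exposure_factor(174, 10), rep(174, 10))
  set.seed(8)
  d <- sample_exposure_factor(c(0, 10), 1e5)
  expect_lt(abs(mean(d) - 5), 3 * 5 / sqrt(1e5))
  pool <- c(2, 7, 13, 21, 30)
  set.seed(9)
  d <- sample_exposure_factor(pool, 1e5)
  freq <- table(d) / 1e5
  se <- sqrt(0.2 * 0.8 / 1e5)
  expect_true(all(abs(freq - 0.2) < 3 * se + 1e-9))
  expect_error(sample_exposure_factor(numeric(0), 1, "winter/weeding"),
               "winter/weeding")
})

test_that("task-rate perturbation stays within the uniform band", {
  set.seed(10)
  d <- sample_task_rate(45.25, 2, 0.2, 1e5)
  expect_true(all(d >= 45.25 * 1.8 & d <= 45.25 * 2.2))
  expect_identical(sample_task_rate(45.25, 2, 0, 5), rep(90.5, 5))
  set.seed(12)
  d <- sample_task_rate(45.25, 0.5, 0.2, 1e5)
  expect_lt(abs(mean(d) - 22.625), 3 * sd(d) / sqrt(1e5))
  expect_error(sample_task_rate(45.25, 0.5, 0.6, 1), "positive")
})

test_that("degenerate configs collapse to the empirical dose bit-for-bit", {
  cfg <- simulation_config(
    n_growers = 200, seed = 42, method = 2, season = "spring",
    bw_table = bw_point_table(80), pools = 174,
    rate_perturbation_halfwidth = 0
  )
  sim <- run_simulation(cfg)
  expected <- add_method2(400, 45.25, 1.375, 174, 80)$add_total
  expect_identical(sim$draws$add_total, rep(expected, 200))
  # method 1 with an all-zero pool gives all-zero doses
  cfg1 <- simulation_config(n_growers = 100, seed = 1, method = 1,
                            season = "fall", bw_table = bw_point_table(70),
                            pools = 0)
  expect_identical(run_simulation(cfg1)$draws$add_total, rep(0, 100))
  # method 3: single-value pools + zero halfwidth
  pools3 <- as.list(setNames(c(10, 0, 20, 5, 30, 0), meso_activities()))
  cfg3 <- simulation_config(n_growers = 150, seed = 3, method = 3,
                            season = "summer",
                            bw_table = bw_point_table(75), pools = pools3,
                            rate_perturbation_halfwidth = 0)
  rates <- build_rate_set()
  sim3 <- run_simulation(cfg3, rates)
  expected3 <- add_method3(400, rates,
                           unlist(pools3)[meso_activities()],
                           BW = 75)$add_total
  expect_identical(sim3$draws$add_total, rep(expected3, 150))
})

test_that("identical config and seed reproduce identical draws", {
  tab <- generate_bodyweight_table("weighted_sample", seed = 2)
  pools <- as.list(setNames(list(c(0, 10, 25), c(5, 8), c(0, 40),
                                 c(12, 20, 31), c(3, 60), c(0, 0, 18)),
                            meso_activities()))
  cfg <- simulation_config(n_growers = 500, seed = 77, method = 3,
                           season = "spring", bw_table = tab,
                           pools = pools)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$summary, s2$summary)
  # a different seed changes the draws
  cfg2 <- simulation_config(n_growers = 500, seed = 78, method = 3,
                            season = "spring", bw_table = tab,
                            pools = pools)
  expect_false(identical(run_simulation(cfg2)$draws, s1$draws))
})

test_that("simulated means match the enumerated closed-form expectation", {
  # small pools/tables so the expectation is enumerable exactly
  tab <- tibble::tibble(weight_kg = c(55, 72, 90, 110),
                        population_weight = c(2, 5, 4, 1))
  e_inv_bw <- sum(tab$population_weight / tab$weight_kg) /
    sum(tab$population_weight)

  # method 1: E[ADD] = C*IR*1e-6/AT * E[days] * E[1/BW]
  pool1 <- c(0, 4.35, 13.05, 21.75, 30.45)
  cfg1 <- simulation_config(n_growers = 1e5, seed = 91, method = 1,
                            season = "spring", bw_table = tab,
                            pools = pool1)
  sim1 <- run_simulation(cfg1)
  expected1 <- 400 * 378e-6 / 30.5 * mean(pool1) * e_inv_bw
  mc_se1 <- sd(sim1$draws$add_total) / sqrt(1e5)
  expect_lt(abs(mean(sim1$draws$add_total) - expected1), 3 * mc_se1)

  # method 3 with rate perturbation: E[h_a * U_a] = mean(pool_a) * scale_a,
  # pools small enough that the indoor complement never clamps
  pools3 <- as.list(setNames(list(c(0, 20, 45), c(0, 10), c(15, 30),
                                  c(0, 5, 50), c(25, 40), c(0, 8, 12)),
                             meso_activities()))
  rates <- build_rate_set()
  cfg3 <- simulation_config(n_growers = 1e5, seed = 92, method = 3,
                            season = "summer", bw_table = tab,
                            pools = pools3,
                            rate_perturbation_halfwidth = 0.2)
  sim3 <- run_simulation(cfg3, rates)
  mean_h <- vapply(pools3, mean, numeric(1))[meso_activities()]
  scales <- rates$scaling_factors[meso_activities()]
  expected3 <- 24 * 400e-6 / 730.8 * e_inv_bw *
    (sum(rates$hourly_outdoor * scales * mean_h) +
       rates$hourly_indoor * (730.8 - sum(mean_h)))
  mc_se3 <- sd(sim3$draws$add_total) / sqrt(1e5)
  expect_lt(abs(mean(sim3$draws$add_total) - expected3), 3 * mc_se3)
})

test_that("summaries are percentile-sane and stable in n", {
  tab <- generate_bodyweight_table("weighted_sample", seed = 14)
  pool <- c(0, 30, 80, 174, 300, 500)
  run_at <- function(n, seed) {
    run_simulation(simulation_config(n_growers = n, seed = seed,
                                     method = 2, season = "fall",
                                     bw_table = tab, pools = pool))
  }
  s_small <- run_at(1000, 51)$summary
  s_large <- run_at(10000, 52)$summary
  for (s in list(s_small, s_large)) {
    expect_true(s$p5 <= s$median && s$median <= s$p95)
    expect_true(s$mean >= 0)
  }
  expect_lt(abs(s_small$mean - s_large$mean) / s_large$mean, 0.1)
  expect_true(all(run_at(1000, 53)$draws$add_total >= 0))
})

test_that("cohort-derived pools respect season, task and zero handling", {
  cohort <- tiny_cohort()
  p1 <- factor_pools(cohort, 1, "spring")
  expect_setequal(p1, c(5 * 4.35, 3 * 4.35))
  p3 <- factor_pools(cohort, 3, "spring")
  expect_equal(sort(p3$transplanting), 20)
  expect_equal(p3$irrigation, 0) # non-engagement kept by default
  expect_identical(factor_pools(cohort, 3, "spring",
                                include_zeros = FALSE)$irrigation,
                   numeric(0))
  expect_error(
    simulation_config(n_growers = 10, seed = 1, method = 3,
                      season = "spring", bw_table = bw_point_table(),
                      pools = factor_pools(cohort, 3, "spring",
                                           include_zeros = FALSE)),
    "irrigation"
  )
})
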