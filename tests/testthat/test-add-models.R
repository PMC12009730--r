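test_that("daily-rate dose model matches hand arithmetic", {
  # EF = AT cancels: 400 * 3.78e-4 / 80
  expect_equal(add_method1(400, 378, 30.5, 80)$add_total,
               400 * 378e-6 / 80)
  expect_identical(add_method1(400, 378, 0, 80)$add_total, 0)
  # independent hand computation, 5 d/wk grower
  expect_equal(add_method1(400, 378, 21.75, 65)$add_total,
               (400 * 378e-6 * 21.75) / (65 * 30.5))
  expect_error(add_method1(400, 378, 10, BW = 0), "positive")
  expect_error(add_method1(400, 378, -1, BW = 70), ">= 0")
})

test_that("hourly-rate dose model splits indoor/outdoor and conserves the month", {
  # indoor-only month
  r0 <- add_method2(400, 45.25, 1.375, 0, 80)
  expect_equal(r0$add_total, 24 * 400 * 1.375e-6 * 730.8 / (80 * 730.8))
  expect_identical(r0$add_outdoor, 0)
  # outdoor-only month
  r1 <- add_method2(400, 45.25, 1.375, 730.8, 80)
  expect_equal(r1$add_total, 24 * 400 * 45.25e-6 / 80)
  # two-term sum, hand computed
  r2 <- add_method2(400, 45.25, 1.375, 174, 70)
  expect_equal(r2$add_total,
               24 * (400 * 45.25e-6 * 174) / (70 * 730.8) +
                 24 * (400 * 1.375e-6 * (730.8 - 174)) / (70 * 730.8))
  expect_equal(r2$add_total, r2$add_outdoor + r2$add_indoor)
  # the complement definition forbids clamping
  expect_error(add_method2(400, 45.25, 1.375, 731, 70), "\\[0, 730.8\\]")
})

test_that("task-specific dose model sums per-task and indoor terms", {
  rates <- build_rate_set()
  # all-zero task hours reduces to the indoor-only hourly model
  r0 <- add_method3(400, rates, setNames(rep(0, 6), meso_activities()),
                    BW = 80)
  expect_equal(r0$add_total, add_method2(400, 45.25, 1.375, 0, 80)$add_total)
  # a single maintained-rate task equals the hourly model at those hours
  r1 <- add_method3(400, rates, c(bed_preparation = 50), BW = 80)
  expect_equal(r1$add_total,
               add_method2(400, 45.25, 1.375, 50, 80)$add_total)
  # three-term hand computation with the doubled rates
  r2 <- add_method3(400, rates, c(transplanting = 20, weeding = 30),
                    BW = 75)
  denom <- 75 * 730.8
  expect_equal(r2$add_total,
               24 * 400e-6 * (90.5 * 20 + 90.5 * 30 +
                                1.375 * (730.8 - 50)) / denom)
  expect_equal(r2$add_outdoor + r2$add_indoor, r2$add_total)
  expect_equal(r2$add_transplanting + r2$add_weeding, r2$add_outdoor)
  expect_false(r2$indoor_hours_clamped)
  expect_error(add_method3(400, rates, c(weeding = -1), BW = 70), ">= 0")
})

test_that("task hours above the month clamp the indoor term and flag it", {
  rates <- build_rate_set()
  r <- add_method3(400, rates, c(weeding = 500, irrigation = 400), BW = 70)
  expect_true(r$indoor_hours_clamped)
  expect_identical(r$add_indoor, 0)
  expect_identical(r$ef_indoor_hours, 0)
  expect_true(r$add_total >= 0)
})

test_that("dose models are homogeneous in C and rates, inverse in BW", {
  rates <- build_rate_set()
  h <- c(bed_preparation = 30, weeding = 60)
  base <- add_method3(400, rates, h, BW = 70)$add_total
  expect_equal(add_method3(800, rates, h, BW = 70)$add_total, 2 * base)
  expect_equal(add_method3(400, rates, h, BW = 140)$add_outdoor,
               add_method3(400, rates, h, BW = 70)$add_outdoor / 2)
  expect_equal(add_method1(400, 756, 20, 70)$add_total,
               2 * add_method1(400, 378, 20, 70)$add_total)
})

test_that("method 2's exposure hours always sum to the 730.8-hour month", {
  set.seed(21)
  hrs <- runif(500, 0, 730.8)
  r <- add_method2(400, 45.25, 1.375, hrs, BW = 80)
  expect_identical(r$ef_outdoor_hours + r$ef_indoor_hours,
                   rep(730.8, 500))
})

test_that("method 3 with unit scalings reduces to method 2", {
  rates <- build_rate_set(setNames(rep(0.5, 6), meso_activities()))
  set.seed(31)
  for (i in 1:50) {
    h <- setNames(runif(6, 0, 100), meso_activities())
    bw <- runif(1, 45, 120)
    m3 <- add_method3(400, rates, h, BW = bw)$add_total
    m2 <- add_method2(400, rates$hourly_outdoor, rates$hourly_indoor,
                      sum(h), BW = bw)$add_total
    expect_equal(m3, m2, tolerance = 1e-12)
  }
})

test_that("body weight lookup honors brackets, overrides, and gaps", {
  tab <- tibble::tibble(sex = "male", age_low = 30, age_high = 50,
                        median_kg = 88.8)
  expect_equal(body_weight_for("male", 40, tab), 88.8)
  expect_equal(body_weight_for("male", 40, tab, body_weight = 70), 70)
  expect_error(body_weight_for("male", 17, tab), "bracket")
  expect_error(body_weight_for("female", 40, tab), "bracket")
  full <- default_lookup_table()
  expect_equal(body_weight_for(c("male", "female"), c(40, 40), full,
                               body_weight = c(NA, 65)),
               c(88.8, 65))
})

test_that("annual aggregation sums and averages the four seasons", {
  seasonal <- tibble::tibble(
    grower_id = "A", season = seasons(), method = 1L,
    add_total = c(1e-3, 2e-3, 5e-4, 5e-4)
  )
  out <- annualize(seasonal)
  expect_equal(out$cumulative, 4e-3)
  expect_equal(out$mean_seasonal, 1e-3)
  one <- seasonal
  one$add_total <- c(2e-3, 0, 0, 0)
  out1 <- annualize(one)
  expect_equal(out1$cumulative, out1$mean_seasonal * 4)
  expect_error(annualize(seasonal[1:3, ]), "four seasons")
})

test_that("cohort-level estimation wires factors, weights and models together", {
  cohort <- tiny_cohort()
  rates <- build_rate_set()
  tab <- default_lookup_table()
  r1 <- estimate_add(cohort, 1, rates, tab)
  expect_identical(nrow(r1), 4L)
  # grower B reported 70 kg, overriding the lookup
  expect_equal(r1$body_weight_kg[r1$grower_id == "B"], 70)
  b <- r1[r1$grower_id == "B", ]
  expect_equal(b$add_total, (400 * 378e-6 * 3 * 4.35) / (70 * 30.5))
  # method 3 uses per-task hours: grower A spring has 20 + 12 task hours
  r3 <- estimate_add(cohort, 3, rates, tab)
  a <- r3[r3$grower_id == "A" & r3$season == "spring", ]
  bw_a <- body_weight_for("male", 40, tab)
  expect_equal(a$add_outdoor,
               24 * 400e-6 * (90.5 * 20 + 90.5 * 12) / (bw_a * 730.8))
  expect_error(estimate_add(empty <- generate_cohort(
    cohort_spec(n_growers = 0, seed = 1)), 1), "no records")
})
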