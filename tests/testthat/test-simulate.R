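test_that("simulation is bit-reproducible under a fixed seed and restores RNG", {
  set.seed(999)
  before <- .Random.seed
  a <- simulate_cohort(2000, seed = 11, base_params)
  expect_identical(.Random.seed, before)  # caller's stream untouched
  b <- simulate_cohort(2000, seed = 11, base_params)
  expect_identical(a$patients, b$patients)
  expect_identical(a$summary, b$summary)
  c <- simulate_cohort(2000, seed = 12, base_params)
  expect_false(identical(a$patients, c$patients))
  expect_error(simulate_cohort(0, seed = 1), "positive")
})

test_that("patient records satisfy their structural invariants", {
  sim <- simulate_cohort(3000, seed = 2, base_params, streams = TRUE)
  pt <- sim$patients
  expect_identical(nrow(pt), 3000L)
  expect_true(all(pt$genetic_class %in% c("high", "not_high")))
  # detection coincides with high-risk progressors
  expect_identical(pt$detected, pt$genetic_class == "high" & pt$progresses_10yr)
  cy <- pt$fellow_eye_conversion_year
  expect_true(all(is.na(cy[!pt$progresses_10yr])))
  expect_true(all(is.na(cy[pt$progresses_10yr]) |
                    (cy[pt$progresses_10yr] >= 1 &
                       cy[pt$progresses_10yr] <= 12)))
  expect_true(all(pt$qaly_accrual_12yr >= 0 & pt$qaly_accrual_12yr <= 12))
  # streams have exactly timeline_years entries per patient
  expect_identical(dim(sim$qaly_streams), c(3000L, 12L))
  expect_identical(dim(sim$cost_streams), c(3000L, 12L))
  expect_equal(rowSums(sim$qaly_streams), pt$qaly_accrual_12yr)
})

test_that("single-patient cohorts give degenerate frequencies", {
  sim <- simulate_cohort(1, seed = 5, base_params)
  f <- stratum_frequencies(sim)
  expect_true(f$fraction[f$stratum == "high_risk"] %in% c(0, 1))
})

test_that("stratum frequencies recover the generating margins at large n", {
  sim <- simulate_cohort(100000, seed = 3, base_params, streams = FALSE)
  f <- stratum_frequencies(sim)
  within_ci <- function(stratum, target) {
    r <- f[f$stratum == stratum, ]
    r$ci_lower <= target && target <= r$ci_upper
  }
  expect_true(within_ci("high_risk", 0.225))
  expect_true(within_ci("progression_10yr", 0.20))
  expect_true(within_ci("detected_among_progressors", 0.90))
  expect_true(within_ci("first_eye_late", 0.780))
  expect_true(within_ci("second_eye_late", 0.622))
  expect_true(within_ci("both_eyes_late", 0.780 * 0.622))  # 48.5%
})

test_that("population means converge to the deterministic cohort quantities", {
  sim <- simulate_cohort(200000, seed = 4, base_params, streams = FALSE)
  s <- sim$summary
  expect_lt(abs(s$mean_qaly_gain - 0.595), 3 * s$se_qaly_gain)
  expect_lt(abs(s$mean_net_cost_societal - (-160582)),
            3 * s$se_net_cost_societal)
  expect_lt(abs(s$mean_net_cost_third_party - 25960),
            3 * s$se_net_cost_third_party)
  expect_identical(s$per_screened_cost, 2205)
})

test_that("between-seed scatter is calibrated to the reported standard error", {
  n <- 20000
  ests <- ses <- numeric(20)
  for (k in 1:20) {
    s <- simulate_cohort(n, seed = 100 + k, base_params,
                         streams = FALSE)$summary
    ests[k] <- s$mean_qaly_gain
    ses[k] <- s$se_qaly_gain
  }
  ratio <- sd(ests) / mean(ses)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  expect_lt(abs(mean(ests) - 0.595), 3 * mean(ses) / sqrt(20))
})

test_that("conversion years follow the trajectory increments", {
  sim <- simulate_cohort(150000, seed = 6, base_params, streams = FALSE)
  pt <- sim$patients
  cy <- pt$fellow_eye_conversion_year[pt$progresses_10yr]
  # year-1 conversion mass ~21.2% and never-within-horizon ~7.5%
  expect_equal(mean(!is.na(cy) & cy == 1) * 100, 21.2, tolerance = 0.05)
  expect_equal(mean(is.na(cy)) * 100, 7.5, tolerance = 0.1)
})
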