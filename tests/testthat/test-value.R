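test_that("discounted annuity matches a brute-force end-of-year sum", {
  for (u in c(0, 0.538, 0.789, 1)) {
    for (r in c(0, 0.03, 0.1)) {
      for (y in c(0, 1, 12)) {
        expect_equal(discounted_annuity(u, r, y), sum_discounted(u, r, y))
      }
    }
  }
  # frozen closed-form values: annuity factor (1 - 1.03^-12)/0.03 = 9.954004
  expect_equal(round(discounted_annuity(0.789, 0.03, 12), 3), 7.854)
  expect_equal(discounted_annuity(1, 0, 12), 12)
  expect_equal(discounted_annuity(0, 0.03, 12), 0)
  expect_error(discounted_annuity(0.5, 0.03, -1), "years")
  expect_error(discounted_annuity(1.2, 0.03, 5), "utility")
})

test_that("zero-rate limit recovers utility x years", {
  for (u in c(0.26, 0.658, 0.97)) {
    expect_equal(discounted_annuity(u, 0, 12), u * 12)
    # tiny positive rates are cancellation-limited; agreement is approximate
    expect_equal(discounted_annuity(u, 1e-9, 12), u * 12, tolerance = 1e-4)
  }
})

test_that("unadjusted arm gains reproduce the accrual differences", {
  p <- base_params
  expect_equal(qaly_gain(p$accrual_early, p$accrual_sham), 1.934)
  expect_lt(abs(qaly_gain(p$accrual_early, p$accrual_sham) - 1.933), 0.0011)
  expect_equal(qaly_gain(p$accrual_late, p$accrual_sham), 0.571)
  expect_equal(qaly_gain(p$accrual_early, p$accrual_early), 0)
})

test_that("adjustment products hit the three- and four-way targets", {
  p <- base_params
  expect_equal(round(adjustment_product(p), 3), 0.437)
  expect_equal(round(adjustment_product(p, include_combined = TRUE), 3), 0.374)
  ones <- amd_parameters(first_eye_late_fraction = 1,
                         second_eye_late_fraction = 1, test_sensitivity = 1,
                         combined_eye_multiplier = 1)
  expect_equal(adjustment_product(ones, include_combined = TRUE), 1)
})

test_that("adjusted gains and percent QOL gains match the published chain", {
  p <- base_params
  expect_equal(round(adjusted_qaly_gain(1.363, p), 3), 0.595)
  expect_equal(round(adjusted_qaly_gain(1.933, p), 3), 0.844)
  expect_lt(abs(adjusted_qaly_gain(1.933, p) - 0.845), 0.002)
  expect_equal(adjusted_qaly_gain(0, p), 0)
  expect_equal(round(percent_qol_gain(0.845, 5.990), 1), 14.1)
  expect_equal(round(percent_qol_gain(0.250, 5.990), 1), 4.2)
  expect_equal(round(percent_qol_gain(0.571, 5.990), 1), 9.5)
  # unadjusted early gain deviates from this rule by ~0.5 points
  expect_lt(abs(percent_qol_gain(1.933, 5.990) - 32.8), 0.6)
  expect_equal(percent_qol_gain(0, 5.990), 0)
  expect_error(percent_qol_gain(1, 0), "sham_accrual")
})

test_that("per-screened dilution divides and is flagged approximate", {
  g <- per_screened_gain(0.595, 30.3)
  expect_equal(as.numeric(g), 0.595 / 30.3)
  expect_equal(round(as.numeric(g), 4), 0.0196)
  expect_true(attr(g, "approximate"))
  expect_equal(as.numeric(per_screened_gain(0, 30.3)), 0)
  expect_equal(as.numeric(per_screened_gain(0.595, 1)), 0.595)
  expect_error(per_screened_gain(0.595, 0), "screened_per_early_case")
})

test_that("adjustment never increases a gain and preserves arm ordering", {
  p <- base_params
  set.seed(7)
  for (i in 1:25) {
    q <- amd_parameters(first_eye_late_fraction = runif(1),
                        second_eye_late_fraction = runif(1),
                        test_sensitivity = runif(1))
    gains <- c(early = qaly_gain(p$accrual_early, p$accrual_sham),
               late = qaly_gain(p$accrual_late, p$accrual_sham))
    adj <- adjusted_qaly_gain(gains, q)
    expect_true(all(adj <= gains))
    expect_gte(adj["early"], adj["late"])
  }
})

test_that("value table reproduces the arm rows and the incremental row", {
  v <- value_table(base_params)
  inc <- v[v$cohort == "early_vs_late", ]
  expect_equal(inc$gain_unadjusted, 1.363)
  expect_equal(round(inc$gain_adjusted, 3), 0.595)
  expect_equal(round(inc$qol_adjusted_pct, 1), 9.9)  # ~10.0% printed
  expect_equal(round(v$qol_adjusted_pct[v$cohort == "early"], 1), 14.1)
  expect_equal(round(v$qol_adjusted_pct[v$cohort == "late"], 1), 4.2)
  expect_equal(v$gain_adjusted[v$cohort == "sham"], 0)
})

test_that("rebuilding the early accrual from components is consistent within 0.05 QALY", {
  chk <- accrual_consistency(base_params)
  expect_lt(abs(chk$difference), 0.05)
})
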