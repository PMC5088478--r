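test_that("identity scenario reproduces the base case bit-for-bit", {
  base_rows <- run_scenario(scenario("base_case", list()), base_params)
  soc <- base_rows[base_rows$perspective == "societal", ]
  tp <- base_rows[base_rows$perspective == "third_party", ]
  ref_soc <- cur_table(4.1, "societal", base_params)
  ref_tp <- cur_table(10.1, "third_party", base_params)
  expect_identical(soc$total_cost, ref_soc$total_cost)
  expect_identical(soc$cur, ref_soc$cur)
  expect_identical(tp$total_cost, ref_tp$total_cost)
  expect_identical(soc$screening_cost_total, 2082402000 / 1000)
})

test_that("genetic-price scenarios reproduce the published cost totals exactly", {
  r500 <- run_scenario(scenario("price_500", list(genetic_test_price = 500)),
                       base_params)
  expect_equal(unique(r500$screening_cost_total), 754575.6)  # $754,576k
  r1000 <- run_scenario(scenario("price_1000",
                                 list(genetic_test_price = 1000)),
                        base_params)
  expect_equal(unique(r1000$screening_cost_total), 1226775.6)  # $1,226,776k
})

test_that("removing the extra exam reproduces the published cost total", {
  r <- run_scenario(scenario("no_extra_exams", list(extra_exams = 0)),
                    base_params)
  expect_equal(unique(r$screening_cost_total), 1906 * 944400 / 1000)
  expect_equal(round(unique(r$screening_cost_total)), 1800026)
})

test_that("CUR responds monotonically to price, screening age, and injections", {
  eval_cur <- function(ov) {
    r <- run_scenario(scenario("s", ov), base_params)
    r$cur[r$perspective == "societal"]
  }
  prices <- c(250, 500, 1000, 1461, 2500)
  curs <- vapply(prices, function(x) eval_cur(list(genetic_test_price = x)),
                 numeric(1))
  expect_true(all(diff(curs) > 0))
  periods <- c(0L, 5L, 13L, 25L)
  curs <- vapply(periods, function(k)
    eval_cur(list(extra_compounding_periods = k)), numeric(1))
  expect_true(all(diff(curs) > 0))
  inj <- c(0, 11, 22, 44)
  curs <- vapply(inj, function(k)
    eval_cur(list(extra_injections = k, injection_unit_cost = 853)),
    numeric(1))
  expect_true(all(diff(curs) > 0))
})

test_that("injection differential enters per screened patient and raises break-even", {
  expect_equal(injection_differential_cost(0, 853, base_params), 0)
  expect_equal(injection_differential_cost(22, 853, base_params),
               22 * 853 / 30.3)
  pc0 <- base_per_capita_cost(base_params)
  be0 <- breakeven_uptake(144000, "societal", base_params)
  pc1 <- pc0 + injection_differential_cost(22, 853, base_params)
  be1 <- breakeven_uptake(144000, "societal", base_params, per_capita = pc1)
  pc2 <- pc0 + injection_differential_cost(44, 853, base_params)
  be2 <- breakeven_uptake(144000, "societal", base_params, per_capita = pc2)
  expect_gt(as.numeric(be1), as.numeric(be0))
  expect_gt(as.numeric(be2), as.numeric(be1))
  # double-injection differential pushes the societal break-even toward ~6%
  expect_gt(as.numeric(be1), 5)
  expect_lt(as.numeric(be1), 7)
})

test_that("scenario validation rejects unknown override keys", {
  expect_error(scenario("bad", list(frobnicate = 1)), "unknown key")
  expect_silent(scenario("ok", list(discount_rate = 0.05,
                                    genetic_test_price = 750)))
})

test_that("the registered bundle runs under both perspectives", {
  tab <- run_sensitivity(base_params)
  expect_identical(nrow(tab), 2L * length(default_scenarios()))
  expect_setequal(unique(tab$perspective), c("societal", "third_party"))
  expect_identical(tab$incremental_pct[tab$perspective == "societal"][1], 4.1)
  expect_identical(tab$incremental_pct[tab$perspective == "third_party"][1],
                   10.1)
})
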