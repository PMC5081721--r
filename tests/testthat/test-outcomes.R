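test_that("discount factors follow (1 + r)^(-t)", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(1, 0.035), 1 / 1.035)
  expect_equal(discount_factor(1, 0.035), 0.966184, tolerance = 1e-6)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_error(discount_factor(1, -0.1), ">= 0")
})

test_that("acute cost of one event is the sum of the four care items", {
  ledger <- tibble::tibble(year = 0, first_events = 1, repeat_events = 0,
                           cad_deaths = 0, history_py = 0, alive = 1)
  cc <- compute_costs(ledger, "reference", cost_set(), discount_rate = 0.035)
  expect_equal(cc$cost_acute, 3557.46 + 1605.36 + 213.78 + 854.56)
  expect_equal(cc$cost_acute, 6231.16)
  expect_equal(cc$cost_chronic + cc$cost_mortality + cc$cost_measures, 0)
})

test_that("measure costs follow each option's schedule", {
  n <- 20
  ledger <- tibble::tibble(year = 0:(n - 1), first_events = 0,
                           repeat_events = 0, cad_deaths = 0, history_py = 0,
                           alive = 1e6)
  costs <- cost_set()
  dfac <- discount_factor(0:(n - 1), 0.035)

  # reference: no measures at all
  ref <- compute_costs(ledger, "reference", costs)
  expect_true(all(ref$cost_total == 0))

  # legal limit: food inspection only, every year (closed-form oracle)
  legal <- compute_costs(ledger, "legal_limit", costs)
  expect_equal(legal$cost_measures, 1e6 * 0.86 * dfac)
  expect_equal(sum(legal$cost_measures), 1e6 * 0.86 * sum(dfac))

  # labeling: inspection all years + information measures in years 0-4
  lab <- compute_costs(ledger, "labeling", costs)
  info <- 1.15 + 4.48 + 1.90 + 8.28
  expect_equal(lab$cost_measures[1:5], 1e6 * (0.86 + info) * dfac[1:5])
  expect_equal(lab$cost_measures[6:n], 1e6 * 0.86 * dfac[6:n])

  # unknown measure name in a hand-built option is a config error
  opt <- policy_option("voluntary")
  opt$measures$measure <- "helicopter_drop"
  expect_error(compute_costs(ledger, opt, costs), "helicopter_drop")
})

test_that("chronic and mortality costs use their bundles", {
  ledger <- tibble::tibble(year = 2, first_events = 0, repeat_events = 0,
                           cad_deaths = 10, history_py = 100, alive = 1000)
  cc <- compute_costs(ledger, "reference", cost_set(), discount_rate = 0)
  expect_equal(cc$cost_chronic, 100 * (617.34 + 6440.19 + 2158.88))
  expect_equal(cc$cost_mortality, 10 * 5101.94)
})

test_that("DALYs combine life-expectancy YLL with weighted YLD", {
  # two-age life table with hand-computable expectancy
  tt <- toy_tables(max_age = 2, q = 0.5)
  # q = (0.5, 0.5, 1); discounted LE at age 0, rate 0:
  # e(2) = 0; e(1) = 0.5 * (1 + 0) = 0.5; e(0) = 0.5 * (1 + 0.5) = 0.75
  daly0 <- daly_parameters(0.4, 0.08, discount_effects = FALSE)
  led <- tibble::tibble(year = 0, age = 0, sex = "F", first_events = 2,
                        repeat_events = 1, cad_deaths = 3, history_py = 10)
  out <- compute_dalys(led, tt$life, daly0, rate = 0.035)
  expect_equal(out$yll, 3 * 0.75)
  expect_equal(out$yld, 3 * 0.4 * 1 + 10 * 0.08)
  expect_equal(out$dalys, out$yll + out$yld)

  # zero weights give zero YLD
  dalyz <- daly_parameters(0, 0)
  outz <- compute_dalys(led, tt$life, dalyz, rate = 0.035)
  expect_equal(outz$yld, 0)

  # no events and no deaths give (0, 0)
  led0 <- dplyr::mutate(led, first_events = 0, repeat_events = 0,
                        cad_deaths = 0, history_py = 0)
  out0 <- compute_dalys(led0, tt$life, daly0)
  expect_equal(out0$yll, 0)
  expect_equal(out0$yld, 0)
})

test_that("discounted life expectancy matches a brute-force survival sum", {
  syn <- synthetic_config(seed = 4, max_age = 60)
  lt <- generate_life_table(syn)
  r <- 0.035
  e <- discounted_life_expectancy(lt, r)
  # brute force at a few ages: sum over k >= 1 of S(a, k) / (1 + r)^k
  for (probe in list(c(20, "F"), c(40, "M"), c(55, "F"))) {
    a <- as.integer(probe[1]); s <- probe[2]
    q <- lt$q_all_cause[lt$sex == s]
    surv <- cumprod(1 - q[(a + 1):length(q)])
    brute <- sum(surv / (1 + r)^seq_along(surv))
    expect_equal(e$life_expectancy[e$age == a & e$sex == s], brute,
                 tolerance = 1e-12)
  }
})

test_that("run totals equal the outcome-module recomputation from the ledger", {
  inp <- toy_inputs(max_age = 30, q = 0.03, p0 = 0.06, cf = 0.25,
                    ages = c(5, 15), count = 2000,
                    cfg = run_config(horizon_years = 20,
                                     daly = daly_parameters(0.4, 0.08)))
  run <- run_option(inp, "labeling", stratified = TRUE)
  cc <- compute_costs(run$ledger, "labeling", inp$run_config$costs,
                      inp$run_config$discount_rate)
  expect_equal(sum(cc$cost_total), run$total_cost, tolerance = 1e-12)
  dd <- compute_dalys(run$ledger_strata, inp$life_table,
                      inp$run_config$daly, inp$run_config$discount_rate)
  expect_equal(dd$yll, run$yll, tolerance = 1e-9)
  expect_equal(dd$yld, run$yld, tolerance = 1e-9)
})

test_that("totals scale linearly with the ledger and shrink with the rate", {
  inp <- toy_inputs(max_age = 30, ages = c(5, 15), count = 2000,
                    cfg = run_config(horizon_years = 20,
                                     daly = daly_parameters(0.4, 0.08)))
  run <- run_option(inp, "voluntary")
  led <- run$ledger
  cc1 <- compute_costs(led, "voluntary", cost_set(), 0.035)
  cc2 <- compute_costs(dplyr::mutate(led, dplyr::across(
    c(first_events, repeat_events, cad_deaths, history_py, alive),
    ~ 3 * .x)), "voluntary", cost_set(), 0.035)
  expect_equal(cc2$cost_total, 3 * cc1$cost_total)

  rates <- c(0, 0.015, 0.035, 0.08)
  totals <- vapply(rates, function(r) {
    sum(compute_costs(led, "voluntary", cost_set(), r)$cost_total)
  }, numeric(1))
  expect_true(all(diff(totals) < 0))

  # identical ledgers under different options differ only by measure costs
  ca <- compute_costs(led, "reference", cost_set(), 0.035)
  cb <- compute_costs(led, "legal_limit", cost_set(), 0.035)
  expect_equal(cb$cost_acute, ca$cost_acute)
  expect_equal(cb$cost_chronic, ca$cost_chronic)
  expect_equal(cb$cost_mortality, ca$cost_mortality)
  expect_false(isTRUE(all.equal(cb$cost_measures, ca$cost_measures)))
})
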