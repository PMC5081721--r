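test_that("initialization puts everyone in Well", {
  tt <- toy_tables(max_age = 3)
  tt$pop$count <- c(10, 20, 30, 0, 15, 25, 0, 0)
  st <- initialize_cohort(tt$pop)
  expect_equal(sum(st$well), 100)
  expect_equal(sum(st$cad) + sum(st$history) + sum(st$dead), 0)

  empty <- initialize_cohort(dplyr::mutate(tt$pop, count = 0))
  expect_true(all(unlist(empty[, c("well", "cad", "history", "dead")]) == 0))
})

test_that("identity transitions leave the cohort unchanged except for aging", {
  tt <- toy_tables(max_age = 5, q = 0, p0 = 0, cf = 0)
  tt$life$q_all_cause[tt$life$age == 5] <- 0  # no absorbing top here
  tt$pop$count[tt$pop$age == 2] <- 100
  tr <- suppressWarnings(build_trajectory("reference", "base", horizon = 3))
  trans <- assemble_transitions(tt$life, tt$morb, tr)
  st <- initialize_cohort(tt$pop)
  out <- markov_step(st, trans, t = 0)
  expect_equal(out$events$first_events, 0)
  expect_equal(out$events$cad_deaths, 0)
  expect_equal(sum(out$state$well), 200)
  expect_equal(out$state$well[out$state$age == 3 & out$state$sex == "F"], 100)
  expect_equal(out$state$well[out$state$age == 2 & out$state$sex == "F"], 0)
})

test_that("a single hand-set stratum steps to hand-computed occupancies", {
  q <- 0.02; p0 <- 0.05; cf <- 0.3
  tt <- toy_tables(max_age = 5, q = q, p0 = p0, cf = cf)
  tt$pop$count[tt$pop$age == 1 & tt$pop$sex == "F"] <- 1000
  tr <- build_trajectory("reference", scenario_spec("z", initial_intake = 0),
                         horizon = 3)
  trans <- assemble_transitions(tt$life, tt$morb, tr)
  st <- initialize_cohort(tt$pop)
  out <- markov_step(st, trans, t = 0)

  q_other <- 1 - exp(-(-log(1 - q) + log(1 - p0 * cf)))
  expect_equal(out$events$first_events, 1000 * p0)
  expect_equal(out$events$other_deaths, 1000 * q_other)
  s2 <- out$state
  expect_equal(s2$well[s2$age == 2 & s2$sex == "F"],
               1000 * (1 - p0 - q_other))
  expect_equal(s2$cad[s2$age == 2 & s2$sex == "F"], 1000 * p0)

  # second step: the acute compartment resolves by case fatality
  out2 <- markov_step(out$state, trans, t = 1)
  expect_equal(out2$events$cad_deaths, 1000 * p0 * cf)
  s3 <- out2$state
  expect_equal(s3$history[s3$age == 3 & s3$sex == "F"], 1000 * p0 * (1 - cf))
  # conservation across both steps
  total <- sum(s3$well + s3$cad + s3$history + s3$dead)
  expect_equal(total, 1000, tolerance = 1e-12)
})

test_that("closed-cohort conservation holds at every cycle", {
  inp <- toy_inputs(max_age = 30, q = 0.03, p0 = 0.06, cf = 0.25,
                    ages = c(0, 10, 20, 28), count = 12345,
                    cfg = run_config(horizon_years = 40,
                                     daly = daly_parameters(0.4, 0.08)))
  run <- run_option(inp, "reference")
  total0 <- sum(inp$population$count)
  with(run$ledger, {
    expect_true(all(abs(alive + dplyr::lag(dead, default = 0) - total0) <
                      1e-9 * total0))
  })
  final_alive <- run$ledger$alive[nrow(run$ledger)]
  expect_lt(final_alive / total0, 1)
})

test_that("the engine is linear in the population (scaling and doubling)", {
  base <- toy_inputs(max_age = 20, ages = c(5, 10), count = 1000,
                     cfg = run_config(horizon_years = 15,
                                      daly = daly_parameters(0.4, 0.08)))
  double <- toy_inputs(max_age = 20, ages = c(5, 10), count = 2000,
                       cfg = base$run_config)
  r1 <- run_option(base, "voluntary")
  r2 <- run_option(double, "voluntary")
  expect_equal(r2$events, 2 * r1$events)
  expect_equal(r2$cad_deaths, 2 * r1$cad_deaths)
  expect_equal(r2$total_cost, 2 * r1$total_cost)
  expect_equal(r2$dalys, 2 * r1$dalys)
  expect_equal(r2$ledger$history_py, 2 * r1$ledger$history_py)
})

test_that("zero CAD incidence decouples to a pure life-table projection", {
  q <- 0.04
  inp <- toy_inputs(max_age = 25, q = q, p0 = 0, cf = 0.3, ages = 3,
                    count = 5000,
                    cfg = run_config(horizon_years = 12,
                                     daly = daly_parameters(0.4, 0.08)))
  run <- run_option(inp, "reference")
  expect_equal(run$events, 0)
  expect_equal(run$cad_deaths, 0)
  expect_equal(run$dalys, 0)
  # independent survival projection: 10000 people, constant q per year
  expected_alive <- 10000 * (1 - q)^(0:11)
  expect_equal(run$ledger$alive, expected_alive, tolerance = 1e-12)
})

test_that("monotone harm: pointwise-lower intake never yields more events", {
  cfg <- run_config(horizon_years = 30, daly = daly_parameters(0.4, 0.08))
  inp <- toy_inputs(max_age = 40, p0 = 0.05, ages = c(10, 20, 30),
                    count = 10000, cfg = cfg)
  runs <- lapply(c("legal_limit", "voluntary", "labeling", "reference"),
                 function(id) run_option(inp, id))
  events <- vapply(runs, function(r) r$events, numeric(1))
  dalys <- vapply(runs, function(r) r$dalys, numeric(1))
  expect_true(all(diff(events) >= 0))
  expect_true(all(diff(dalys) >= 0))
})

test_that("cohort engine agrees with a seeded microsimulation oracle", {
  # tiny instance: people at 3 ages, 2 sexes, 10k persons, 20 years
  cfg <- run_config(horizon_years = 20, daly = daly_parameters(0.4, 0.08))
  tt <- toy_tables(max_age = 95, q = 0, p0 = 0, cf = 0)
  syn <- synthetic_config(seed = 8, max_age = 95)
  tt$life <- generate_life_table(syn)
  tt$morb <- generate_morbidity_table(syn)
  pop <- tt$pop
  pop$count[pop$age %in% c(40, 60, 75)] <- round(10000 / 6)
  inp <- as_inputs(tt$life, tt$morb, pop, cfg)

  run <- run_option(inp, "voluntary")
  expected <- c(run$first_events, run$repeat_events, run$cad_deaths,
                run$other_deaths)

  reps <- microsim_replicates(inp, "voluntary", cfg, n_rep = 50, seed = 202)
  mc_mean <- colMeans(reps)
  mc_se <- apply(reps, 2, stats::sd) / sqrt(nrow(reps))
  for (j in 1:4) {
    expect_lt(abs(mc_mean[j] - expected[j]), 3 * mc_se[j] + 1e-9)
  }
})
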