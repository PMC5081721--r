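test_that("distribution builders match their closed forms", {
  # lognormal from the published RR CI: sigma = (ln 1.37 - ln 1.11) / 3.92
  d <- build_distribution(1.23, ci = c(1.11, 1.37), family = "lognormal")
  expect_equal(d$pars$sigma, (log(1.37) - log(1.11)) / (2 * qnorm(0.975)))
  expect_equal(d$pars$sigma, 0.05369, tolerance = 1e-4)
  expect_equal(d$pars$mu, log(1.23))

  # gamma by moment matching: mean 3557.46, SE 20% -> shape 25, scale 142.2984
  g <- build_distribution(3557.46, se = 0.2 * 3557.46, family = "gamma")
  expect_equal(g$pars$shape, 25)
  expect_equal(g$pars$scale, 142.2984, tolerance = 1e-10)

  # point distributions always return the mean
  p <- build_distribution(7, family = "point")
  expect_equal(draw_distribution(p, 5), rep(7, 5))

  # validation: CI must bracket the mean; support constraints enforced
  expect_error(build_distribution(2, ci = c(0.5, 1.5), family = "lognormal"),
               "bracket")
  expect_error(build_distribution(-1, se = 1, family = "gamma"),
               "non-negative")
  expect_error(build_distribution(0, se = 1, family = "lognormal"),
               "positive")
})

test_that("sampled moments recover the specified means within 1%", {
  set.seed(314)
  n <- 1e5
  specs <- list(
    build_distribution(1.23, ci = c(1.11, 1.37), family = "lognormal"),
    build_distribution(1.5, se = 0.3, family = "lognormal"),
    build_distribution(3557.46, se = 711.492, family = "gamma"),
    build_distribution(0.86, se = 0.172, family = "gamma")
  )
  for (d in specs) {
    x <- draw_distribution(d, n)
    expect_lt(abs(mean(x) / d$mean - 1), 0.01)
    expect_true(all(x > 0))
  }
})

test_that("point-mass PSA reproduces the deterministic analysis exactly", {
  inp <- toy_inputs(max_age = 40, q = 0.02, p0 = 0.04, cf = 0.2,
                    ages = c(20, 30), count = 5e4,
                    cfg = run_config(horizon_years = 25,
                                     daly = daly_parameters(0.4, 0.08),
                                     psa = list(n_draws = 5, seed = 9)))
  det <- run_deterministic(inp)
  psa <- run_psa(inp, distributions = psa_distributions(inp$run_config,
                                                        point = TRUE))
  for (id in inp$run_config$options) {
    ddraws <- psa$draws[psa$draws$option == id, ]
    expect_equal(unique(ddraws$cost), det$runs[[id]]$total_cost)
    expect_equal(unique(ddraws$dalys), det$runs[[id]]$dalys)
  }
  sm <- psa$summary
  for (id in setdiff(inp$run_config$options, "reference")) {
    expect_equal(sm$mean_delta_cost[sm$option == id],
                 det$incremental$delta_cost[det$incremental$option == id])
  }
  expect_equal(psa$n_resampled, 0L)
})

test_that("identical seeds give identical PSA results, different seeds differ", {
  inp <- toy_inputs(max_age = 30, ages = 15, count = 1e4,
                    cfg = run_config(horizon_years = 10,
                                     daly = daly_parameters(0.4, 0.08),
                                     options = c("reference", "legal_limit")))
  a <- run_psa(inp, n_draws = 8, seed = 123)
  b <- run_psa(inp, n_draws = 8, seed = 123)
  c <- run_psa(inp, n_draws = 8, seed = 124)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)
  expect_false(isTRUE(all.equal(a$draws$cost, c$draws$cost)))
})

test_that("the PSA leaves the caller's RNG stream untouched", {
  inp <- toy_inputs(max_age = 20, ages = 10, count = 1e3,
                    cfg = run_config(horizon_years = 5,
                                     daly = daly_parameters(0.4, 0.08),
                                     options = c("reference", "voluntary")))
  set.seed(77)
  before <- runif(3)
  set.seed(77)
  suppressWarnings(invisible(run_psa(inp, n_draws = 2, seed = 55)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("ce_plane flips signs to DALYs-avoided vs costs-saved", {
  inp <- toy_inputs(max_age = 30, ages = 15, count = 1e4,
                    cfg = run_config(horizon_years = 10,
                                     daly = daly_parameters(0.4, 0.08),
                                     options = c("reference", "legal_limit")))
  psa <- run_psa(inp, n_draws = 6, seed = 5)
  pts <- ce_plane(psa)
  expect_equal(nrow(pts), 6)
  merged <- dplyr::left_join(pts, psa$draws, by = c("draw", "option"))
  expect_equal(merged$dalys_avoided, -merged$delta_dalys)
  expect_equal(merged$costs_saved, -merged$delta_cost)

  # empty PSA still yields a well-formed, header-only export
  psa0 <- psa
  psa0$draws <- psa$draws[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  pts0 <- ce_plane(psa0, path)
  expect_equal(nrow(pts0), 0)
  expect_equal(readLines(path), "draw,option,dalys_avoided,costs_saved")
})

test_that("PSA summary probabilities are frequencies over the draws", {
  inp <- toy_inputs(max_age = 40, p0 = 0.04, ages = c(20, 30), count = 5e4,
                    cfg = run_config(horizon_years = 25,
                                     daly = daly_parameters(0.4, 0.08),
                                     options = c("reference", "voluntary",
                                                 "legal_limit")))
  psa <- run_psa(inp, n_draws = 40, seed = 42)
  for (id in c("voluntary", "legal_limit")) {
    d <- psa$draws[psa$draws$option == id, ]
    s <- psa$summary[psa$summary$option == id, ]
    expect_equal(s$p_save_costs, mean(d$delta_cost < 0))
    expect_equal(s$p_save_dalys, mean(d$delta_dalys < 0))
    expect_equal(s$p_dominant, mean(d$delta_cost < 0 & d$delta_dalys < 0))
    expect_gte(s$p_dominant, 0)
    expect_lte(s$p_dominant, 1)
  }
  expect_equal(nrow(psa$draws), 40 * 3)
})
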