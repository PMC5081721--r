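# Internal numeric engine. All occupancy vectors are ordered by (sex block:
# F then M) x (age 0..max_age); the public wrappers convert to/from tibbles.

# Advance ages by one year within each sex block; occupants already at the
# top age stay there (the life-table invariant q(max_age) = 1 makes the top
# age absorbing, so they die within the next cycle).
age_up <- function(v, n_age) {
  w <- numeric(length(v))
  i1 <- seq_len(n_age)
  i2 <- n_age + i1
  w[i1[-1]] <- v[i1[-n_age]]
  w[n_age] <- w[n_age] + v[n_age]
  w[i2[-1]] <- v[i2[-n_age]]
  w[2 * n_age] <- w[2 * n_age] + v[2 * n_age]
  w
}

# Discounted remaining life expectancy per stratum, by backward recursion
# within each sex block: e(a) = (1 - q(a)) * v * (1 + e(a + 1)), v = 1/(1+r).
# Counts expected discounted whole future years lived, from the input life
# table of the run.
disc_life_expectancy <- function(q, n_age, rate) {
  v <- 1 / (1 + rate)
  e <- numeric(2 * n_age)
  for (blk in 0:1) {
    off <- blk * n_age
    e[off + n_age] <- (1 - q[off + n_age]) * v
    if (n_age > 1) {
      for (a in seq(n_age - 1, 1)) {
        e[off + a] <- (1 - q[off + a]) * v * (1 + e[off + a + 1])
      }
    }
  }
  e
}

# Per-capita policy-measure cost at each model year 0..H-1.
measure_per_capita <- function(option, costs, horizon) {
  out <- numeric(horizon)
  if (nrow(option$measures) == 0) return(out)
  bad <- setdiff(option$measures$measure, MEASURE_NAMES)
  if (length(bad)) {
    abort(paste0("unknown measure name(s) in option '", option$id, "': ",
                 paste(bad, collapse = ", ")))
  }
  t <- seq_len(horizon) - 1
  for (i in seq_len(nrow(option$measures))) {
    m <- option$measures[i, ]
    active <- t >= m$from & t < m$to
    out[active] <- out[active] + costs[[m$measure]]
  }
  out
}

# Assemble the numeric parameter set for one option run. Overrides allow the
# PSA to substitute drawn tables/costs without touching the input tibbles.
core_pars <- function(inputs, option, cfg,
                      q = NULL, p0 = NULL, cf = NULL,
                      costs = NULL, risk = NULL, traj_intake = NULL) {
  lt <- inputs$life_table
  mb <- inputs$morbidity
  pp <- inputs$population
  n_age <- max(lt$age) + 1
  risk <- risk %||% cfg$risk
  costs <- costs %||% cfg$costs
  if (is.null(traj_intake)) {
    tr <- build_trajectory(option, cfg$scenario, horizon = cfg$horizon_years,
                           shape = cfg$decay_shape)
    traj_intake <- tr$intake_e_pct
  }
  e0 <- traj_intake[1]
  rrf <- rr_for_intake_change(traj_intake - e0, risk$rr_per_2epct)
  mult <- NULL
  sm <- cfg$scenario$multipliers
  if (!is.null(sm)) {
    grid <- sex_grid(n_age - 1) %>% left_join(sm, by = c("age", "sex"))
    mult <- grid$multiplier
    if (anyNA(mult)) abort("scenario multipliers do not cover the input grid")
  }
  list(
    mult = mult,
    n_age = n_age,
    ages = rep(0:(n_age - 1), 2),
    sexes = rep(SEXES, each = n_age),
    q = q %||% lt$q_all_cause,
    p0 = p0 %||% mb$p_cad_first,
    cf = cf %||% mb$case_fatality,
    pop = pp$count,
    rrf = rrf[seq_len(cfg$horizon_years)],
    risk = risk,
    costs = costs,
    daly = cfg$daly,
    horizon = cfg$horizon_years,
    rate = cfg$discount_rate,
    measure_pc = measure_per_capita(option, costs, cfg$horizon_years)
  )
}

# Deterministic expected-value cohort run. Returns per-year series and
# discounted totals as plain numerics.
core_run <- function(par, check = TRUE, strata = FALSE) {
  n_age <- par$n_age
  H <- par$horizon
  q <- par$q; p0 <- par$p0; cf <- par$cf
  if (check) {
    for (nm in c("q", "p0", "cf")) {
      v <- par[[nm]]
      if (any(!is.finite(v) | v < 0 | v > 1)) {
        abort(paste0("invalid probability in '", nm, "' input"))
      }
    }
    if (any(!is.finite(par$pop) | par$pop < 0)) {
      abort("population counts must be non-negative")
    }
  }
  dw <- par$daly
  e_rate <- if (dw$discount_effects) par$rate else 0
  e_disc <- disc_life_expectancy(q, n_age, e_rate)
  df <- (1 + par$rate)^(-(0:(H - 1)))
  df_e <- if (dw$discount_effects) df else rep(1, H)
  cs <- par$costs
  acute_bundle <- cs$inpatient + cs$medication + cs$emergency + cs$outpatient
  chronic_bundle <- cs$primary_care + cs$informal_care + cs$production_loss_morbidity

  W <- par$pop
  C1 <- numeric(2 * n_age)  # acute CAD, first event
  C2 <- numeric(2 * n_age)  # acute CAD, repeat event
  Hs <- numeric(2 * n_age)  # history of CAD
  dead <- 0

  z <- numeric(H)
  series <- list(first_events = z, repeat_events = z, cad_deaths = z,
                 other_deaths = z, alive = z, well = z, cad = z,
                 history_py = z, dead = z,
                 yll = z, yld = z,
                 cost_acute = z, cost_chronic = z, cost_mortality = z,
                 cost_measures = z)
  strata_rec <- if (strata) {
    m <- matrix(0, H, 2 * n_age)
    list(first_events = m, repeat_events = m, cad_deaths = m,
         other_deaths = m, history_py = m, alive = m)
  }

  for (ti in seq_len(H)) {
    rrf_t <- if (length(par$rrf) == 1) par$rrf else par$rrf[ti]
    # Per-stratum intake multipliers enter the RR factor through the exponent.
    if (!is.null(par$mult)) rrf_t <- rrf_t^par$mult
    tr <- transition_rows(q, p0, cf, rrf_t, par$risk, check = FALSE)
    fe <- W * tr$p_first_cad
    dow <- W * tr$p_death_other_well
    W_stay <- W - fe - dow
    d1 <- C1 * tr$p_death_cad
    s1 <- C1 - d1
    d2 <- C2 * tr$p_death_repeat_cad
    s2 <- C2 - d2
    re <- Hs * tr$p_repeat_cad
    doh <- Hs * tr$p_death_other_history
    H_stay <- Hs - re - doh

    cad_death_v <- d1 + d2
    series$first_events[ti] <- sum(fe)
    series$repeat_events[ti] <- sum(re)
    series$cad_deaths[ti] <- sum(cad_death_v)
    series$other_deaths[ti] <- sum(dow) + sum(doh)
    series$alive[ti] <- sum(W) + sum(C1) + sum(C2) + sum(Hs)
    series$well[ti] <- sum(W)
    series$cad[ti] <- sum(C1) + sum(C2)
    series$history_py[ti] <- sum(Hs)
    series$yll[ti] <- sum(cad_death_v * e_disc) * df_e[ti]
    events_t <- series$first_events[ti] + series$repeat_events[ti]
    series$yld[ti] <- (events_t * dw$disability_weight_acute * dw$acute_duration +
                         series$history_py[ti] * dw$disability_weight_history) * df_e[ti]
    series$cost_acute[ti] <- events_t * acute_bundle * df[ti]
    series$cost_chronic[ti] <- series$history_py[ti] * chronic_bundle * df[ti]
    series$cost_mortality[ti] <- series$cad_deaths[ti] * cs$production_loss_mortality * df[ti]
    series$cost_measures[ti] <- series$alive[ti] * par$measure_pc[ti] * df[ti]

    if (strata) {
      strata_rec$first_events[ti, ] <- fe
      strata_rec$repeat_events[ti, ] <- re
      strata_rec$cad_deaths[ti, ] <- cad_death_v
      strata_rec$other_deaths[ti, ] <- dow + doh
      strata_rec$history_py[ti, ] <- Hs
      strata_rec$alive[ti, ] <- W + C1 + C2 + Hs
    }
    dead <- dead + series$cad_deaths[ti] + series$other_deaths[ti]
    series$dead[ti] <- dead
    W <- age_up(W_stay, n_age)
    C1 <- age_up(fe, n_age)
    C2 <- age_up(re, n_age)
    Hs <- age_up(s1 + s2 + H_stay, n_age)
  }

  total_cost_by_cat <- c(
    acute = sum(series$cost_acute),
    chronic = sum(series$cost_chronic),
    mortality = sum(series$cost_mortality),
    measures = sum(series$cost_measures)
  )
  strata_tbl <- if (strata) {
    purrr::map_dfr(seq_len(H), function(ti) {
      tibble(year = ti - 1, age = par$ages, sex = par$sexes,
             first_events = strata_rec$first_events[ti, ],
             repeat_events = strata_rec$repeat_events[ti, ],
             cad_deaths = strata_rec$cad_deaths[ti, ],
             other_deaths = strata_rec$other_deaths[ti, ],
             history_py = strata_rec$history_py[ti, ],
             alive = strata_rec$alive[ti, ])
    })
  }
  list(
    series = series,
    ledger_strata = strata_tbl,
    final = list(well = W, cad = C1 + C2, history = Hs, dead = dead),
    totals = list(
      cost_by_category = total_cost_by_cat,
      total_cost = sum(total_cost_by_cat),
      yll = sum(series$yll),
      yld = sum(series$yld),
      dalys = sum(series$yll) + sum(series$yld),
      first_events = sum(series$first_events),
      repeat_events = sum(series$repeat_events),
      events = sum(series$first_events) + sum(series$repeat_events),
      cad_deaths = sum(series$cad_deaths),
      other_deaths = sum(series$other_deaths)
    )
  )
}
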