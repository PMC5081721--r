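# Stochastic individual-level microsimulation oracle. Simulates every person
# of each (age, sex) stratum through the four-state model with sampled
# transitions (exact per-stratum binomial/multinomial sampling, which is
# distributionally identical to per-person Bernoulli draws), mirroring the
# cohort engine's semantics: yearly cycles, one-year acute state, repeat
# events from the history state with elevated fatality, top age absorbing,
# ages capped at the grid top.
#
# Returns total first events, repeat events, CAD deaths and other deaths
# over the horizon.
microsim_once <- function(inputs, option, cfg) {
  lt <- dplyr::arrange(inputs$life_table, sex, age)
  mb <- dplyr::arrange(inputs$morbidity, sex, age)
  pp <- dplyr::arrange(inputs$population, sex, age)
  n_age <- max(lt$age) + 1
  S <- 2 * n_age
  if (is.character(option)) option <- policy_option(option)
  traj <- build_trajectory(option, cfg$scenario, horizon = cfg$horizon_years)
  e <- traj$intake_e_pct
  risk <- cfg$risk

  W <- pp$count; C1 <- numeric(S); C2 <- numeric(S); Hs <- numeric(S)
  tot <- c(first_events = 0, repeat_events = 0, cad_deaths = 0,
           other_deaths = 0)
  shift <- function(v) {
    w <- numeric(S)
    i1 <- seq_len(n_age); i2 <- n_age + i1
    w[i1[-1]] <- v[i1[-n_age]]; w[n_age] <- w[n_age] + v[n_age]
    w[i2[-1]] <- v[i2[-n_age]]; w[S] <- w[S] + v[S]
    w
  }
  for (ti in seq_len(cfg$horizon_years)) {
    rrf <- rr_for_intake_change(e[ti] - e[1], risk$rr_per_2epct)
    tr <- tfacea:::transition_rows(lt$q_all_cause, mb$p_cad_first,
                                   mb$case_fatality, rrf, risk)
    fe <- dow <- d1 <- d2 <- re <- doh <- numeric(S)
    for (s in seq_len(S)) {
      if (W[s] > 0) {
        draw <- rmultinom(1, W[s], c(tr$p_stay_well[s], tr$p_first_cad[s],
                                     tr$p_death_other_well[s]))
        fe[s] <- draw[2]; dow[s] <- draw[3]; W[s] <- draw[1]
      }
      if (C1[s] > 0) d1[s] <- rbinom(1, C1[s], tr$p_death_cad[s])
      if (C2[s] > 0) d2[s] <- rbinom(1, C2[s], tr$p_death_repeat_cad[s])
      if (Hs[s] > 0) {
        draw <- rmultinom(1, Hs[s], c(tr$p_stay_history[s],
                                      tr$p_repeat_cad[s],
                                      tr$p_death_other_history[s]))
        re[s] <- draw[2]; doh[s] <- draw[3]; Hs[s] <- draw[1]
      }
    }
    tot <- tot + c(sum(fe), sum(re), sum(d1) + sum(d2), sum(dow) + sum(doh))
    Hs <- shift(Hs + (C1 - d1) + (C2 - d2))
    W <- shift(W)
    C1 <- shift(fe)
    C2 <- shift(re)
  }
  tot
}

microsim_replicates <- function(inputs, option, cfg, n_rep, seed) {
  set.seed(seed)
  t(vapply(seq_len(n_rep),
           function(i) microsim_once(inputs, option, cfg),
           numeric(4)))
}
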