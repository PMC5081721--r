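#' Relative-risk parameters for CAD and trans-fat intake
#'
#' The pooled multivariable-adjusted relative risk of coronary-artery-disease
#' events is 1.23 (95% CI 1.11--1.37) per 2 E% of trans-fat intake replacing
#' carbohydrate. Second and subsequent events carry a relative risk of 1.5
#' versus the first event, and death from a repeat event a relative risk of
#' 1.5 versus death from the first event (both assumptions of the model).
#'
#' @param rr_per_2epct Relative risk per 2 E% intake.
#' @param rr_ci Length-2 vector, the 95% CI of `rr_per_2epct` (used by the
#'   PSA's lognormal).
#' @param rr_repeat_event RR of a second or subsequent CAD event.
#' @param rr_death_second_event RR of death from a repeat event vs the first.
#' @return An object of class `tfa_risk_parameters`.
#' @export
risk_parameters <- function(rr_per_2epct = 1.23,
                            rr_ci = c(1.11, 1.37),
                            rr_repeat_event = 1.5,
                            rr_death_second_event = 1.5) {
  if (rr_per_2epct <= 0 || rr_repeat_event <= 0 || rr_death_second_event <= 0) {
    abort("all relative risks must be positive")
  }
  structure(list(rr_per_2epct = rr_per_2epct, rr_ci = rr_ci,
                 rr_repeat_event = rr_repeat_event,
                 rr_death_second_event = rr_death_second_event),
            class = "tfa_risk_parameters")
}

#' Relative-risk multiplier for an intake change
#'
#' Log-linear dose scaling of the per-2-E% relative risk:
#' `rr_per_2epct ^ (delta_e_pct / 2)`. A 2 E% increase returns the RR itself;
#' no change returns 1.
#'
#' @param delta_e_pct Intake change in E% (current minus baseline).
#' @param rr_per_2epct Relative risk per 2 E%.
#' @return The RR multiplier (vectorised over `delta_e_pct`).
#' @export
rr_for_intake_change <- function(delta_e_pct, rr_per_2epct = 1.23) {
  rr_per_2epct^(delta_e_pct / 2)
}

trajectory_intake_at <- function(trajectory, t) {
  idx <- match(t, trajectory$year)
  if (anyNA(idx)) abort("trajectory is not defined at the requested year(s)")
  trajectory$intake_e_pct[idx]
}

#' First-CAD-event probability at a model year
#'
#' Scales the baseline first-event probability (which already embeds the
#' baseline intake) by the relative-risk multiplier for the intake change
#' since year 0: `p_t = min(1, p0 * rr^( (E_t - E_0) / 2 ))`. At `t = 0` the
#' baseline probability is returned exactly.
#'
#' @param t Model year (may be a vector).
#' @param age,sex Stratum selectors (scalars).
#' @param trajectory A [build_trajectory()] result.
#' @param morbidity Morbidity table tibble (`age`, `sex`, `p_cad_first`, ...).
#' @param risk_params A [risk_parameters()].
#' @return First-event probabilities, one per element of `t`.
#' @export
cad_probability_at <- function(t, age, sex, trajectory, morbidity,
                               risk_params = risk_parameters()) {
  p0 <- morbidity$p_cad_first[morbidity$age == age & morbidity$sex == sex]
  if (length(p0) != 1) abort("stratum not found in morbidity table")
  e0 <- trajectory_intake_at(trajectory, 0)
  et <- trajectory_intake_at(trajectory, t)
  out <- pmin(1, pmax(0, p0 * rr_for_intake_change(et - e0,
                                                   risk_params$rr_per_2epct)))
  out[t == 0] <- p0
  out
}

# Internal: the eight transition probabilities (+ repeat-event fatality) for
# every stratum at one model year, computed on aligned numeric vectors.
# `q` all-cause, `p0` baseline first-event, `cf` case fatality; `rrf` the
# intake RR multiplier at this year. Ages where q == 1 are treated as fully
# absorbing (death claims everyone in Well/History).
transition_rows <- function(q, p0, cf, rrf, risk, check = TRUE) {
  if (check) {
    for (nm in c("q", "p0", "cf")) {
      v <- get(nm)
      if (any(!is.finite(v) | v < 0 | v > 1)) {
        i <- which(!is.finite(v) | v < 0 | v > 1)[1]
        abort(sprintf("invalid probability in input '%s' at stratum %d", nm, i))
      }
    }
  }
  p_first <- pmin(1, p0 * rrf)
  # Non-CAD death from Well/History: all-cause with the CAD-death hazard
  # removed by hazard subtraction, guarded to [0, 1].
  h_all <- -log1p(-q)
  h_cad_death <- -log1p(-p_first * cf)
  q_other <- -expm1(-pmax(0, h_all - h_cad_death))
  absorbing <- q >= 1 - 1e-12
  p_first[absorbing] <- 0
  q_other[absorbing] <- 1
  p_death_other_well <- pmin(q_other, 1 - p_first)
  p_stay_well <- 1 - p_first - p_death_other_well
  p_repeat <- pmin(1, risk$rr_repeat_event * p_first)
  p_repeat[absorbing] <- 0
  p_death_other_history <- pmin(q_other, 1 - p_repeat)
  p_stay_history <- 1 - p_repeat - p_death_other_history
  cf_repeat <- pmin(1, risk$rr_death_second_event * cf)
  list(
    p_stay_well = p_stay_well,
    p_first_cad = p_first,
    p_survive_cad = 1 - cf,
    p_stay_history = p_stay_history,
    p_repeat_cad = p_repeat,
    p_death_other_well = p_death_other_well,
    p_death_cad = cf,
    p_death_other_history = p_death_other_history,
    p_death_repeat_cad = cf_repeat,
    p_survive_repeat_cad = 1 - cf_repeat
  )
}

# RR multiplier per year of a trajectory (vector over years 0..horizon).
trajectory_rr_factors <- function(trajectory, risk) {
  e0 <- trajectory$intake_e_pct[trajectory$year == 0]
  rr_for_intake_change(trajectory$intake_e_pct - e0, risk$rr_per_2epct)
}

#' Assemble the transition-probability table
#'
#' Builds the eight Fig-1-style transition probabilities (plus the
#' repeat-event fatality) for every (year, age, sex) on the input grid.
#' Outgoing probabilities from each state sum to one by construction.
#'
#' @param life_table,morbidity Input tibbles on a shared age-sex grid.
#' @param trajectory A [build_trajectory()] result.
#' @param risk_params A [risk_parameters()].
#' @param years Years to tabulate (default: all years of the trajectory
#'   except the final boundary point).
#' @return A tibble with columns `year`, `age`, `sex`, and the transition
#'   probabilities `p_stay_well`, `p_first_cad`, `p_survive_cad`,
#'   `p_stay_history`, `p_repeat_cad`, `p_death_other_well`, `p_death_cad`,
#'   `p_death_other_history`, `p_death_repeat_cad`.
#' @export
assemble_transitions <- function(life_table, morbidity, trajectory,
                                 risk_params = risk_parameters(),
                                 years = NULL) {
  grid <- life_table %>%
    arrange(.data$sex, .data$age) %>%
    left_join(morbidity, by = c("age", "sex"))
  if (anyNA(grid$p_cad_first)) {
    abort("morbidity table grid does not match the life table grid")
  }
  rrf_all <- trajectory_rr_factors(trajectory, risk_params)
  if (is.null(years)) years <- head(trajectory$year, -1)
  purrr::map_dfr(years, function(t) {
    rrf <- rrf_all[trajectory$year == t]
    rows <- transition_rows(grid$q_all_cause, grid$p_cad_first,
                            grid$case_fatality, rrf, risk_params)
    tibble(year = t, age = grid$age, sex = grid$sex, !!!rows[1:9])
  })
}
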