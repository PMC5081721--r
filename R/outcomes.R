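#' Discount factor
#'
#' `(1 + rate)^(-t)`; the model applies a 3.5% annual rate to both costs and
#' effects by default.
#'
#' @param t Time in years (vectorised).
#' @param rate Annual discount rate, `>= 0`.
#' @return Discount multipliers.
#' @examples
#' discount_factor(1, 0.035) # 0.966...
#' @export
discount_factor <- function(t, rate = 0.035) {
  if (any(rate < 0)) abort("discount rate must be >= 0")
  (1 + rate)^(-t)
}

#' Discounted remaining life expectancy from a life table
#'
#' Expected discounted future whole years of life at each (age, sex) of the
#' input life table, by backward recursion over the annual survival
#' probabilities. Used for the years-of-life-lost (YLL) component of DALYs.
#'
#' @param life_table A life table tibble (`age`, `sex`, `q_all_cause`).
#' @param rate Annual discount rate applied to future life years.
#' @return A tibble `age`, `sex`, `life_expectancy`.
#' @export
discounted_life_expectancy <- function(life_table, rate = 0.035) {
  lt <- life_table %>% arrange(.data$sex, .data$age)
  n_age <- max(lt$age) + 1
  e <- disc_life_expectancy(lt$q_all_cause, n_age, rate)
  lt %>% select("age", "sex") %>% mutate(life_expectancy = e)
}

#' Discounted costs from an event ledger
#'
#' Per model year: acute-event costs (in-patient + medication + emergency +
#' outpatient, per event), chronic costs (primary care + informal care +
#' production losses from morbidity, per history person-year), mortality
#' costs (production losses per CAD death) and policy-measure costs (active
#' measures of the option, per alive person per year), each multiplied by the
#' year's discount factor.
#'
#' @param ledger A per-year ledger tibble with columns `year`,
#'   `first_events`, `repeat_events`, `cad_deaths`, `history_py`, `alive`.
#' @param option A [policy_option()] (or identifier); determines the measure
#'   schedule.
#' @param costs A [cost_set()].
#' @param discount_rate Annual discount rate.
#' @return A tibble with `year`, `cost_acute`, `cost_chronic`,
#'   `cost_mortality`, `cost_measures`, `cost_total` (all discounted).
#' @export
compute_costs <- function(ledger, option, costs = cost_set(),
                          discount_rate = 0.035) {
  if (is.character(option)) option <- policy_option(option)
  t <- ledger$year
  df <- discount_factor(t, discount_rate)
  mpc_full <- measure_per_capita(option, costs, max(t) + 1)
  mpc <- mpc_full[t + 1]
  acute_bundle <- costs$inpatient + costs$medication + costs$emergency +
    costs$outpatient
  chronic_bundle <- costs$primary_care + costs$informal_care +
    costs$production_loss_morbidity
  events <- ledger$first_events + ledger$repeat_events
  tibble(
    year = t,
    cost_acute = events * acute_bundle * df,
    cost_chronic = ledger$history_py * chronic_bundle * df,
    cost_mortality = ledger$cad_deaths * costs$production_loss_mortality * df,
    cost_measures = ledger$alive * mpc * df
  ) %>%
    mutate(cost_total = .data$cost_acute + .data$cost_chronic +
             .data$cost_mortality + .data$cost_measures)
}

#' DALYs from a stratified event ledger
#'
#' Years of life lost (YLL) are the discounted remaining life expectancy --
#' computed from the run's own life table -- at the age and sex of each CAD
#' death, further discounted to the year of death. Years lived with
#' disability (YLD) are acute events times the acute disability weight times
#' its duration, plus history person-years times the chronic weight, both
#' discounted. No age-weighting is applied.
#'
#' @param ledger_strata A per-(year, age, sex) ledger tibble with columns
#'   `year`, `age`, `sex`, `first_events`, `repeat_events`, `cad_deaths`,
#'   `history_py` (as from `run_option(..., stratified = TRUE)`).
#' @param life_table The life table used by the run.
#' @param daly A [daly_parameters()].
#' @param rate Annual discount rate of the run.
#' @return A list with components `yll`, `yld` and `dalys`.
#' @export
compute_dalys <- function(ledger_strata, life_table, daly, rate = 0.035) {
  e_rate <- if (daly$discount_effects) rate else 0
  e <- discounted_life_expectancy(life_table, e_rate)
  df <- ledger_strata %>%
    left_join(e, by = c("age", "sex")) %>%
    mutate(dfac = if (daly$discount_effects) discount_factor(.data$year, rate) else 1)
  yll <- sum(df$cad_deaths * df$life_expectancy * df$dfac)
  yld <- sum(((df$first_events + df$repeat_events) *
                daly$disability_weight_acute * daly$acute_duration +
                df$history_py * daly$disability_weight_history) * df$dfac)
  list(yll = yll, yld = yld, dalys = yll + yld)
}
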