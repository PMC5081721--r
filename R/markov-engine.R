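#' Initialise the cohort state
#'
#' Places every person of the population pyramid in the Well state; the CAD,
#' History and Dead states start empty (the model follows an event-free
#' closed cohort from "today").
#'
#' @param population A population tibble (`age`, `sex`, `count`).
#' @return A tibble of class `tfa_cohort_state` with columns `age`, `sex`,
#'   `well`, `cad`, `history`, `dead`.
#' @export
initialize_cohort <- function(population) {
  out <- population %>%
    arrange(.data$sex, .data$age) %>%
    mutate(well = .data$count, cad = 0, history = 0, dead = 0) %>%
    select("age", "sex", "well", "cad", "history", "dead")
  structure(out, class = c("tfa_cohort_state", class(out)))
}

#' Advance the cohort one yearly cycle
#'
#' Deterministic expected-value update: fractions of each stratum flow
#' Well to (Well, CAD, Dead-other), CAD to (History, Dead-CAD), History to
#' (History, repeat CAD, Dead-other); everyone then ages by one year. The
#' top age is absorbing (its all-cause death probability is 1), which keeps
#' the closed cohort exactly conserved.
#'
#' Occupants of the `cad` column are treated as first-event cases (fatality
#' `p_death_cad`); supply `cad_first`/`cad_repeat` columns instead to
#' distinguish repeat events, whose fatality is `p_death_repeat_cad`.
#'
#' @param state A cohort state tibble from [initialize_cohort()] (or a
#'   previous step).
#' @param transitions A transition table from [assemble_transitions()].
#' @param t Model year whose transition rows apply.
#' @return A list with `state` (the advanced cohort) and `events` (a one-row
#'   tibble: `year`, `first_events`, `repeat_events`, `cad_deaths`,
#'   `other_deaths`, `alive`, `history_py`).
#' @export
markov_step <- function(state, transitions, t = 0) {
  if ("year" %in% names(transitions)) {
    transitions <- transitions %>% filter(.data$year == t)
  }
  df <- state %>%
    arrange(.data$sex, .data$age) %>%
    left_join(transitions, by = c("age", "sex"))
  if (anyNA(df$p_first_cad)) {
    abort("transitions are not defined for every stratum of the state")
  }
  n_age <- max(df$age) + 1
  c1 <- if ("cad_first" %in% names(state)) df$cad_first else df$cad
  c2 <- if ("cad_repeat" %in% names(state)) df$cad_repeat else 0 * df$cad

  fe <- df$well * df$p_first_cad
  dow <- df$well * df$p_death_other_well
  w_stay <- df$well - fe - dow
  d1 <- c1 * df$p_death_cad
  d2 <- c2 * df$p_death_repeat_cad
  re <- df$history * df$p_repeat_cad
  doh <- df$history * df$p_death_other_history
  h_stay <- df$history - re - doh
  if (any(w_stay < -1e-9) || any(h_stay < -1e-9)) {
    abort("negative occupancy after update: transition rows are inconsistent")
  }

  events <- tibble(
    year = t,
    first_events = sum(fe),
    repeat_events = sum(re),
    cad_deaths = sum(d1 + d2),
    other_deaths = sum(dow + doh),
    alive = sum(df$well + c1 + c2 + df$history),
    history_py = sum(df$history)
  )
  new_state <- df %>%
    select("age", "sex") %>%
    mutate(
      well = age_up(w_stay, n_age),
      cad_first = age_up(fe, n_age),
      cad_repeat = age_up(re, n_age),
      history = age_up((c1 - d1) + (c2 - d2) + h_stay, n_age),
      dead = df$dead + dow + doh + d1 + d2
    ) %>%
    mutate(cad = .data$cad_first + .data$cad_repeat, .after = "well")
  # deaths stay attributed to the stratum where they occurred; living
  # compartments have aged by one year
  list(state = structure(new_state, class = c("tfa_cohort_state",
                                              class(new_state))),
       events = events)
}

#' Run one policy option through the cohort model
#'
#' Builds the option's intake trajectory under the configured scenario,
#' assembles the time-varying transition probabilities, runs the closed
#' multi-age cohort in yearly cycles over the horizon, and attaches
#' discounted costs and DALYs.
#'
#' @param inputs A `tfa_inputs` object ([read_inputs()] / [as_inputs()]).
#' @param option A [policy_option()] or its identifier.
#' @param run_config Optional [run_config()]; defaults to the one carried by
#'   `inputs`.
#' @param stratified Also record the per-(year, age, sex) event ledger
#'   (`$ledger_strata`), needed by [compute_dalys()].
#' @return An object of class `tfa_run`: a list with `option`, `scenario`,
#'   `ledger` (per-year tibble), `cost_by_category`, `total_cost`, `yll`,
#'   `yld`, `dalys`, event/death totals.
#' @export
run_option <- function(inputs, option, run_config = NULL,
                       stratified = FALSE) {
  stopifnot(inherits(inputs, "tfa_inputs"))
  cfg <- run_config %||% inputs$run_config
  if (is.character(option)) option <- policy_option(option)
  par <- core_pars(inputs, option, cfg)
  res <- core_run(par, strata = stratified)
  new_run(res, option, cfg)
}

new_run <- function(res, option, cfg) {
  s <- res$series
  ledger <- tibble(
    year = seq_along(s$alive) - 1,
    alive = s$alive, well = s$well, cad = s$cad, history_py = s$history_py,
    dead = s$dead, first_events = s$first_events,
    repeat_events = s$repeat_events, cad_deaths = s$cad_deaths,
    other_deaths = s$other_deaths,
    yll = s$yll, yld = s$yld,
    cost_acute = s$cost_acute, cost_chronic = s$cost_chronic,
    cost_mortality = s$cost_mortality, cost_measures = s$cost_measures
  )
  structure(list(
    option = option$id,
    scenario = cfg$scenario$name,
    ledger = ledger,
    ledger_strata = res$ledger_strata,
    cost_by_category = res$totals$cost_by_category,
    total_cost = res$totals$total_cost,
    yll = res$totals$yll,
    yld = res$totals$yld,
    dalys = res$totals$dalys,
    first_events = res$totals$first_events,
    repeat_events = res$totals$repeat_events,
    events = res$totals$events,
    cad_deaths = res$totals$cad_deaths,
    other_deaths = res$totals$other_deaths,
    run_config = cfg
  ), class = "tfa_run")
}

#' @export
print.tfa_run <- function(x, ...) {
  cat("<tfa_run> option:", x$option, " scenario:", x$scenario, "\n")
  cat(sprintf("  discounted total cost: %.0f EUR\n", x$total_cost))
  cat(sprintf("  discounted DALYs: %.1f (YLL %.1f + YLD %.1f)\n",
              x$dalys, x$yll, x$yld))
  cat(sprintf("  CAD events: %.1f  CAD deaths: %.1f\n",
              x$events, x$cad_deaths))
  invisible(x)
}

#' Run the deterministic analysis for all configured options
#'
#' Runs every policy option in the configuration under the configured
#' scenario and computes the incremental analysis against the reference
#' option.
#'
#' @inheritParams run_option
#' @return An object of class `tfa_analysis`: a list with `runs` (named list
#'   of `tfa_run`), `by_option` (one-row-per-option tibble) and `incremental`
#'   (tibble mirroring the option-vs-reference comparison).
#' @export
run_deterministic <- function(inputs, run_config = NULL) {
  stopifnot(inherits(inputs, "tfa_inputs"))
  cfg <- run_config %||% inputs$run_config
  runs <- setNames(
    lapply(cfg$options, function(id) run_option(inputs, id, cfg)),
    cfg$options
  )
  by_option <- purrr::map_dfr(runs, glance_run)
  incr <- if ("reference" %in% names(runs)) {
    incremental_table(runs, reference = "reference",
                      gdp_per_capita = cfg$gdp_per_capita)
  } else {
    NULL
  }
  structure(list(runs = runs, by_option = by_option, incremental = incr,
                 run_config = cfg), class = "tfa_analysis")
}

glance_run <- function(run) {
  tibble(
    option = run$option,
    scenario = run$scenario,
    total_cost = run$total_cost,
    cost_acute = unname(run$cost_by_category["acute"]),
    cost_chronic = unname(run$cost_by_category["chronic"]),
    cost_mortality = unname(run$cost_by_category["mortality"]),
    cost_measures = unname(run$cost_by_category["measures"]),
    dalys = run$dalys,
    yll = run$yll,
    yld = run$yld,
    events = run$events,
    cad_deaths = run$cad_deaths
  )
}

#' @export
print.tfa_analysis <- function(x, ...) {
  cat("<tfa_analysis> scenario:", x$run_config$scenario$name, "\n")
  print(x$by_option %>% select("option", "total_cost", "dalys", "events"))
  if (!is.null(x$incremental)) {
    cat("\nIncremental vs reference:\n")
    print(x$incremental)
  }
  invisible(x)
}
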