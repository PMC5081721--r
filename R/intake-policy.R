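#' Initial-intake scenario
#'
#' The population's initial industrially-produced trans-fat (iTFA) intake,
#' expressed in percent of total energy (E%). Presets mirror the evaluated
#' scenarios: base case 0.3 E%, scenario 1 (`s1`) 0.15, scenario 2 (`s2`)
#' 0.45, scenario 3 (`s3`) 0.7. Optional age/sex multipliers scale the
#' overall mean per stratum (default: every stratum at the overall mean).
#'
#' @param name One of `"base"`, `"s1"`, `"s2"`, `"s3"`, or any label when
#'   `initial_intake` is given explicitly.
#' @param initial_intake Overall mean initial intake in E%; defaults to the
#'   preset value for `name`.
#' @param multipliers Optional tibble with columns `age`, `sex`, `multiplier`
#'   scaling the overall mean per stratum.
#' @return An object of class `tfa_scenario`.
#' @export
scenario_spec <- function(name = "base", initial_intake = NULL,
                          multipliers = NULL) {
  if (is.null(initial_intake)) {
    if (!name %in% names(SCENARIO_INTAKES)) {
      abort(paste0("unknown scenario '", name,
                   "' (field 'scenario'); known presets: ",
                   paste(names(SCENARIO_INTAKES), collapse = ", ")))
    }
    initial_intake <- unname(SCENARIO_INTAKES[name])
  }
  if (initial_intake < 0) abort("initial intake must be >= 0")
  structure(list(name = name, initial_intake = initial_intake,
                 multipliers = multipliers), class = "tfa_scenario")
}

#' Policy option definition
#'
#' The four policy options and their intake phase-out assumptions:
#' * `reference` — no EU-level action; iTFA leaves the food supply over 10
#'   years through national efforts and industry innovation. No measure costs.
#' * `voluntary` — EU-level voluntary agreements; total removal after 5
#'   years. Food inspection runs for the whole horizon.
#' * `labeling` — mandatory trans-fat labeling of prepackaged foods; the
#'   first 2 years follow the reference slope, then the prepackaged share
#'   (50% of intake) declines to zero over 3 years while the rest stays on
#'   the reference path. Food inspection runs for the whole horizon and the
#'   information measures (school, worksite, mass media, physician
#'   counseling) for an initial window (default 5 years).
#' * `legal_limit` — a legislative iTFA limit; total removal in 2 years.
#'   Food inspection runs for the whole horizon.
#'
#' @param id One of `"reference"`, `"voluntary"`, `"labeling"`,
#'   `"legal_limit"`.
#' @param info_measure_years Years over which the labeling option's
#'   information measures accrue (default 5).
#' @return An object of class `tfa_policy_option` with fields `id`,
#'   `phase_out_years` and a `measures` tibble (`measure`, `from`, `to`;
#'   year intervals are half-open `[from, to)`, `to = Inf` meaning the whole
#'   horizon).
#' @export
policy_option <- function(id = POLICY_OPTION_IDS, info_measure_years = 5) {
  id <- match.arg(id)
  measures <- switch(
    id,
    reference = tibble(measure = character(), from = double(), to = double()),
    voluntary = tibble(measure = "food_inspection", from = 0, to = Inf),
    labeling = bind_rows(
      tibble(measure = "food_inspection", from = 0, to = Inf),
      tibble(measure = c("school", "worksite", "mass_media",
                         "physician_counseling"),
             from = 0, to = info_measure_years)
    ),
    legal_limit = tibble(measure = "food_inspection", from = 0, to = Inf)
  )
  phase_out <- switch(id, reference = 10, voluntary = 5, labeling = 10,
                      legal_limit = 2)
  structure(list(id = id, phase_out_years = phase_out, measures = measures),
            class = "tfa_policy_option")
}

#' @rdname policy_option
#' @param ids Identifiers of the options to build.
#' @export
policy_options <- function(ids = POLICY_OPTION_IDS, info_measure_years = 5) {
  setNames(lapply(ids, policy_option, info_measure_years = info_measure_years),
           ids)
}

# Decay from intake e0 to 0 over `T` years, evaluated at integer years t.
# Linear is the default anchor-to-anchor interpolation; the exponential
# variant is scaled so it still reaches exactly 0 at year T.
decay_curve <- function(e0, phase_out, t, shape = "linear", rate = 0.5) {
  if (phase_out <= 0) return(ifelse(t >= 0, 0, e0))
  if (shape == "linear") {
    e0 * pmax(0, 1 - t / phase_out)
  } else {
    raw <- (exp(-rate * t) - exp(-rate * phase_out)) / (1 - exp(-rate * phase_out))
    e0 * pmax(0, raw)
  }
}

#' Build the iTFA intake trajectory for a policy option
#'
#' Produces the intake (E%) at each model year `t = 0..horizon` for one
#' policy option under one initial-intake scenario. Trajectories are
#' non-increasing, start at the scenario's initial intake and reach exactly
#' zero by the option's phase-out completion (10 y reference, 5 y voluntary,
#' 2 y legal limit; labeling follows the reference slope for 2 years, then
#' its prepackaged half declines to zero over 3 years while the
#' non-prepackaged half continues on the reference path to year 10).
#'
#' @param option A [policy_option()] or its identifier.
#' @param scenario A [scenario_spec()] or preset name.
#' @param horizon Number of model years.
#' @param shape `"linear"` (default) or `"exponential"` decay between anchor
#'   points.
#' @return A tibble of class `tfa_trajectory` with columns `year`,
#'   `intake_e_pct`.
#' @export
build_trajectory <- function(option, scenario = "base", horizon = 85,
                             shape = c("linear", "exponential")) {
  shape <- match.arg(shape)
  if (is.character(option)) option <- policy_option(option)
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  e0 <- scenario$initial_intake
  t <- 0:horizon
  if (max(t) < option$phase_out_years && e0 > 0) {
    warn(paste0("horizon (", horizon, " y) is shorter than the ",
                option$id, " phase-out (", option$phase_out_years,
                " y); trajectory truncated"))
  }
  intake <- if (option$id == "labeling") {
    # Two components of equal initial size: prepackaged and non-prepackaged.
    # Both ride the reference 10-y slope for 2 years; the prepackaged share
    # then drops linearly to 0 over years 2..5, with no spillover to the
    # non-prepackaged share.
    non_prepack <- decay_curve(e0 / 2, 10, t, shape)
    prepack_at2 <- decay_curve(e0 / 2, 10, 2, shape)
    prepack <- ifelse(t <= 2, decay_curve(e0 / 2, 10, t, shape),
                      decay_curve(prepack_at2, 3, t - 2, shape))
    non_prepack + prepack
  } else {
    decay_curve(e0, option$phase_out_years, t, shape)
  }
  out <- tibble(year = t, intake_e_pct = intake)
  structure(out, class = c("tfa_trajectory", class(out)),
            option = option$id, scenario = scenario$name,
            initial_intake = e0, multipliers = scenario$multipliers)
}

#' Cumulative intake of a trajectory
#'
#' Sum of the yearly intakes over the trajectory, in E%-years. Across the
#' four options the ordering `legal_limit <= voluntary <= labeling <=
#' reference` holds for every scenario.
#'
#' @param trajectory A [build_trajectory()] result.
#' @return A single number (E%-years).
#' @export
cumulative_intake <- function(trajectory) {
  sum(trajectory$intake_e_pct)
}

#' Export one or more trajectories for inspection
#'
#' @param trajectories A list of `tfa_trajectory` objects.
#' @param path Optional CSV path.
#' @return A tibble with columns `option`, `year`, `intake_e_pct`.
#' @export
export_trajectories <- function(trajectories, path = NULL) {
  out <- purrr::map_dfr(trajectories, function(tr) {
    tibble(option = attr(tr, "option"), year = tr$year,
           intake_e_pct = tr$intake_e_pct)
  })
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
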