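#' Model cost set (2011 euros)
#'
#' The cost parameters of the model: per-event and per-person-year disease
#' costs and per-person-per-year costs of the policy measures. All values are
#' in 2011 euros; no currency or inflation adjustment happens inside the
#' package.
#'
#' @param production_loss_mortality Production losses per CAD death.
#' @param production_loss_morbidity Production losses per history person-year.
#' @param informal_care Informal-care cost per history person-year.
#' @param primary_care Primary-care cost per history person-year.
#' @param outpatient Outpatient cost per acute event.
#' @param emergency Accident-and-emergency cost per acute event.
#' @param inpatient In-patient cost per acute event.
#' @param medication Medication cost per acute event.
#' @param school School-based intervention, per person per year.
#' @param worksite Worksite intervention, per person per year.
#' @param mass_media Mass-media campaigns, per person per year.
#' @param physician_counseling Physician counseling, per person per year.
#' @param food_inspection Food-inspection programme, per person per year.
#' @return An object of class `tfa_cost_set` (a named list of non-negative
#'   numbers).
#' @export
cost_set <- function(production_loss_mortality = 5101.94,
                     production_loss_morbidity = 2158.88,
                     informal_care = 6440.19,
                     primary_care = 617.34,
                     outpatient = 854.56,
                     emergency = 213.78,
                     inpatient = 3557.46,
                     medication = 1605.36,
                     school = 1.15,
                     worksite = 4.48,
                     mass_media = 1.90,
                     physician_counseling = 8.28,
                     food_inspection = 0.86) {
  costs <- list(
    production_loss_mortality = production_loss_mortality,
    production_loss_morbidity = production_loss_morbidity,
    informal_care = informal_care,
    primary_care = primary_care,
    outpatient = outpatient,
    emergency = emergency,
    inpatient = inpatient,
    medication = medication,
    school = school,
    worksite = worksite,
    mass_media = mass_media,
    physician_counseling = physician_counseling,
    food_inspection = food_inspection
  )
  v <- unlist(costs)
  if (any(!is.finite(v)) || any(v < 0)) abort("all costs must be finite and >= 0")
  structure(costs, class = "tfa_cost_set")
}

MEASURE_NAMES <- c("school", "worksite", "mass_media", "physician_counseling",
                   "food_inspection")

#' DALY computation parameters
#'
#' Disability weights carry no package defaults; the packaged example
#' configuration (`inst/extdata/eu_default_config.yaml`) ships values sourced
#' from the published Global Burden of Disease 2010 weight tables.
#'
#' @param disability_weight_acute Disability weight for the acute CAD year,
#'   in `[0, 1]`.
#' @param disability_weight_history Disability weight for a year lived in the
#'   post-acute (history of CAD) state, in `[0, 1]`.
#' @param acute_duration Duration of acute disability in years (default 1, the
#'   cycle length).
#' @param discount_effects Whether DALYs are discounted at the run's rate.
#' @return An object of class `tfa_daly_parameters`.
#' @export
daly_parameters <- function(disability_weight_acute,
                            disability_weight_history,
                            acute_duration = 1,
                            discount_effects = TRUE) {
  if (disability_weight_acute < 0 || disability_weight_acute > 1 ||
      disability_weight_history < 0 || disability_weight_history > 1) {
    abort("disability weights must lie in [0, 1]")
  }
  structure(list(
    disability_weight_acute = disability_weight_acute,
    disability_weight_history = disability_weight_history,
    acute_duration = acute_duration,
    discount_effects = isTRUE(discount_effects)
  ), class = "tfa_daly_parameters")
}

#' Run configuration
#'
#' Collects the run-level settings: the lifetime horizon (85 one-year cycles),
#' the 3.5%/y discount rate applied to both costs and effects, the initial
#' intake scenario, the policy options to evaluate, the EU GDP-per-capita
#' threshold used for cost-effectiveness classification, the cost set, DALY
#' parameters, and the PSA settings.
#'
#' @param horizon_years Number of one-year cycles (default 85).
#' @param discount_rate Annual discount rate in `[0, 1)` (default 0.035).
#' @param scenario A scenario name (`"base"`, `"s1"`, `"s2"`, `"s3"`) or a
#'   [scenario_spec()].
#' @param options Character vector of policy option identifiers, a subset of
#'   `reference`, `voluntary`, `labeling`, `legal_limit`.
#' @param gdp_per_capita GDP per capita in euros (default 23300).
#' @param costs A [cost_set()].
#' @param daly A [daly_parameters()]; defaults to the packaged example values.
#' @param risk A [risk_parameters()].
#' @param decay_shape Shape of the intake decline between its anchor points:
#'   `"linear"` (default) or `"exponential"`.
#' @param psa A list with elements `n_draws` (default 1000), `seed`,
#'   `cost_se_frac` (SE as a fraction of the mean for point-valued costs and
#'   assumption RRs, default 0.2) and `table_cv` (coefficient of variation of
#'   the per-table lognormal multipliers, default 0.1).
#' @return An object of class `tfa_run_config`.
#' @export
run_config <- function(horizon_years = 85,
                       discount_rate = 0.035,
                       scenario = "base",
                       options = POLICY_OPTION_IDS,
                       gdp_per_capita = 23300,
                       costs = cost_set(),
                       daly = NULL,
                       risk = risk_parameters(),
                       decay_shape = c("linear", "exponential"),
                       psa = list()) {
  if (horizon_years < 1) abort("horizon_years must be at least 1")
  if (discount_rate < 0 || discount_rate >= 1) {
    abort("discount_rate must lie in [0, 1)")
  }
  bad <- setdiff(options, POLICY_OPTION_IDS)
  if (length(bad)) {
    abort(paste0("unknown policy option(s): ", paste(bad, collapse = ", "),
                 " (field 'options')"))
  }
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  if (is.null(daly)) daly <- default_daly_parameters()
  psa_defaults <- list(n_draws = 1000L, seed = 1L, cost_se_frac = 0.2,
                       table_cv = 0.1)
  psa <- utils::modifyList(psa_defaults, psa)
  structure(list(
    horizon_years = as.integer(horizon_years),
    discount_rate = discount_rate,
    scenario = scenario,
    options = options,
    gdp_per_capita = gdp_per_capita,
    costs = costs,
    daly = daly,
    risk = risk,
    decay_shape = match.arg(decay_shape),
    psa = psa
  ), class = "tfa_run_config")
}

default_config_path <- function() {
  system.file("extdata", "eu_default_config.yaml", package = "tfacea",
              mustWork = TRUE)
}

# Disability weights are externally sourced (GBD 2010) and deliberately live
# only in the packaged example configuration, not as function defaults.
default_daly_parameters <- function() {
  cfg <- yaml::read_yaml(default_config_path())
  daly_parameters(
    disability_weight_acute = cfg$daly$disability_weight_acute,
    disability_weight_history = cfg$daly$disability_weight_history,
    acute_duration = cfg$daly$acute_duration %||% 1
  )
}

#' Read a run configuration from a YAML or JSON file
#'
#' The dialect is chosen by file extension (`.yaml`/`.yml` vs `.json`).
#' Omitted fields take the documented defaults (e.g. a missing
#' `discount_rate` becomes 0.035).
#'
#' @param path Path to the configuration file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort(paste0("unsupported config extension '", ext, "' (use yaml or json)"))
  }
  run_config_from_list(raw)
}

run_config_from_list <- function(raw) {
  costs <- do.call(cost_set, raw$costs %||% list())
  daly <- if (is.null(raw$daly)) NULL else {
    daly_parameters(
      disability_weight_acute = raw$daly$disability_weight_acute,
      disability_weight_history = raw$daly$disability_weight_history,
      acute_duration = raw$daly$acute_duration %||% 1,
      discount_effects = raw$daly$discount_effects %||% TRUE
    )
  }
  risk_args <- raw$risk %||% list()
  scenario <- raw$scenario %||% "base"
  if (is.list(scenario)) {
    scenario <- scenario_spec(name = scenario$name %||% "custom",
                              initial_intake = scenario$initial_intake)
  }
  run_config(
    horizon_years = raw$horizon_years %||% 85,
    discount_rate = raw$discount_rate %||% 0.035,
    scenario = scenario,
    options = raw$options %||% POLICY_OPTION_IDS,
    gdp_per_capita = raw$gdp_per_capita %||% 23300,
    costs = costs,
    daly = daly,
    risk = do.call(risk_parameters, risk_args),
    decay_shape = raw$decay_shape %||% "linear",
    psa = raw$psa %||% list()
  )
}

validate_prob_column <- function(df, col, file) {
  v <- df[[col]]
  bad <- which(!is.finite(v) | v < 0 | v > 1)
  if (length(bad)) {
    i <- bad[1]
    abort(sprintf(
      "%s: row %d (age %s, sex %s), field '%s' = %s is not a probability in [0, 1]",
      file, i, df$age[i], df$sex[i], col, format(v[i])
    ))
  }
  invisible(df)
}

validate_grid <- function(df, file, reference = NULL, required = character()) {
  need <- c("age", "sex", required)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing column(s) %s", file,
                  paste(missing_cols, collapse = ", ")))
  }
  if (!all(df$sex %in% SEXES)) {
    abort(sprintf("%s: field 'sex' must be one of %s", file,
                  paste(SEXES, collapse = ", ")))
  }
  key <- df %>% select("age", "sex") %>% arrange(.data$sex, .data$age)
  full <- sex_grid(max(df$age))
  if (!identical(dim(key), dim(full)) || !all(key$age == full$age & key$sex == full$sex)) {
    abort(sprintf("%s: age-sex grid is not a complete 0..max_age x {F, M} grid",
                  file))
  }
  if (!is.null(reference)) {
    if (max(df$age) != max(reference$age)) {
      abort(sprintf("%s: age-sex grid does not match the life table grid", file))
    }
  }
  invisible(df)
}

#' Read and validate the full model input set
#'
#' Loads the life table, morbidity table and population pyramid CSVs plus an
#' optional run-configuration file into a validated in-memory model.
#' Validation errors name the offending file, row and field.
#'
#' @param dir Directory holding `life_table.csv`, `morbidity.csv`,
#'   `population.csv` (individual paths can override).
#' @param life_table,morbidity,population Explicit file paths.
#' @param run_config_path Optional path to a YAML/JSON run configuration;
#'   omitted fields take the documented defaults.
#' @return An object of class `tfa_inputs`: a list with tibbles `life_table`,
#'   `morbidity`, `population` and a `run_config`.
#' @export
read_inputs <- function(dir = NULL,
                        life_table = file.path(dir, "life_table.csv"),
                        morbidity = file.path(dir, "morbidity.csv"),
                        population = file.path(dir, "population.csv"),
                        run_config_path = NULL) {
  for (p in c(life_table, morbidity, population)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  # base-R read.csv parses doubles with correctly-rounded strtod, so a
  # write -> read round trip of the shortest-round-trip CSV representation
  # is bit-exact
  read_table <- function(path) {
    as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  lt <- read_table(life_table)
  mb <- read_table(morbidity)
  pp <- read_table(population)
  validate_grid(lt, life_table, required = "q_all_cause")
  validate_prob_column(lt, "q_all_cause", life_table)
  validate_grid(mb, morbidity, reference = lt,
                required = c("p_cad_first", "case_fatality"))
  validate_prob_column(mb, "p_cad_first", morbidity)
  validate_prob_column(mb, "case_fatality", morbidity)
  validate_grid(pp, population, reference = lt, required = "count")
  pp$count <- as.numeric(pp$count)
  bad <- which(!is.finite(pp$count) | pp$count < 0)
  if (length(bad)) {
    i <- bad[1]
    abort(sprintf("%s: row %d (age %s, sex %s), field 'count' = %s must be a non-negative number",
                  population, i, pp$age[i], pp$sex[i], format(pp$count[i])))
  }
  cfg <- if (is.null(run_config_path)) run_config() else read_run_config(run_config_path)
  new_inputs(lt, mb, pp, cfg)
}

new_inputs <- function(life_table, morbidity, population, cfg = run_config()) {
  structure(list(
    life_table = as_tibble(life_table) %>% arrange(.data$sex, .data$age),
    morbidity = as_tibble(morbidity) %>% arrange(.data$sex, .data$age),
    population = as_tibble(population) %>% arrange(.data$sex, .data$age),
    run_config = cfg
  ), class = "tfa_inputs")
}

#' Bundle in-memory tables into a validated input set
#'
#' @param life_table,morbidity,population Tibbles as produced by the
#'   synthetic-data generators (or read from CSV).
#' @param run_config A [run_config()].
#' @return A `tfa_inputs` object.
#' @export
as_inputs <- function(life_table, morbidity, population,
                      run_config = tfacea::run_config()) {
  new_inputs(life_table, morbidity, population, run_config)
}

#' Write analysis outputs to a directory
#'
#' Writes `results_by_option.csv`, `incremental.csv` and, when a PSA result is
#' supplied, `psa_draws.csv`, `ce_plane.csv` and `summary.json`. Numbers are
#' serialized at full double precision so a write/read round trip is
#' bit-faithful.
#'
#' @param results A `tfa_analysis` object from [run_deterministic()], or a
#'   list with elements `by_option` and `incremental` (tibbles), and
#'   optionally `psa` (a `tfa_psa`).
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    written <<- c(written, path)
  }
  by_option <- results$by_option %||%
    tibble(option = character(), total_cost = double(), dalys = double())
  wr(by_option, "results_by_option.csv")
  incremental <- results$incremental %||%
    tibble(option = character(), delta_cost = double(), delta_dalys = double(),
           icer = double(), status = character(), ce_class = character())
  wr(incremental, "incremental.csv")
  if (!is.null(results$psa)) {
    wr(results$psa$draws, "psa_draws.csv")
    wr(ce_plane(results$psa), "ce_plane.csv")
    path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(psa_summary_list(results$psa), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, path)
  }
  invisible(written)
}
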