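# Shared builders for small, fully hand-controlled model inputs.

# A complete age-sex grid with constant (or age-varying) probabilities.
toy_tables <- function(max_age = 5, q = 0.02, p0 = 0.05, cf = 0.3) {
  grid <- tidyr::expand_grid(sex = c("F", "M"), age = 0:max_age) |>
    dplyr::select(age, sex) |>
    dplyr::arrange(sex, age)
  qv <- rep_len(q, max_age + 1)
  life <- grid |> dplyr::mutate(q_all_cause = rep(qv, 2))
  life$q_all_cause[life$age == max_age] <- 1
  morb <- grid |> dplyr::mutate(p_cad_first = rep_len(p0, dplyr::n()),
                                case_fatality = rep_len(cf, dplyr::n()))
  pop <- grid |> dplyr::mutate(count = 0)
  list(life = life, morb = morb, pop = pop, grid = grid)
}

# Inputs with people placed at given ages (same count in both sexes).
toy_inputs <- function(max_age = 5, q = 0.02, p0 = 0.05, cf = 0.3,
                       ages = 0, count = 1000, cfg = NULL) {
  tt <- toy_tables(max_age, q, p0, cf)
  tt$pop$count[tt$pop$age %in% ages] <- count
  cfg <- cfg %||% run_config(horizon_years = 10,
                             daly = daly_parameters(0.4, 0.08))
  as_inputs(tt$life, tt$morb, tt$pop, cfg)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

default_inputs_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tabs <- generate_inputs(synthetic_config(seed = 1))
      cache <<- as_inputs(tabs$life_table, tabs$morbidity, tabs$population)
    }
    cache
  }
})
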