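#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a policy-option run
#'
#' One row per model year of the event ledger, with discounted cost and DALY
#' components.
#'
#' @param x A `tfa_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tfa_run <- function(x, ...) {
  x$ledger %>% mutate(option = x$option, scenario = x$scenario,
                      .before = "year")
}

#' @rdname tidy.tfa_run
#' @export
glance.tfa_run <- function(x, ...) {
  glance_run(x)
}

#' Tidy a deterministic analysis
#'
#' @param x A `tfa_analysis`.
#' @param ... Unused.
#' @return The per-option summary tibble (`tidy`) or a one-row overview
#'   (`glance`).
#' @export
tidy.tfa_analysis <- function(x, ...) {
  x$by_option
}

#' @rdname tidy.tfa_analysis
#' @export
glance.tfa_analysis <- function(x, ...) {
  ref <- x$runs[["reference"]]
  tibble(
    scenario = x$run_config$scenario$name,
    n_options = length(x$runs),
    horizon_years = x$run_config$horizon_years,
    discount_rate = x$run_config$discount_rate,
    reference_cost = if (is.null(ref)) NA_real_ else ref$total_cost,
    reference_dalys = if (is.null(ref)) NA_real_ else ref$dalys
  )
}

#' Tidy a probabilistic sensitivity analysis
#'
#' `tidy()` returns the per-draw results; `glance()` the per-option summary
#' with dominance probabilities.
#'
#' @param x A `tfa_psa`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tfa_psa <- function(x, ...) {
  x$draws
}

#' @rdname tidy.tfa_psa
#' @export
glance.tfa_psa <- function(x, ...) {
  x$summary %>% mutate(n_draws = x$n_draws, scenario = x$scenario)
}
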