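#' Incremental cost-effectiveness ratio from raw deltas
#'
#' `delta_cost / delta_dalys`, with the sign convention of the published
#' tables: a negative ICER is printed when DALYs are averted
#' (`delta_dalys < 0`) at positive incremental cost. `NA` when
#' `delta_dalys = 0`.
#'
#' @param delta_cost Incremental cost (option minus reference), euros.
#' @param delta_dalys Incremental DALYs (option minus reference); negative
#'   means health gain.
#' @return The ICER in euros per DALY (vectorised).
#' @export
icer <- function(delta_cost, delta_dalys) {
  ifelse(delta_dalys == 0, NA_real_, delta_cost / delta_dalys)
}

dominance_status <- function(delta_cost, delta_dalys) {
  dplyr::case_when(
    delta_cost < 0 & delta_dalys < 0 ~ "dominant",
    delta_cost > 0 & delta_dalys > 0 ~ "dominated",
    delta_dalys == 0 & delta_cost < 0 ~ "dominant",
    delta_dalys == 0 & delta_cost > 0 ~ "dominated",
    TRUE ~ "icer"
  )
}

#' Incremental analysis of one option against the reference
#'
#' Computes cost and DALY differences, dominance status and the ICER. An
#' option is *dominant* when it saves both costs and DALYs, and *dominated*
#' when it costs more and produces more DALYs. When `delta_dalys = 0` at
#' non-zero cost the ICER is undefined and the class follows the cost sign.
#'
#' @param option_result,reference_result `tfa_run` objects from the same
#'   inputs and configuration (or any lists with `total_cost`, `dalys` and
#'   `option` fields).
#' @param gdp_per_capita Threshold for [classify_ce()]; `NULL` skips
#'   classification.
#' @return A one-row tibble of class `tfa_incremental`: `option`,
#'   `delta_cost`, `delta_dalys`, `icer`, `status`, and `ce_class` when a
#'   threshold is supplied.
#' @export
incremental <- function(option_result, reference_result,
                        gdp_per_capita = 23300) {
  dc <- option_result$total_cost - reference_result$total_cost
  dd <- option_result$dalys - reference_result$dalys
  status <- dominance_status(dc, dd)
  out <- tibble(
    option = option_result$option %||% "option",
    delta_cost = dc,
    delta_dalys = dd,
    icer = ifelse(status == "icer", icer(dc, dd), NA_real_),
    status = status
  )
  if (!is.null(gdp_per_capita)) {
    out$ce_class <- classify_ce(out$icer, out$status, gdp_per_capita)
  }
  structure(out, class = c("tfa_incremental", class(out)))
}

#' Incremental table for a set of runs
#'
#' @param runs Named list of `tfa_run` objects including the reference.
#' @param reference Name of the reference option.
#' @param gdp_per_capita GDP-per-capita threshold in euros.
#' @return A tibble with one row per non-reference option.
#' @export
incremental_table <- function(runs, reference = "reference",
                              gdp_per_capita = 23300) {
  ref <- runs[[reference]]
  if (is.null(ref)) abort(paste0("reference option '", reference,
                                 "' not among the runs"))
  others <- runs[setdiff(names(runs), reference)]
  purrr::map_dfr(others, incremental, reference_result = ref,
                 gdp_per_capita = gdp_per_capita)
}

#' WHO GDP-threshold cost-effectiveness classification
#'
#' Classifies an incremental result by the magnitude of its ICER against the
#' GDP-per-capita threshold: below 1 GDP per DALY averted is *highly
#' cost-effective*, below 3 GDP *cost-effective* (both bounds strict),
#' otherwise *not cost-effective*. Dominant and dominated results pass
#' through unchanged. For the EU the threshold is 23,300 euros (3x = 69,900).
#'
#' @param icer ICER values (euros per DALY; sign ignored).
#' @param status Dominance status (`"dominant"`, `"dominated"`, `"icer"`),
#'   recycled as needed.
#' @param gdp_per_capita GDP per capita in euros.
#' @return Character vector with levels `dominant`, `highly_cost_effective`,
#'   `cost_effective`, `not_cost_effective`, `dominated`.
#' @export
classify_ce <- function(icer, status = "icer", gdp_per_capita = 23300) {
  if (gdp_per_capita <= 0) abort("gdp_per_capita must be positive")
  n <- max(length(icer), length(status))
  icer <- rep_len(icer, n)
  status <- rep_len(status, n)
  mag <- abs(icer)
  dplyr::case_when(
    status == "dominant" ~ "dominant",
    status == "dominated" ~ "dominated",
    is.na(mag) ~ NA_character_,
    mag < gdp_per_capita ~ "highly_cost_effective",
    mag < 3 * gdp_per_capita ~ "cost_effective",
    TRUE ~ "not_cost_effective"
  )
}
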