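#' Cost-effectiveness plane of a PSA
#'
#' Scatter of DALYs avoided against costs saved relative to the reference
#' option, one point per draw and option.
#'
#' @param object A `tfa_psa`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfa_psa <- function(object, ...) {
  pts <- ce_plane(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$dalys_avoided / 1e6,
                                    y = .data$costs_saved / 1e6,
                                    colour = .data$option)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "DALYs avoided (millions)",
                  y = "Costs saved (million EUR)",
                  colour = "Policy option",
                  title = "Cost-effectiveness plane vs no EU-level action") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Intake trajectories of the four policy options
#'
#' @param scenario A [scenario_spec()] or preset name.
#' @param horizon Years to show (default 12, covering all phase-outs).
#' @param shape Decay shape passed to [build_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(scenario = "base", horizon = 12,
                              shape = "linear") {
  df <- purrr::map_dfr(POLICY_OPTION_IDS, function(id) {
    tr <- build_trajectory(id, scenario, horizon = horizon, shape = shape)
    tibble(option = id, year = tr$year, intake_e_pct = tr$intake_e_pct)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$intake_e_pct,
                                   colour = .data$option)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Model year", y = "iTFA intake (E%)",
                  colour = "Policy option") +
    ggplot2::theme_minimal()
}

#' Per-year cost breakdown of a run
#'
#' @param run A `tfa_run`.
#' @return A ggplot object (stacked discounted cost components by year).
#' @export
plot_cost_breakdown <- function(run) {
  df <- run$ledger %>%
    select("year", "cost_acute", "cost_chronic", "cost_mortality",
           "cost_measures") %>%
    tidyr::pivot_longer(-"year", names_to = "component", values_to = "cost",
                        names_prefix = "cost_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$cost / 1e6,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Model year", y = "Discounted cost (million EUR)",
                  fill = "Component",
                  title = paste("Cost breakdown:", run$option)) +
    ggplot2::theme_minimal()
}
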