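#' Build a parametric distribution for the PSA
#'
#' Gamma for quantities constrained to be zero or positive (parameterised by
#' moment matching: `shape = (mean/se)^2`, `scale = se^2/mean`), lognormal
#' for relative-risk-type quantities (from a 95% CI: `sigma = (log(upper) -
#' log(lower)) / (2 * 1.96)`, `mu = log(mean)`; from an SE:
#' mean-preserving `sigma^2 = log(1 + cv^2)`), or a point mass.
#'
#' @param mean Central value.
#' @param se Standard error (alternative to `ci`).
#' @param ci Length-2 95% confidence interval (alternative to `se`).
#' @param family `"gamma"`, `"lognormal"` or `"point"`.
#' @return An object of class `tfa_distribution`.
#' @examples
#' build_distribution(1.23, ci = c(1.11, 1.37), family = "lognormal")
#' build_distribution(3557.46, se = 711.492, family = "gamma")
#' @export
build_distribution <- function(mean, se = NULL, ci = NULL,
                               family = c("gamma", "lognormal", "point")) {
  family <- match.arg(family)
  if (!is.null(ci)) {
    if (length(ci) != 2 || ci[1] > mean || ci[2] < mean) {
      abort("ci must be a length-2 interval bracketing the mean")
    }
  }
  if (family == "gamma" && mean < 0) {
    abort("gamma distributions are only for non-negative quantities")
  }
  if (family == "lognormal" && mean <= 0) {
    abort("lognormal distributions are only for positive quantities")
  }
  pars <- switch(
    family,
    point = list(),
    gamma = {
      if (is.null(se)) abort("gamma requires an se")
      if (se == 0 || mean == 0) list(point = TRUE) else {
        list(shape = (mean / se)^2, scale = se^2 / mean)
      }
    },
    lognormal = {
      if (!is.null(ci)) {
        sigma <- (log(ci[2]) - log(ci[1])) / (2 * qnorm(0.975))
        list(mu = log(mean), sigma = sigma)
      } else if (!is.null(se)) {
        if (se == 0) list(point = TRUE) else {
          s2 <- log(1 + (se / mean)^2)
          list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
        }
      } else {
        abort("lognormal requires an se or a ci")
      }
    }
  )
  structure(list(family = family, mean = mean, pars = pars),
            class = "tfa_distribution")
}

#' Draw from a PSA distribution
#'
#' @param dist A [build_distribution()] result.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_distribution <- function(dist, n = 1) {
  stopifnot(inherits(dist, "tfa_distribution"))
  if (dist$family == "point" || isTRUE(dist$pars$point)) {
    return(rep(dist$mean, n))
  }
  switch(dist$family,
         gamma = rgamma(n, shape = dist$pars$shape, scale = dist$pars$scale),
         lognormal = rlnorm(n, meanlog = dist$pars$mu,
                            sdlog = dist$pars$sigma))
}

#' Distribution set for every uncertain model parameter
#'
#' Builds the PSA distributions: lognormal for the CAD relative risk (from
#' its 95% CI) and the two assumption RRs (repeat event and repeat-event
#' death, SE a configurable fraction of the mean, default 20%), gamma for
#' all thirteen cost items (same SE fraction), and lognormal multipliers
#' (mean 1, configurable CV) applied per draw to the life table, the CAD
#' probability column and the case-fatality column.
#'
#' @param cfg A [run_config()].
#' @param point If `TRUE`, every distribution degenerates to its mean
#'   (useful for checking equivalence with the deterministic analysis).
#' @return Named list of `tfa_distribution` objects.
#' @export
psa_distributions <- function(cfg, point = FALSE) {
  sef <- cfg$psa$cost_se_frac
  tcv <- cfg$psa$table_cv
  risk <- cfg$risk
  d <- list(
    rr_per_2epct = build_distribution(risk$rr_per_2epct, ci = risk$rr_ci,
                                      family = "lognormal"),
    rr_repeat_event = build_distribution(risk$rr_repeat_event,
                                         se = sef * risk$rr_repeat_event,
                                         family = "lognormal"),
    rr_death_second_event = build_distribution(
      risk$rr_death_second_event, se = sef * risk$rr_death_second_event,
      family = "lognormal"),
    mult_life_table = build_distribution(1, se = tcv, family = "lognormal"),
    mult_cad_probability = build_distribution(1, se = tcv,
                                              family = "lognormal"),
    mult_case_fatality = build_distribution(1, se = tcv,
                                            family = "lognormal")
  )
  for (nm in names(unclass(cfg$costs))) {
    d[[paste0("cost_", nm)]] <- build_distribution(cfg$costs[[nm]],
                                                   se = sef * cfg$costs[[nm]],
                                                   family = "gamma")
  }
  if (point) d <- lapply(d, function(x) { x$family <- "point"; x })
  d
}

draw_parameter_set <- function(dists) {
  lapply(dists, draw_distribution, n = 1)
}

#' Probabilistic sensitivity analysis
#'
#' Repeats the full model under random parameter draws: each draw samples
#' every uncertain parameter independently from its distribution, reruns all
#' configured policy options with the sampled parameter set, and records
#' discounted costs and DALYs plus their differences against the reference
#' option (common draws across options). Draws yielding invalid inputs are
#' resampled and counted. Summaries report per-option means, the probability
#' of saving costs, of saving DALYs, and of joint dominance, mirroring the
#' published probability table.
#'
#' @param inputs A `tfa_inputs` object.
#' @param run_config Optional [run_config()] override.
#' @param n_draws Number of draws (default from the config, 1000).
#' @param seed RNG seed (default from the config).
#' @param distributions Optional distribution set from
#'   [psa_distributions()].
#' @return An object of class `tfa_psa`: list with `draws` (tibble: `draw`,
#'   `option`, `cost`, `dalys`, `delta_cost`, `delta_dalys`), `summary`
#'   (per-option tibble), `n_draws`, `n_resampled`, `seed`.
#' @export
run_psa <- function(inputs, run_config = NULL, n_draws = NULL, seed = NULL,
                    distributions = NULL) {
  stopifnot(inherits(inputs, "tfa_inputs"))
  cfg <- run_config %||% inputs$run_config
  n_draws <- n_draws %||% cfg$psa$n_draws
  seed <- seed %||% cfg$psa$seed
  dists <- distributions %||% psa_distributions(cfg)
  options <- cfg$options
  if (!"reference" %in% options) {
    abort("the PSA requires the reference option among cfg$options")
  }
  opts <- policy_options(options)
  H <- cfg$horizon_years
  # Trajectories are policy assumptions, not uncertain parameters: fixed
  # across draws.
  traj <- lapply(opts, function(o) {
    build_trajectory(o, cfg$scenario, horizon = H,
                     shape = cfg$decay_shape)$intake_e_pct
  })
  base_par <- lapply(opts, function(o) {
    core_pars(inputs, o, cfg, traj_intake = traj[[o$id]])
  })
  q0 <- base_par[[1]]$q
  p00 <- base_par[[1]]$p0
  cf0 <- base_par[[1]]$cf
  top_age <- base_par[[1]]$n_age - 1
  is_top <- base_par[[1]]$ages == top_age

  rows <- vector("list", n_draws)
  n_resampled <- 0L
  with_seed(seed, {
    for (i in seq_len(n_draws)) {
      repeat {
        ps <- draw_parameter_set(dists)
        res <- tryCatch(
          psa_one_draw(ps, base_par, opts, traj, cfg, q0, p00, cf0, is_top),
          error = function(e) NULL
        )
        if (!is.null(res)) break
        n_resampled <- n_resampled + 1L
        if (n_resampled > 100 * n_draws) {
          abort("PSA resampling limit exceeded; check the distributions")
        }
      }
      res$draw <- i
      rows[[i]] <- res
    }
  })
  draws <- bind_rows(rows) %>% select("draw", dplyr::everything())
  ref <- draws %>%
    filter(.data$option == "reference") %>%
    select("draw", ref_cost = "cost", ref_dalys = "dalys")
  draws <- draws %>%
    left_join(ref, by = "draw") %>%
    mutate(delta_cost = .data$cost - .data$ref_cost,
           delta_dalys = .data$dalys - .data$ref_dalys) %>%
    select(-"ref_cost", -"ref_dalys")
  structure(list(
    draws = draws,
    summary = summarise_psa(draws, cfg$gdp_per_capita),
    n_draws = n_draws,
    n_resampled = n_resampled,
    seed = seed,
    scenario = cfg$scenario$name
  ), class = "tfa_psa")
}

psa_one_draw <- function(ps, base_par, opts, traj, cfg, q0, p00, cf0,
                         is_top) {
  q <- pmin(1, q0 * ps$mult_life_table)
  q[is_top] <- 1  # the top age stays absorbing under any draw
  p0 <- pmin(1, p00 * ps$mult_cad_probability)
  cf <- pmin(1, cf0 * ps$mult_case_fatality)
  costs <- cost_set(
    production_loss_mortality = ps$cost_production_loss_mortality,
    production_loss_morbidity = ps$cost_production_loss_morbidity,
    informal_care = ps$cost_informal_care,
    primary_care = ps$cost_primary_care,
    outpatient = ps$cost_outpatient,
    emergency = ps$cost_emergency,
    inpatient = ps$cost_inpatient,
    medication = ps$cost_medication,
    school = ps$cost_school,
    worksite = ps$cost_worksite,
    mass_media = ps$cost_mass_media,
    physician_counseling = ps$cost_physician_counseling,
    food_inspection = ps$cost_food_inspection
  )
  risk <- risk_parameters(
    rr_per_2epct = ps$rr_per_2epct,
    rr_repeat_event = ps$rr_repeat_event,
    rr_death_second_event = ps$rr_death_second_event
  )
  if (any(!is.finite(c(q, p0, cf)))) abort("invalid draw")
  purrr::map_dfr(opts, function(o) {
    par <- base_par[[o$id]]
    par$q <- q; par$p0 <- p0; par$cf <- cf
    par$risk <- risk
    par$costs <- costs
    e <- traj[[o$id]]
    par$rrf <- rr_for_intake_change(e - e[1],
                                    risk$rr_per_2epct)[seq_len(cfg$horizon_years)]
    par$measure_pc <- measure_per_capita(o, costs, cfg$horizon_years)
    res <- core_run(par, check = FALSE)
    tibble(option = o$id, cost = res$totals$total_cost,
           dalys = res$totals$dalys)
  })
}

summarise_psa <- function(draws, gdp_per_capita) {
  draws %>%
    filter(.data$option != "reference") %>%
    group_by(.data$option) %>%
    summarise(
      mean_cost = mean(.data$cost),
      mean_dalys = mean(.data$dalys),
      mean_delta_cost = mean(.data$delta_cost),
      mean_delta_dalys = mean(.data$delta_dalys),
      p_save_costs = mean(.data$delta_cost < 0),
      p_save_dalys = mean(.data$delta_dalys < 0),
      p_dominant = mean(.data$delta_cost < 0 & .data$delta_dalys < 0),
      .groups = "drop"
    ) %>%
    mutate(
      status = dominance_status(.data$mean_delta_cost, .data$mean_delta_dalys),
      icer = ifelse(.data$status == "icer",
                    icer(.data$mean_delta_cost, .data$mean_delta_dalys),
                    NA_real_),
      ce_class = classify_ce(.data$icer, .data$status, gdp_per_capita)
    )
}

#' Cost-effectiveness plane points
#'
#' One point per (draw, non-reference option): DALYs avoided against costs
#' saved relative to the reference, the axes of the published plane.
#'
#' @param psa A `tfa_psa` object.
#' @param path Optional CSV path to write.
#' @return A tibble `draw`, `option`, `dalys_avoided`, `costs_saved`.
#' @export
ce_plane <- function(psa, path = NULL) {
  out <- psa$draws %>%
    filter(.data$option != "reference") %>%
    mutate(dalys_avoided = -.data$delta_dalys,
           costs_saved = -.data$delta_cost) %>%
    select("draw", "option", "dalys_avoided", "costs_saved")
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

psa_summary_list <- function(psa) {
  list(
    n_draws = psa$n_draws,
    n_resampled = psa$n_resampled,
    seed = psa$seed,
    scenario = psa$scenario,
    options = purrr::transpose(psa$summary)
  )
}

#' @export
print.tfa_psa <- function(x, ...) {
  cat("<tfa_psa>", x$n_draws, "draws, scenario", x$scenario,
      "(resampled:", x$n_resampled, ")\n")
  print(x$summary)
  invisible(x)
}
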