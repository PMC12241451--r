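#' Monthly population totals of one season
#'
#' @param result A [simulate_population()] result.
#' @param j Season index.
#' @return Numeric vector of the six monthly totals `N(i, j)` (juveniles
#'   plus adults; eggs excluded).
#' @export
season_totals <- function(result, j) {
  tr <- result$trajectory
  if (length(j) != 1L || is.na(j) || !j %in% tr$season) {
    stop(sprintf("season %s is not present in the simulation result",
                 format(j)), call. = FALSE)
  }
  tr$N_total[tr$season == j]
}

#' Mean population size of one season
#'
#' Arithmetic mean of the six monthly totals of season `j`.
#'
#' @inheritParams season_totals
#' @return A single abundance.
#' @export
season_mean <- function(result, j) {
  mean(season_totals(result, j))
}

#' Seasonal population growth rate (percent)
#'
#' Percent change between the mean population size of the first and last
#' modelled seasons: `(N_last_mean - N_first_mean) / N_first_mean * 100`.
#' Despite being a "growth rate", it is a total change over the whole run,
#' not annualised.
#'
#' @inheritParams season_totals
#' @param j_first,j_last Season indices to compare; `j_last = NULL` uses
#'   the final season.
#' @return Percent change, or `NA` (with a warning) when the first-season
#'   mean is zero.
#' @export
lambda_growth <- function(result, j_first = 1, j_last = NULL) {
  if (is.null(j_last)) j_last <- max(result$trajectory$season)
  n_first <- season_mean(result, j_first)
  n_last <- season_mean(result, j_last)
  if (n_first == 0) {
    warning("growth rate undefined: first-season mean population size is 0",
            call. = FALSE)
    return(NA_real_)
  }
  (n_last - n_first) / n_first * 100
}

#' Time to quasi-extinction
#'
#' The deterministic model never reaches exactly zero from a positive state
#' with positive survivals, so extinction is declared at the first monthly
#' step whose total abundance falls below `threshold` (one individual by
#' default) and stays below it for the remainder of the run. Steps count
#' active months only: six per season, so step 120 closes season 20.
#'
#' @inheritParams season_totals
#' @param threshold Quasi-extinction threshold in individuals (default 1).
#' @return The extinction step (integer) or `NA` if the population never
#'   goes quasi-extinct within the run.
#' @export
time_to_extinction <- function(result, threshold = 1.0) {
  tot <- result$trajectory$N_total
  below <- tot < threshold
  if (!any(below)) return(NA_integer_)
  # first step from which every later total is also below threshold
  sustained <- rev(cumprod(rev(below))) > 0
  if (!any(sustained)) return(NA_integer_)
  result$trajectory$step[which(sustained)[1]]
}

#' Run one snow-loss scenario
#'
#' Simulates `n_seasons` seasons with the scenario's adjusted winter
#' survival (the spec's `d_w` overrides the parameter set's) and computes
#' the summary statistics used to compare scenarios: mean, standard
#' deviation, minimum and maximum of the six monthly totals of the last
#' season, the time to quasi-extinction, and the seasonal growth rate
#' between the first and last seasons.
#'
#' @param spec A [scenario_spec()].
#' @param params A [model_parameters()] object; its `d_w` is replaced by
#'   the scenario's adjusted value.
#' @param init An [initial_state()].
#' @param n_seasons Number of seasons (default 20).
#' @param threshold Quasi-extinction threshold (default 1 individual).
#' @param mode Maturation bookkeeping passed to [simulate_population()].
#' @return An object of class `"scenario_summary"`: a list with `scenario`,
#'   `d_w`, `mortality`, `t_min`, `mean_final`, `sd_final`, `min_final`,
#'   `max_final`, `time_to_extinction`, `lambda_pct`, `n_seasons`, and the
#'   full `result`. The standard deviation is the sample SD (n - 1) of the
#'   six last-season totals.
#' @export
#' @examples
#' sc <- build_paper_scenarios()
#' run_scenario(sc[["3"]], default_parameters(), default_initial_state())
run_scenario <- function(spec, params, init, n_seasons = 20,
                         threshold = 1.0,
                         mode = c("literal", "corrected")) {
  if (!inherits(spec, "scenario_spec")) {
    stop("`spec` must be a 'scenario_spec' object", call. = FALSE)
  }
  mode <- match.arg(mode)
  params$d_w <- spec$d_w
  validate_parameters(params)
  result <- simulate_population(init, params, n_seasons = n_seasons,
                                mode = mode)
  finals <- season_totals(result, n_seasons)
  lam <- if (season_mean(result, 1) > 0) {
    lambda_growth(result, 1, n_seasons)
  } else {
    NA_real_
  }
  structure(list(
    scenario = spec$name, d_w = spec$d_w, mortality = spec$mortality,
    t_min = spec$t_min,
    mean_final = mean(finals),
    sd_final = stats::sd(finals),
    min_final = min(finals),
    max_final = max(finals),
    time_to_extinction = time_to_extinction(result, threshold),
    lambda_pct = lam,
    n_seasons = n_seasons,
    result = result
  ), class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  tte <- if (is.na(x$time_to_extinction)) "none" else
    sprintf("%d months", x$time_to_extinction)
  cat(sprintf("Scenario '%s' (d_w = %g, %d seasons):\n",
              x$scenario, x$d_w, x$n_seasons))
  cat(sprintf("  final season: mean = %.4g, sd = %.4g, min = %.4g, max = %.4g\n",
              x$mean_final, x$sd_final, x$min_final, x$max_final))
  cat(sprintf("  time to extinction: %s; growth rate = %s\n", tte,
              if (is.na(x$lambda_pct)) "undefined" else
                sprintf("%.3g%%", x$lambda_pct)))
  invisible(x)
}

#' Run the five canonical scenarios and tabulate them
#'
#' Convenience wrapper: runs [build_paper_scenarios()] under a common
#' parameter set and returns one summary row per scenario.
#'
#' @inheritParams run_scenario
#' @param scenarios A list of [scenario_spec()]s; defaults to the five
#'   canonical snow-loss scenarios.
#' @return A data frame with columns `scenario`, `t_min`, `mortality`,
#'   `d_w`, `mean_final`, `sd_final`, `min_final`, `max_final`,
#'   `time_to_extinction_months`, `lambda_pct`.
#' @export
run_paper_scenarios <- function(params = default_parameters(),
                                init = default_initial_state(),
                                n_seasons = 20, threshold = 1.0,
                                mode = c("literal", "corrected"),
                                scenarios = build_paper_scenarios()) {
  mode <- match.arg(mode)
  rows <- lapply(scenarios, function(sp) {
    s <- run_scenario(sp, params, init, n_seasons = n_seasons,
                      threshold = threshold, mode = mode)
    data.frame(
      scenario = s$scenario, t_min = s$t_min, mortality = s$mortality,
      d_w = s$d_w, mean_final = s$mean_final, sd_final = s$sd_final,
      min_final = s$min_final, max_final = s$max_final,
      time_to_extinction_months = as.integer(s$time_to_extinction),
      lambda_pct = s$lambda_pct
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-at-a-time sensitivity of a scenario summary statistic
#'
#' Perturbs each scalar demographic parameter by `+-perturbation`
#' (relative), clipping to `[0, 1]` with a warning when needed, re-runs the
#' simulation, and reports the elasticity of the response: the proportional
#' change in the response per proportional change in the parameter,
#' computed by a central difference
#' `((R_hi - R_lo) / R_0) / ((p_hi - p_lo) / p_0)`. A pseudo-parameter
#' `init_scale` perturbs the whole initial state; its elasticity is exactly
#' 1 because the model is linear in the state.
#'
#' @inheritParams run_scenario
#' @param n_seasons Simulation horizon (default 20 seasons).
#' @param perturbation Relative perturbation (default 0.10).
#' @param response Function mapping a `simulation_result` to a single
#'   number; default is the final-season mean total.
#' @param parameters Character vector of scalar parameters to perturb.
#' @return A data frame with columns `parameter`, `value`, `low`, `high`,
#'   `response_low`, `response_high`, `elasticity`.
#' @export
sensitivity_oat <- function(params, init, n_seasons = 20,
                            perturbation = 0.10,
                            response = function(res)
                              season_mean(res, max(res$trajectory$season)),
                            mode = c("literal", "corrected"),
                            parameters = c("d_a1", "d_a2", "d_a3", "d_j",
                                           "d_e", "d_w", "a")) {
  validate_parameters(params)
  mode <- match.arg(mode)
  base_res <- simulate_population(init, params, n_seasons, mode = mode)
  r0 <- response(base_res)

  run_with <- function(p) {
    response(simulate_population(init, p, n_seasons, mode = mode))
  }
  clip01 <- function(v, nm) {
    if (v < 0 || v > 1) {
      warning(sprintf("perturbed '%s' = %g clipped to [0, 1]", nm, v),
              call. = FALSE)
      v <- min(max(v, 0), 1)
    }
    v
  }

  rows <- lapply(parameters, function(nm) {
    p0 <- params[[nm]]
    lo <- clip01(p0 * (1 - perturbation), nm)
    hi <- clip01(p0 * (1 + perturbation), nm)
    p_lo <- params; p_lo[[nm]] <- lo
    p_hi <- params; p_hi[[nm]] <- hi
    r_lo <- run_with(p_lo)
    r_hi <- run_with(p_hi)
    elast <- if (r0 == 0 || p0 == 0 || hi == lo) {
      if (r_hi == r_lo) 0 else NA_real_
    } else {
      ((r_hi - r_lo) / r0) / ((hi - lo) / p0)
    }
    data.frame(parameter = nm, value = p0, low = lo, high = hi,
               response_low = r_lo, response_high = r_hi,
               elasticity = elast)
  })

  # initial-state scale as a pseudo-parameter (elasticity 1 by linearity)
  scale_state <- function(c) {
    initial_state(J = init$J * c, N1 = init$N1 * c, N2 = init$N2 * c,
                  N3 = init$N3 * c)
  }
  r_lo <- response(simulate_population(scale_state(1 - perturbation),
                                       params, n_seasons, mode = mode))
  r_hi <- response(simulate_population(scale_state(1 + perturbation),
                                       params, n_seasons, mode = mode))
  elast <- if (r0 == 0) {
    if (r_hi == r_lo) 0 else NA_real_
  } else {
    ((r_hi - r_lo) / r0) / (2 * perturbation)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    parameter = "init_scale", value = 1, low = 1 - perturbation,
    high = 1 + perturbation, response_low = r_lo, response_high = r_hi,
    elasticity = elast)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
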