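#' Eggs laid in the current month
#'
#' Per-capita laying: adults of age class 1 and 2 (and optionally 3) lay
#' according to their monthly schedules, so the expected egg count is
#' `N1 * e1[i] + N2 * e2[i] + N3 * e3[i]` for active month `i`.
#'
#' @param state A named list with abundances `N1`, `N2`, `N3` and the
#'   active-month index `month` (1 = May ... 6 = October).
#' @param params A [model_parameters()] object.
#' @return Expected number of eggs laid this month (continuous, >= 0).
#' @export
#' @examples
#' p <- default_parameters()
#' lay_eggs(list(N1 = 10, N2 = 0, N3 = 0, month = 1), p)
lay_eggs <- function(state, params) {
  validate_parameters(params)
  i <- check_month(state$month)
  n1 <- state$N1 %||% 0
  n2 <- state$N2 %||% 0
  n3 <- state$N3 %||% 0
  n1 * params$e1[i] + n2 * params$e2[i] + n3 * params$e3[i]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

check_month <- function(i) {
  if (length(i) != 1L || is.na(i) || i != as.integer(i) || i < 1 || i > 6) {
    stop("month index must be an integer in 1..6 (1 = May ... 6 = October)",
         call. = FALSE)
  }
  as.integer(i)
}

season_row <- function(history, i) {
  r <- which(history$month == i)
  if (length(r) != 1L) {
    stop(sprintf("history is missing the state for month %d of the current season", i),
         call. = FALSE)
  }
  history[r, , drop = FALSE]
}

#' Juveniles present in month i
#'
#' Hatching and juvenile survival within a season. No juveniles are present
#' in month 1 (overwintered juveniles have matured). In month 2 the only
#' juveniles are the hatchlings of month-1 eggs. From month 5 onward the
#' cohort hatched three months earlier reaches maturity (the mean time to
#' maturity is about 99 days) and leaves the juvenile pool:
#'
#' * `"literal"` bookkeeping removes `(1 - a) * J(i-3) * d_j`, exactly as
#'   the update rules are printed; combined with the adult gain
#'   `a * J(i-3) * d_j` the whole lagged cohort term exits the pool.
#' * `"corrected"` bookkeeping removes only the maturing fraction
#'   `a * J(i-3) * d_j`, leaving the rest to overwinter as juveniles.
#'
#' A negative intermediate (possible in literal mode under extreme
#' schedules) is clamped to 0 with a warning; [simulate_population()]
#' records such events in its diagnostics instead.
#'
#' @param history A data frame of the current season's states so far, with
#'   columns `month`, `E`, `J` (one row per month already computed).
#' @param params A [model_parameters()] object.
#' @param i Active-month index in 1..6.
#' @param mode `"literal"` (default) or `"corrected"` maturation
#'   bookkeeping.
#' @return Juvenile abundance for month `i` (continuous, >= 0).
#' @export
#' @examples
#' p <- default_parameters()
#' h <- data.frame(month = 1, E = 50, J = 0, N1 = 10, N2 = 0, N3 = 0)
#' update_juveniles(h, p, i = 2)  # 50 * d_e
update_juveniles <- function(history, params, i,
                             mode = c("literal", "corrected")) {
  validate_parameters(params)
  mode <- match.arg(mode)
  i <- check_month(i)
  step <- juvenile_step(history, params, i, mode)
  if (step$clamped) {
    warning(sprintf(
      "negative juvenile count (%.6g) at month %d clamped to 0 (%s mode)",
      step$raw, i, mode), call. = FALSE)
  }
  step$J
}

# Shared juvenile update; returns the clamped value plus the raw
# pre-clamp intermediate so callers can log clamping events.
juvenile_step <- function(history, params, i, mode) {
  if (i == 1L) return(list(J = 0, raw = 0, clamped = FALSE))
  prev <- season_row(history, i - 1L)
  if (i == 2L) {
    j <- prev$E * params$d_e
    return(list(J = j, raw = j, clamped = FALSE))
  }
  j <- prev$J * params$d_j + prev$E * params$d_e
  if (i >= 5L) {
    lag <- season_row(history, i - params$maturation_lag)
    frac <- if (mode == "literal") 1 - params$a else params$a
    j <- j - frac * lag$J * params$d_j
  }
  list(J = max(j, 0), raw = j, clamped = j < 0)
}

#' Adults present in month i (within a season)
#'
#' Monthly adult survival for the three age classes, plus mid-season
#' recruitment into age class 1: in months 5 and 6 the juvenile cohort
#' hatched three months earlier contributes `a * J(i-3) * d_j` newly
#' matured adults. Month 1 states are produced by [overwinter()], not here.
#'
#' @inheritParams update_juveniles
#' @param i Active-month index in 2..6.
#' @return Named numeric vector `c(N1, N2, N3)`.
#' @export
update_adults <- function(history, params, i) {
  validate_parameters(params)
  i <- check_month(i)
  if (i == 1L) {
    stop("month-1 adult abundances come from overwinter(), not update_adults()",
         call. = FALSE)
  }
  prev <- season_row(history, i - 1L)
  n1 <- prev$N1 * params$d_a1
  if (i >= 5L) {
    lag <- season_row(history, i - params$maturation_lag)
    n1 <- n1 + params$a * lag$J * params$d_j
  }
  c(N1 = n1, N2 = prev$N2 * params$d_a2, N3 = prev$N3 * params$d_a3)
}

#' Overwintering transition between seasons
#'
#' The single aggregated winter step (November--April compressed): only
#' juveniles and adults overwinter, each surviving with probability `d_w`.
#' Surviving juveniles mature into age class 1, age-1 adults advance to
#' age 2, age-2 adults to age 3, and age-3 adults are removed (there is no
#' fourth age class). Unhatched eggs are discarded -- egg overwintering
#' does not occur in this species. Month-1 eggs of the new season are laid
#' afresh by the advanced adult classes.
#'
#' @param final_state The month-6 state of the closing season: a named list
#'   with `J`, `N1`, `N2`, `N3` (and `month = 6`).
#' @param params A [model_parameters()] object.
#' @return A named list for month 1 of the next season with fields
#'   `month = 1`, `E`, `J = 0`, `N1`, `N2`, `N3`.
#' @export
#' @examples
#' p <- default_parameters()
#' overwinter(list(month = 6, J = 100, N1 = 50, N2 = 20, N3 = 5), p)
overwinter <- function(final_state, params) {
  validate_parameters(params)
  if (!is.null(final_state$month) && final_state$month != 6L) {
    stop("overwinter() expects the month-6 state of the closing season",
         call. = FALSE)
  }
  nxt <- list(
    month = 1L,
    J = 0,
    N1 = (final_state$J %||% 0) * params$d_w,
    N2 = (final_state$N1 %||% 0) * params$d_w,
    N3 = (final_state$N2 %||% 0) * params$d_w
  )
  nxt$E <- lay_eggs(nxt, params)
  nxt
}

#' Simulate the population over multiple seasons
#'
#' Runs the deterministic model: within each six-month season, months 2..6
#' update juveniles (hatching, survival, maturation of the lagged cohort),
#' adults (survival plus mid-season recruitment) and egg laying; seasons
#' are joined by the [overwinter()] transition. Abundances are expected
#' counts and the whole map is linear in the state.
#'
#' @param init An [initial_state()] object (or a named list with `J`,
#'   `N1`, `N2`, `N3`) for season 1, month 1. Month-1 eggs are computed
#'   from the laying schedules.
#' @param params A [model_parameters()] object.
#' @param n_seasons Number of seasons to simulate (>= 1).
#' @param mode Maturation bookkeeping, `"literal"` (default) or
#'   `"corrected"`; see [update_juveniles()].
#' @return An object of class `"simulation_result"`: a list with
#'   * `trajectory`: data frame with one row per active month and columns
#'     `season`, `month`, `step` (`(season - 1) * 6 + month`), `E`, `J`,
#'     `N1`, `N2`, `N3`, `N_total` (total excludes eggs);
#'   * `parameters`, `mode`;
#'   * `diagnostics`: data frame of clamping events (empty when none),
#'     with columns `season`, `month`, `step`, `value`.
#' @export
#' @examples
#' res <- simulate_population(default_initial_state(), default_parameters(),
#'                            n_seasons = 3)
#' head(res$trajectory)
simulate_population <- function(init, params, n_seasons = 20,
                                mode = c("literal", "corrected")) {
  validate_parameters(params)
  mode <- match.arg(mode)
  if (length(n_seasons) != 1L || is.na(n_seasons) || n_seasons < 1) {
    stop("n_seasons must be >= 1", call. = FALSE)
  }
  n_seasons <- as.integer(n_seasons)
  if (!inherits(init, "initial_state")) {
    init <- initial_state(J = init$J %||% 0, N1 = init$N1 %||% 0,
                          N2 = init$N2 %||% 0, N3 = init$N3 %||% 0)
  }

  n_steps <- 6L * n_seasons
  traj <- data.frame(
    season = rep(seq_len(n_seasons), each = 6L),
    month = rep(1:6, n_seasons),
    step = seq_len(n_steps),
    E = numeric(n_steps), J = numeric(n_steps),
    N1 = numeric(n_steps), N2 = numeric(n_steps), N3 = numeric(n_steps)
  )
  clamp_events <- list()

  state1 <- list(month = 1L, J = init$J, N1 = init$N1, N2 = init$N2,
                 N3 = init$N3)
  state1$E <- lay_eggs(state1, params)

  for (j in seq_len(n_seasons)) {
    if (j > 1L) {
      last <- as.list(traj[traj$step == (j - 1L) * 6L, ])
      state1 <- overwinter(list(month = 6L, J = last$J, N1 = last$N1,
                                N2 = last$N2, N3 = last$N3), params)
    }
    season <- data.frame(month = 1L, E = state1$E, J = state1$J,
                         N1 = state1$N1, N2 = state1$N2, N3 = state1$N3)
    for (i in 2:6) {
      jv <- juvenile_step(season, params, i, mode)
      if (jv$clamped) {
        clamp_events[[length(clamp_events) + 1L]] <- data.frame(
          season = j, month = i, step = (j - 1L) * 6L + i, value = jv$raw)
      }
      ad <- update_adults(season, params, i)
      row <- data.frame(month = i, E = 0, J = jv$J,
                        N1 = ad[["N1"]], N2 = ad[["N2"]], N3 = ad[["N3"]])
      row$E <- lay_eggs(as.list(row), params)
      season <- rbind(season, row)
    }
    idx <- (j - 1L) * 6L + 1:6
    traj[idx, c("E", "J", "N1", "N2", "N3")] <-
      season[, c("E", "J", "N1", "N2", "N3")]
  }

  traj$N_total <- traj$J + traj$N1 + traj$N2 + traj$N3
  diagnostics <- if (length(clamp_events)) {
    do.call(rbind, clamp_events)
  } else {
    data.frame(season = integer(), month = integer(), step = integer(),
               value = numeric())
  }
  if (nrow(diagnostics)) {
    warning(sprintf(
      "%d negative juvenile intermediate(s) clamped to 0; see $diagnostics",
      nrow(diagnostics)), call. = FALSE)
  }
  structure(list(trajectory = traj, parameters = params, mode = mode,
                 diagnostics = diagnostics),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  tr <- x$trajectory
  n_seasons <- max(tr$season)
  cat(sprintf("Deterministic simulation: %d seasons (%d monthly steps), %s bookkeeping\n",
              n_seasons, nrow(tr), x$mode))
  cat(sprintf("  initial total N = %g, final total N = %g\n",
              tr$N_total[1], tr$N_total[nrow(tr)]))
  if (nrow(x$diagnostics)) {
    cat(sprintf("  %d clamping event(s); see $diagnostics\n",
                nrow(x$diagnostics)))
  }
  invisible(x)
}
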