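#' Demographic parameter set for the seasonal snail model
#'
#' Bundles all demographic rates of the five-stage model: monthly adult
#' survival for the three age classes, monthly juvenile survival, the egg
#' hatching ratio, winter survival, the recruitment ratio (fraction of a
#' juvenile cohort maturing within its season of hatching), and per-capita
#' monthly egg-laying schedules for each adult age class over the six active
#' months (May--October).
#'
#' @param d_a1,d_a2,d_a3 Monthly survival probabilities of adults at age
#'   class 1, 2 and 3 (per active month, in `[0, 1]`).
#' @param d_j Monthly juvenile survival probability.
#' @param d_e Egg hatching ratio: the fraction of eggs laid in month
#'   `i - 1` that hatch in month `i`.
#' @param d_w Winter survival probability, applied to juveniles and all
#'   adult classes over the single aggregated overwintering transition.
#' @param a Recruitment ratio: the fraction of a juvenile cohort that
#'   matures within its season of hatching (the rest mature the following
#'   season).
#' @param e1,e2,e3 Numeric vectors of length 6: per-capita eggs laid per
#'   month by adults of age class 1, 2 and 3, indexed by active month
#'   (1 = May ... 6 = October). Age-3 adults do not lay under the default
#'   (`e3 = 0`).
#'
#' @return An object of class `"model_parameters"` (a named list). The
#'   fixed structural constants `months_per_season = 6` and
#'   `maturation_lag = 3` are carried on the object.
#' @seealso [default_parameters()] for the text-derived default set,
#'   [simulate_population()] for running the model.
#' @export
#' @examples
#' p <- model_parameters(
#'   d_a1 = 0.875, d_a2 = 0.875, d_a3 = 0.875,
#'   d_j = 0.85, d_e = 0.8, d_w = 0.7, a = 0.125,
#'   e1 = c(4.75, 4.75, 4.75, 4.75, 0, 0),
#'   e2 = c(4.75, 4.75, 4.75, 4.75, 0, 0)
#' )
#' p
model_parameters <- function(d_a1, d_a2, d_a3, d_j, d_e, d_w, a,
                             e1, e2, e3 = rep(0, 6)) {
  p <- list(
    d_a1 = as.numeric(d_a1), d_a2 = as.numeric(d_a2),
    d_a3 = as.numeric(d_a3), d_j = as.numeric(d_j),
    d_e = as.numeric(d_e), d_w = as.numeric(d_w), a = as.numeric(a),
    e1 = as.numeric(e1), e2 = as.numeric(e2), e3 = as.numeric(e3),
    maturation_lag = 3L, months_per_season = 6L
  )
  class(p) <- "model_parameters"
  validate_parameters(p)
  p
}

#' Validate a model parameter set
#'
#' Checks that every survival/ratio parameter lies in `[0, 1]`, that the
#' three laying schedules have length 6 with non-negative entries, and that
#' no value is missing. Called by [model_parameters()] and before every
#' simulation.
#'
#' @param params An object of class `"model_parameters"`.
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field and the valid range.
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "model_parameters")) {
    stop("`params` must be a 'model_parameters' object; see model_parameters()",
         call. = FALSE)
  }
  probs <- c("d_a1", "d_a2", "d_a3", "d_j", "d_e", "d_w", "a")
  for (nm in probs) {
    v <- params[[nm]]
    if (length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
    }
    if (v < 0 || v > 1) {
      stop(sprintf("parameter '%s' = %g is outside the valid range [0, 1]",
                   nm, v), call. = FALSE)
    }
  }
  for (nm in c("e1", "e2", "e3")) {
    v <- params[[nm]]
    if (length(v) != 6L || anyNA(v)) {
      stop(sprintf("laying schedule '%s' must be a numeric vector of length 6",
                   nm), call. = FALSE)
    }
    if (any(v < 0)) {
      stop(sprintf("laying schedule '%s' must be element-wise >= 0", nm),
           call. = FALSE)
    }
  }
  invisible(params)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Seasonal snail model parameters\n")
  cat(sprintf("  adult survival  d_a1 = %g, d_a2 = %g, d_a3 = %g (per month)\n",
              x$d_a1, x$d_a2, x$d_a3))
  cat(sprintf("  juvenile survival d_j = %g, egg hatching d_e = %g\n",
              x$d_j, x$d_e))
  cat(sprintf("  winter survival  d_w = %g, recruitment ratio a = %g\n",
              x$d_w, x$a))
  cat(sprintf("  laying e1 = (%s), season total %g eggs\n",
              paste(x$e1, collapse = ", "), sum(x$e1)))
  cat(sprintf("  laying e2 = (%s), season total %g eggs\n",
              paste(x$e2, collapse = ", "), sum(x$e2)))
  if (any(x$e3 > 0)) {
    cat(sprintf("  laying e3 = (%s)\n", paste(x$e3, collapse = ", ")))
  }
  invisible(x)
}

#' Population state at the start of a season
#'
#' Abundances of juveniles and the three adult age classes at month 1 (May)
#' of season 1. Abundances are expected counts and may be non-integer; the
#' deterministic model propagates expectations. Eggs at month 1 are always
#' computed from the laying schedules, never supplied.
#'
#' @param J Juveniles. Model-generated month-1 states always have `J = 0`
#'   (all juveniles that survive the winter mature into age class 1), but a
#'   user-supplied season-1 state may start with juveniles present.
#' @param N1,N2,N3 Adults at age class 1 (before first overwintering),
#'   2 (after one) and 3 (after two).
#' @return An object of class `"initial_state"`.
#' @seealso [default_initial_state()]
#' @export
initial_state <- function(J = 0, N1 = 0, N2 = 0, N3 = 0) {
  vals <- c(J = as.numeric(J), N1 = as.numeric(N1),
            N2 = as.numeric(N2), N3 = as.numeric(N3))
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("initial abundances must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("initial abundances must be >= 0", call. = FALSE)
  }
  structure(as.list(vals), class = "initial_state")
}

#' @export
print.initial_state <- function(x, ...) {
  cat(sprintf("Initial state (season 1, month 1): J = %g, N1 = %g, N2 = %g, N3 = %g\n",
              x$J, x$N1, x$N2, x$N3))
  invisible(x)
}

#' Default initial population state
#'
#' 100 individuals in each of the juvenile and three adult classes. The
#' scale is arbitrary: the model is linear in the state, so the seasonal
#' growth rate and the scenario ordering do not depend on it.
#'
#' @return An `"initial_state"` object.
#' @export
default_initial_state <- function() {
  initial_state(J = 100, N1 = 100, N2 = 100, N3 = 100)
}
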