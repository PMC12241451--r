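#' Supercooling-point sample
#'
#' A collection of individual supercooling-point (SCP) measurements in
#' degrees Celsius. The SCP is the body-fluid temperature at which ice
#' crystals begin to form; for a freeze-avoidant snail, reaching it is
#' lethal. All measurements must be negative.
#'
#' @param values Numeric vector of SCP measurements (degC, each < 0).
#' @param stage Optional character vector of per-measurement stage tags
#'   (`"juvenile"` or `"adult"`), same length as `values`.
#' @return An object of class `"scp_sample"`.
#' @seealso [mortality_from_scp()], [synthetic_scp_sample()],
#'   [read_scp_csv()]
#' @export
scp_sample <- function(values, stage = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop("SCP sample must be non-empty with no missing values", call. = FALSE)
  }
  if (any(values >= 0)) {
    stop("all SCP values must be negative (degC below freezing)", call. = FALSE)
  }
  if (!is.null(stage)) {
    stage <- as.character(stage)
    if (length(stage) != length(values)) {
      stop("`stage` must have one tag per measurement", call. = FALSE)
    }
    bad <- setdiff(unique(stage), c("juvenile", "adult"))
    if (length(bad)) {
      stop(sprintf("unknown stage tag(s): %s (use 'juvenile' or 'adult')",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(values = values, stage = stage), class = "scp_sample")
}

#' @export
print.scp_sample <- function(x, ...) {
  v <- x$values
  cat(sprintf("SCP sample: n = %d, mean = %.2f degC, median = %.2f, range [%.2f, %.2f]\n",
              length(v), mean(v), stats::median(v), min(v), max(v)))
  invisible(x)
}

#' @export
summary.scp_sample <- function(object, ...) {
  v <- object$values
  c(n = length(v), mean = mean(v), median = stats::median(v),
    min = min(v), max = max(v))
}

#' Freeze mortality implied by a winter minimum temperature
#'
#' An individual freezes (and dies) when the ambient temperature reaches
#' its supercooling point, so the winter freeze-mortality fraction at a
#' minimum air temperature `t_min` is the fraction of the SCP sample at or
#' above `t_min` (ties count as freezing).
#'
#' @param sample An [scp_sample()].
#' @param t_min Minimum winter air temperature (degC).
#' @return Mortality fraction in `[0, 1]`.
#' @export
#' @examples
#' s <- scp_sample(c(-7, -9, -10, -12, -14))
#' mortality_from_scp(s, -10)  # 3 of 5 at or above -10
mortality_from_scp <- function(sample, t_min) {
  if (!inherits(sample, "scp_sample")) {
    stop("`sample` must be an 'scp_sample' object", call. = FALSE)
  }
  if (length(t_min) != 1L || !is.finite(t_min)) {
    stop("`t_min` must be a single finite temperature in degC", call. = FALSE)
  }
  mean(sample$values >= t_min)
}

#' Winter survival adjusted for freeze mortality
#'
#' Freeze mortality acts on top of the baseline overwintering mortality:
#' the adjusted winter survival is `d_w_base * (1 - mortality)`. This
#' multiplicative form reproduces all four published adjusted values after
#' two-decimal rounding (0.7 x 0.97 -> 0.68, 0.7 x 0.77 -> 0.54,
#' 0.7 x 0.50 = 0.35, 0.7 x 0.05 -> 0.04).
#'
#' @param d_w_base Baseline winter survival probability (default regime
#'   with insulating snow cover).
#' @param mortality Freeze-mortality fraction in `[0, 1]`.
#' @return Adjusted winter survival probability (unrounded).
#' @export
#' @examples
#' adjust_winter_survival(0.7, 0.50)  # 0.35
adjust_winter_survival <- function(d_w_base, mortality) {
  for (v in list(d_w_base = d_w_base, mortality = mortality)) {
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("d_w_base and mortality must be single numbers in [0, 1]",
           call. = FALSE)
    }
  }
  d_w_base * (1 - mortality)
}

# Half-up rounding to `digits` decimals, used only when comparing against
# published two-decimal values (internal values are never rounded).
round2 <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Snow-loss scenario specification
#'
#' One winter scenario, defined either by a direct freeze-mortality
#' fraction or by a winter minimum temperature plus an SCP sample (the
#' mortality is then derived with [mortality_from_scp()]). Exactly one of
#' the two routes must determine the mortality.
#'
#' @param name Scenario identifier (character).
#' @param t_min Minimum winter air temperature in degC; `NA` for a
#'   baseline scenario with intact snow cover.
#' @param mortality Direct freeze-mortality fraction in `[0, 1]`, or
#'   `NULL` to derive it from `scp`.
#' @param scp An [scp_sample()] used with `t_min` when `mortality` is not
#'   supplied.
#' @param d_w_base Baseline winter survival (default 0.7).
#' @return An object of class `"scenario_spec"` with fields `name`,
#'   `t_min`, `mortality`, `d_w_base` and the derived `d_w`.
#' @seealso [build_paper_scenarios()], [run_scenario()]
#' @export
scenario_spec <- function(name, t_min = NA_real_, mortality = NULL,
                          scp = NULL, d_w_base = 0.7) {
  name <- as.character(name)
  if (is.null(mortality) && is.null(scp)) {
    mortality <- 0
  } else if (is.null(mortality)) {
    if (is.na(t_min)) {
      stop("deriving mortality from an SCP sample requires `t_min`",
           call. = FALSE)
    }
    mortality <- mortality_from_scp(scp, t_min)
  } else if (!is.null(scp)) {
    stop("supply either a direct `mortality` or (`t_min` + `scp`), not both",
         call. = FALSE)
  }
  d_w <- adjust_winter_survival(d_w_base, mortality)
  structure(list(name = name, t_min = as.numeric(t_min),
                 mortality = mortality, d_w_base = d_w_base, d_w = d_w),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  tm <- if (is.na(x$t_min)) "snow cover intact" else sprintf("t_min = %g degC", x$t_min)
  cat(sprintf("Scenario '%s': %s, freeze mortality = %g, d_w = %g\n",
              x$name, tm, x$mortality, x$d_w))
  invisible(x)
}

#' The five canonical snow-cover-disappearance scenarios
#'
#' Scenario "0" keeps the baseline winter survival (0.7, intact snow
#' cover); scenarios 1--4 expose the overwintering population to winter
#' minima of -5.5, -8, -10 and -14 degC with published freeze mortalities
#' of 3, 23, 50 and 95 per cent, giving adjusted winter survivals of 0.68,
#' 0.54, 0.35 and 0.04 at two decimals.
#'
#' @param d_w_base Baseline winter survival (default 0.7).
#' @return A list of five [scenario_spec()] objects named "0".."4".
#' @export
#' @examples
#' sc <- build_paper_scenarios()
#' sapply(sc, function(s) s$d_w)
build_paper_scenarios <- function(d_w_base = 0.7) {
  defs <- list(
    list(name = "0", t_min = NA_real_, mortality = 0),
    list(name = "1", t_min = -5.5, mortality = 0.03),
    list(name = "2", t_min = -8,   mortality = 0.23),
    list(name = "3", t_min = -10,  mortality = 0.50),
    list(name = "4", t_min = -14,  mortality = 0.95)
  )
  out <- lapply(defs, function(d) {
    scenario_spec(d$name, t_min = d$t_min, mortality = d$mortality,
                  d_w_base = d_w_base)
  })
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}
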