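#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing a full run: the demographic
#' `parameters` block (scalar rates plus the `e1`/`e2` and optional `e3`
#' laying schedules), an optional `initial_state` block, an optional
#' `scenarios` list (each entry either a direct `mortality` or a `t_min`
#' plus `scp_csv` path), and an optional `run` block
#' (`n_seasons`, `extinction_threshold`, `bookkeeping`, `seed`).
#' Unknown keys anywhere are rejected with the offending path named;
#' every applied default is reported with a message.
#'
#' @param path Path to a YAML file.
#' @param quiet Suppress the messages reporting applied defaults.
#' @return An object of class `"run_config"`: a list with `parameters`
#'   ([model_parameters()]), `initial_state` ([initial_state()]),
#'   `scenarios` (list of [scenario_spec()], possibly empty) and `run`
#'   (list with `n_seasons`, `extinction_threshold`, `bookkeeping`,
#'   `seed`).
#' @export
#' @examples
#' cfg_file <- system.file("extdata", "paper_scenarios.yaml",
#'                         package = "vertigopop")
#' cfg <- load_config(cfg_file, quiet = TRUE)
#' cfg$parameters
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("config parse error in %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  note <- function(...) if (!quiet) message(sprintf(...))

  check_keys(raw, c("parameters", "initial_state", "scenarios", "run"),
             "top level")
  if (is.null(raw$parameters)) {
    stop("config is missing the required 'parameters' block", call. = FALSE)
  }

  pk <- c("d_a1", "d_a2", "d_a3", "d_j", "d_e", "d_w", "a",
          "e1", "e2", "e3")
  check_keys(raw$parameters, pk, "parameters")
  missing <- setdiff(setdiff(pk, "e3"), names(raw$parameters))
  if (length(missing)) {
    stop(sprintf("parameters block is missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(raw$parameters$e3)) {
    note("applied default: parameters.e3 = (0, 0, 0, 0, 0, 0)")
  }
  params <- model_parameters(
    d_a1 = raw$parameters$d_a1, d_a2 = raw$parameters$d_a2,
    d_a3 = raw$parameters$d_a3, d_j = raw$parameters$d_j,
    d_e = raw$parameters$d_e, d_w = raw$parameters$d_w,
    a = raw$parameters$a,
    e1 = unlist(raw$parameters$e1), e2 = unlist(raw$parameters$e2),
    e3 = unlist(raw$parameters$e3 %||% rep(0, 6))
  )

  if (is.null(raw$initial_state)) {
    init <- default_initial_state()
    note("applied default: initial_state = 100 in each of J, N1, N2, N3")
  } else {
    check_keys(raw$initial_state, c("J", "N1", "N2", "N3"), "initial_state")
    init <- initial_state(
      J = raw$initial_state$J %||% 0, N1 = raw$initial_state$N1 %||% 0,
      N2 = raw$initial_state$N2 %||% 0, N3 = raw$initial_state$N3 %||% 0)
  }

  scenarios <- list()
  if (!is.null(raw$scenarios)) {
    scenarios <- lapply(seq_along(raw$scenarios), function(k) {
      sc <- raw$scenarios[[k]]
      where <- sprintf("scenarios[%d]", k)
      check_keys(sc, c("name", "t_min", "mortality", "scp_csv", "d_w_base"),
                 where)
      if (is.null(sc$name)) {
        stop(sprintf("%s is missing 'name'", where), call. = FALSE)
      }
      scp <- if (!is.null(sc$scp_csv)) {
        p <- sc$scp_csv
        if (!file.exists(p)) {
          p2 <- file.path(dirname(path), sc$scp_csv)
          if (file.exists(p2)) p <- p2 else {
            stop(sprintf("%s: SCP file not found: %s", where, sc$scp_csv),
                 call. = FALSE)
          }
        }
        read_scp_csv(p)
      }
      scenario_spec(sc$name, t_min = sc$t_min %||% NA_real_,
                    mortality = sc$mortality, scp = scp,
                    d_w_base = sc$d_w_base %||% 0.7)
    })
    names(scenarios) <- vapply(scenarios, function(s) s$name, character(1))
  }

  run_defaults <- list(n_seasons = 20L, extinction_threshold = 1.0,
                       bookkeeping = "literal", seed = 1L)
  run <- raw$run %||% list()
  check_keys(run, names(run_defaults), "run")
  for (nm in names(run_defaults)) {
    if (is.null(run[[nm]])) {
      run[[nm]] <- run_defaults[[nm]]
      note("applied default: run.%s = %s", nm, format(run_defaults[[nm]]))
    }
  }
  if (!run$bookkeeping %in% c("literal", "corrected")) {
    stop("run.bookkeeping must be 'literal' or 'corrected'", call. = FALSE)
  }
  if (run$n_seasons < 1) stop("run.n_seasons must be >= 1", call. = FALSE)

  structure(list(parameters = params, initial_state = init,
                 scenarios = scenarios, run = run),
            class = "run_config")
}

check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible())
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) at %s: %s (allowed: %s)", where,
                 paste(unknown, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  invisible()
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration: %d scenario(s), %d seasons, %s bookkeeping\n",
              length(x$scenarios), x$run$n_seasons, x$run$bookkeeping))
  invisible(x)
}

#' Write / read a simulated trajectory as CSV
#'
#' One row per active month with columns
#' `season,month,step,E,J,N1,N2,N3,N_total`, written at full precision so
#' that a round trip reproduces the totals exactly.
#'
#' @param result A [simulate_population()] result (or its trajectory data
#'   frame).
#' @param path Destination CSV path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns the trajectory data frame.
#' @export
write_trajectory_csv <- function(result, path) {
  tr <- if (inherits(result, "simulation_result")) result$trajectory else result
  cols <- c("season", "month", "step", "E", "J", "N1", "N2", "N3", "N_total")
  stopifnot(all(cols %in% names(tr)))
  write_atomically(tr[, cols], path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  tr <- utils::read.csv(path)
  need <- c("season", "month", "step", "E", "J", "N1", "N2", "N3", "N_total")
  missing <- setdiff(need, names(tr))
  if (length(missing)) {
    stop(sprintf("trajectory CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tr
}

#' Read / write supercooling-point samples as CSV
#'
#' The on-disk format is a single column `scp_c` of measurements in degC,
#' with an optional second column `stage` (`juvenile`/`adult`).
#'
#' @param path CSV path.
#' @param sample An [scp_sample()].
#' @return `read_scp_csv()` returns an [scp_sample()];
#'   `write_scp_csv()` returns `path` invisibly.
#' @export
read_scp_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"scp_c" %in% names(df)) {
    stop(sprintf("SCP CSV %s must have a column named 'scp_c'", path),
         call. = FALSE)
  }
  scp_sample(df$scp_c, stage = df$stage)
}

#' @rdname read_scp_csv
#' @export
write_scp_csv <- function(sample, path) {
  if (!inherits(sample, "scp_sample")) {
    stop("`sample` must be an 'scp_sample' object", call. = FALSE)
  }
  df <- data.frame(scp_c = sample$values)
  if (!is.null(sample$stage)) df$stage <- sample$stage
  write_atomically(df, path)
  invisible(path)
}

#' Write scenario summaries
#'
#' `write_scenario_table_csv()` writes the comparison table (one row per
#' scenario, columns `scenario,mean_final,sd_final,min_final,max_final,`
#' `time_to_extinction_months,lambda_pct`); `write_summary_json()` writes
#' a single scenario summary as JSON.
#'
#' @param table A data frame as returned by [run_paper_scenarios()].
#' @param summary A [run_scenario()] summary.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_scenario_table_csv <- function(table, path) {
  cols <- c("scenario", "mean_final", "sd_final", "min_final", "max_final",
            "time_to_extinction_months", "lambda_pct")
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop(sprintf("scenario table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  write_atomically(table[, cols], path)
  invisible(path)
}

#' @rdname write_scenario_table_csv
#' @export
write_summary_json <- function(summary, path) {
  if (!inherits(summary, "scenario_summary")) {
    stop("`summary` must be a 'scenario_summary' object", call. = FALSE)
  }
  out <- summary[c("scenario", "t_min", "mortality", "d_w", "mean_final",
                   "sd_final", "min_final", "max_final",
                   "time_to_extinction", "lambda_pct", "n_seasons")]
  ok <- FALSE
  on.exit(if (!ok && file.exists(path)) unlink(path), add = TRUE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  ok <- TRUE
  invisible(path)
}

# Full-precision CSV write; removes a partial file on failure.
write_atomically <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  ok <- FALSE
  on.exit({
    if (!ok && file.exists(tmp)) unlink(tmp)
  }, add = TRUE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  ok <- TRUE
  invisible(path)
}
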