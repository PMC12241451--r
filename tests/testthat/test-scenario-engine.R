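# Multi-season scenario runs and their summary statistics.

make_result <- function(totals_by_season) {
  # minimal simulation_result stub with prescribed monthly totals
  n <- length(totals_by_season)
  tr <- data.frame(season = rep(seq_len(n), each = 6),
                   month = rep(1:6, n))
  tr$step <- (tr$season - 1) * 6 + tr$month
  tr$N_total <- unlist(totals_by_season)
  structure(list(trajectory = tr), class = "simulation_result")
}

test_that("season mean averages the six monthly totals", {
  res <- make_result(list(rep(10, 6), c(100, 200, 300, 300, 200, 100)))
  expect_equal(season_mean(res, 1), 10)
  expect_equal(season_mean(res, 2), 200)
  expect_equal(season_mean(make_result(list(rep(0, 6))), 1), 0)
  expect_error(season_mean(res, 3), "not present")
})

test_that("growth rate is the percent change between season means", {
  res <- make_result(list(rep(100, 6), rep(101.4, 6)))
  expect_equal(lambda_growth(res, 1, 2), 1.4)
  expect_equal(lambda_growth(make_result(list(rep(5, 6), rep(5, 6)))), 0)
  expect_equal(lambda_growth(make_result(list(rep(100, 6), rep(0, 6)))), -100)
  expect_warning(l0 <- lambda_growth(make_result(list(rep(0, 6), rep(3, 6)))),
                 "undefined")
  expect_true(is.na(l0))
})

test_that("extinction time is the first sustained drop below threshold", {
  # transient dip below 1 at step 3 must not count
  res <- make_result(list(c(5, 3, 0.5, 4, 3, 2), c(0.8, 0.6, 0.4, 0.2, 0.1, 0)))
  expect_equal(time_to_extinction(res), 7L)
  expect_true(is.na(time_to_extinction(make_result(list(rep(10, 6))))))
  expect_equal(time_to_extinction(make_result(list(rep(0, 6)))), 1L)
  # threshold is configurable
  expect_equal(time_to_extinction(res, threshold = 0.05), 12L)
  # zero winter survival: extinct from the opening of season 2
  p0 <- params_with(d_w = 0)
  r0 <- simulate_population(default_initial_state(), p0, n_seasons = 3)
  expect_equal(time_to_extinction(r0), 7L)
  z <- simulate_population(initial_state(), default_parameters(), 2)
  expect_equal(time_to_extinction(z), 1L)
})

test_that("run_scenario overrides d_w and summarises the final season", {
  p <- default_parameters()
  init <- default_initial_state()
  sp0 <- scenario_spec("dead", mortality = 1)  # d_w = 0
  s <- run_scenario(sp0, p, init, n_seasons = 5)
  expect_equal(s$time_to_extinction, 7L)
  expect_equal(s$mean_final, 0)
  expect_equal(s$lambda_pct, -100)

  sc3 <- build_paper_scenarios()[["3"]]
  s3 <- run_scenario(sc3, p, init, n_seasons = 8)
  finals <- season_totals(s3$result, 8)
  expect_equal(s3$mean_final, mean(finals))
  expect_equal(s3$sd_final, sd(finals))
  expect_equal(s3$min_final, min(finals))
  expect_equal(s3$max_final, max(finals))
  expect_true(s3$min_final <= s3$mean_final && s3$mean_final <= s3$max_final)
  expect_equal(s3$result$parameters$d_w, 0.35)
})

test_that("growth rate is invariant to rescaling the initial state", {
  p <- default_parameters()
  sp <- build_paper_scenarios()[["2"]]
  s1 <- run_scenario(sp, p, initial_state(J = 10, N1 = 20, N2 = 5, N3 = 1),
                     n_seasons = 10)
  s2 <- run_scenario(sp, p, initial_state(J = 70, N1 = 140, N2 = 35, N3 = 7),
                     n_seasons = 10)
  expect_equal(s1$lambda_pct, s2$lambda_pct, tolerance = 1e-12)
  expect_equal(s2$mean_final, 7 * s1$mean_final, tolerance = 1e-12)
})

test_that("scenario summaries are ordered by winter severity", {
  for (p in c(list(default_parameters()), random_parameters(2, seed = 11))) {
    tab <- run_paper_scenarios(p, n_seasons = 12)
    expect_equal(tab$scenario, c("0", "1", "2", "3", "4"))
    expect_true(all(diff(tab$mean_final) < 0))
    tte <- ifelse(is.na(tab$time_to_extinction_months), Inf,
                  tab$time_to_extinction_months)
    expect_true(all(tte[-length(tte)] >= tte[-1]))
  }
})

test_that("deterministic scenario runs are bit-reproducible", {
  p <- default_parameters()
  init <- default_initial_state()
  sp <- build_paper_scenarios()[["2"]]
  a <- run_scenario(sp, p, init, n_seasons = 10)
  b <- run_scenario(sp, p, init, n_seasons = 10)
  expect_identical(a$result$trajectory, b$result$trajectory)
  expect_identical(a$mean_final, b$mean_final)
})

test_that("one-at-a-time sensitivity reports meaningful elasticities", {
  p <- default_parameters()
  tab <- sensitivity_oat(p, default_initial_state(), n_seasons = 6)
  expect_setequal(tab$parameter, c("d_a1", "d_a2", "d_a3", "d_j", "d_e",
                                   "d_w", "a", "init_scale"))
  # a persisting population responds positively to winter survival
  expect_gt(tab$elasticity[tab$parameter == "d_w"], 0)
  # linearity: elasticity with respect to initial-state scale is exactly 1
  expect_equal(tab$elasticity[tab$parameter == "init_scale"], 1,
               tolerance = 1e-10)
  # a parameter the response cannot depend on: age-3 survival with no
  # age-3 adults and a one-season horizon
  tab1 <- sensitivity_oat(p, initial_state(J = 50, N1 = 50, N2 = 50, N3 = 0),
                          n_seasons = 1, parameters = "d_a3")
  expect_equal(tab1$elasticity[tab1$parameter == "d_a3"], 0)
})

test_that("perturbations leaving [0, 1] are clipped with a warning", {
  p <- params_with(d_w = 0.95)
  expect_warning(
    tab <- sensitivity_oat(p, default_initial_state(), n_seasons = 2,
                           parameters = "d_w"),
    "clipped")
  expect_lte(tab$high[tab$parameter == "d_w"], 1)
})
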