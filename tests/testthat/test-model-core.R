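# Deterministic five-stage monthly update rules and the overwintering
# transition.

test_that("egg laying is per-capita and schedule-indexed", {
  p <- params_with(e1 = c(5, 2, 0, 0, 0, 0), e2 = c(3, 3, 0, 0, 0, 0))
  expect_equal(lay_eggs(list(N1 = 10, N2 = 0, N3 = 0, month = 1), p), 50)
  expect_equal(lay_eggs(list(N1 = 4, N2 = 6, N3 = 0, month = 2), p),
               4 * 2 + 6 * 3)
  expect_equal(lay_eggs(list(N1 = 0, N2 = 0, N3 = 0, month = 1), p), 0)
  # age-3 adults lay only when e3 is switched on
  expect_equal(lay_eggs(list(N1 = 0, N2 = 0, N3 = 7, month = 1), p), 0)
  p3 <- params_with(e3 = c(2, 0, 0, 0, 0, 0))
  expect_equal(lay_eggs(list(N1 = 0, N2 = 0, N3 = 7, month = 1), p3), 14)
  expect_error(lay_eggs(list(N1 = 1, N2 = 0, N3 = 0, month = 7), p),
               "month index")
  expect_error(lay_eggs(list(N1 = 1, N2 = 0, N3 = 0, month = 0), p),
               "month index")
})

test_that("juvenile update follows the month-indexed branches", {
  p <- params_with(d_e = 0.8, d_j = 0.9, a = 0.1)
  expect_equal(update_juveniles(season_history(integer(0)), p, 1), 0)
  h <- season_history(1, E = 50)
  expect_equal(update_juveniles(h, p, 2), 40)
  # months 3-4: survival of last month's juveniles plus new hatchlings
  h <- season_history(1:2, E = c(50, 20), J = c(0, 40))
  expect_equal(update_juveniles(h, p, 3), 40 * 0.9 + 20 * 0.8)
  # month 5, literal mode: the whole lagged cohort term leaves the pool
  h <- season_history(1:4, E = c(0, 0, 0, 0), J = c(0, 30, 0, 100))
  expect_equal(update_juveniles(h, p, 5), 100 * 0.9 - 0.9 * 30 * 0.9)
  # corrected mode removes only the maturing fraction a * J(2) * d_j
  expect_equal(update_juveniles(h, p, 5, mode = "corrected"),
               100 * 0.9 - 0.1 * 30 * 0.9)
  # a = 1 annihilates the literal subtraction: identical to month-3/4 rule
  p1 <- params_with(d_e = 0.8, d_j = 0.9, a = 1)
  for (i in 5:6) {
    h <- season_history(1:(i - 1), E = 10, J = c(0, 30, 44, 100, 80)[1:(i - 1)])
    expect_equal(update_juveniles(h, p1, i),
                 h$J[i - 1] * 0.9 + h$E[i - 1] * 0.8)
  }
})

test_that("negative literal-mode intermediates are clamped, never silent", {
  # tiny egg input and a huge lagged cohort force the subtraction negative
  p <- params_with(d_e = 0, d_j = 0.5, a = 0.1)
  h <- season_history(1:4, E = 0, J = c(0, 100, 10, 20))
  expect_warning(j5 <- update_juveniles(h, p, 5), "clamped")
  expect_identical(j5, 0)
  # the corrected bookkeeping stays non-negative on the same input
  expect_silent(j5c <- update_juveniles(h, p, 5, mode = "corrected"))
  expect_gte(j5c, 0)
})

test_that("adult update combines survival with mid-season recruitment", {
  h <- season_history(1:2, N1 = c(110, 100))
  expect_equal(unname(update_adults(h, params_with(d_a1 = 0.875), 3)["N1"]),
               87.5)
  p <- params_with(d_a1 = 0.9, d_j = 0.8, a = 0.125)
  h <- season_history(1:4, J = c(0, 40, 0, 0), N1 = c(0, 0, 0, 50))
  out <- update_adults(h, p, 5)
  expect_equal(unname(out["N1"]), 50 * 0.9 + 0.125 * 40 * 0.8)  # 49
  # zero propagates through the older classes
  h0 <- season_history(1:3, N2 = 0, N3 = 0)
  out0 <- update_adults(h0, p, 4)
  expect_equal(unname(out0[c("N2", "N3")]), c(0, 0))
  expect_error(update_adults(h0, p, 1), "overwinter")
})

test_that("overwintering advances classes, drops age 3, eggs and juveniles", {
  p <- params_with(d_w = 0.7)
  nxt <- overwinter(list(month = 6, J = 100, N1 = 50, N2 = 20, N3 = 500), p)
  expect_equal(nxt$N1, 70)
  expect_equal(nxt$N2, 35)
  expect_equal(nxt$N3, 14)
  expect_equal(nxt$J, 0)
  # age-3 adults at season end contribute nothing anywhere
  base <- overwinter(list(month = 6, J = 100, N1 = 50, N2 = 20, N3 = 0), p)
  expect_equal(unlist(nxt[c("J", "N1", "N2", "N3", "E")]),
               unlist(base[c("J", "N1", "N2", "N3", "E")]))
  # d_w = 0 empties the next season
  p0 <- params_with(d_w = 0)
  nxt0 <- overwinter(list(month = 6, J = 100, N1 = 50, N2 = 20, N3 = 5), p0)
  expect_equal(unlist(nxt0[c("J", "N1", "N2", "N3")]),
               c(J = 0, N1 = 0, N2 = 0, N3 = 0))
})

test_that("simulation trajectory has the documented shape and totals", {
  res <- simulate_population(default_initial_state(), default_parameters(),
                             n_seasons = 4)
  tr <- res$trajectory
  expect_equal(nrow(tr), 24)
  expect_equal(tr$step, (tr$season - 1) * 6 + tr$month)
  expect_equal(tr$N_total, tr$J + tr$N1 + tr$N2 + tr$N3)
  # default laying window is May-August: no eggs in months 5-6
  expect_true(all(tr$E[tr$month %in% c(5, 6)] == 0))
  # model-generated month-1 states carry no juveniles
  expect_true(all(tr$J[tr$month == 1 & tr$season > 1] == 0))
  expect_equal(nrow(res$diagnostics), 0)
})

test_that("empty population is absorbing and the model is linear in state", {
  p <- default_parameters()
  z <- simulate_population(initial_state(), p, n_seasons = 3)
  expect_true(all(z$trajectory$N_total == 0))
  x1 <- simulate_population(initial_state(J = 0, N1 = 37, N2 = 11, N3 = 3),
                            p, n_seasons = 6)
  x2 <- simulate_population(initial_state(J = 0, N1 = 3 * 37, N2 = 3 * 11,
                                          N3 = 3 * 3), p, n_seasons = 6)
  for (col in c("E", "J", "N1", "N2", "N3", "N_total")) {
    expect_equal(x2$trajectory[[col]], 3 * x1$trajectory[[col]],
                 tolerance = 1e-12)
  }
})

test_that("winter survival of zero cuts every between-season channel", {
  p <- params_with(d_w = 0)
  res <- simulate_population(default_initial_state(), p, n_seasons = 3)
  tr <- res$trajectory
  expect_true(all(tr$N_total[tr$step >= 7] == 0))
  expect_gt(tr$N_total[6], 0)
})

test_that("final-season abundance is monotone in each survival parameter", {
  init <- default_initial_state()
  grids <- list(d_w = c(0.5, 0.65, 0.8), d_a1 = c(0.6, 0.75, 0.9),
                d_a2 = c(0.6, 0.75, 0.9), d_a3 = c(0.6, 0.75, 0.9),
                d_j = c(0.6, 0.75, 0.9), d_e = c(0.5, 0.7, 0.9))
  for (nm in names(grids)) {
    finals <- vapply(grids[[nm]], function(v) {
      p <- default_parameters()
      p[[nm]] <- v
      # low juvenile survival can trigger (surfaced) literal-mode clamping
      season_mean(suppressWarnings(simulate_population(init, p, n_seasons = 6)), 6)
    }, numeric(1))
    expect_true(all(diff(finals) >= 0), label = sprintf(
      "mean final abundance non-decreasing in %s (got %s)", nm,
      paste(signif(finals, 6), collapse = ", ")))
  }
})

test_that("corrected bookkeeping never needs clamping on plausible rates", {
  init <- default_initial_state()
  for (p in random_parameters(5, seed = 42)) {
    res <- simulate_population(init, p, n_seasons = 8, mode = "corrected")
    expect_equal(nrow(res$diagnostics), 0)
    expect_true(all(res$trajectory$N_total >= 0))
  }
})

test_that("parameters outside [0, 1] are rejected before simulating", {
  expect_error(params_with(d_w = 1.3), "outside the valid range")
  expect_error(params_with(a = -0.1), "outside the valid range")
  expect_error(params_with(e1 = c(-1, 0, 0, 0, 0, 0)), "element-wise")
  expect_error(model_parameters(d_a1 = 0.9, d_a2 = 0.9, d_a3 = 0.9,
                                d_j = 0.9, d_e = 0.9, d_w = 0.7, a = 0.1,
                                e1 = c(1, 2, 3), e2 = rep(0, 6)),
               "length 6")
})
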