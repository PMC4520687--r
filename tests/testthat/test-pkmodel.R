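test_that("activity link: relative activity and conversion rate", {
  expect_equal(relative_activity(tpmt_activity(10, 10)), 1.0)
  expect_equal(relative_activity(tpmt_activity(5, 10)), 0.5)
  expect_equal(relative_activity(tpmt_activity(30, 30)), 1.0)
  expect_error(tpmt_activity(31, 30), "invalid")
  expect_error(tpmt_activity(5, -1), "invalid")

  expect_equal(effective_conversion_rate(tpmt_activity(30, 30, 50)), 0)
  expect_equal(effective_conversion_rate(tpmt_activity(0, 30, 50)), 50)
  expect_equal(effective_conversion_rate(tpmt_activity(7.5, 30, 50)), 37.5)
  # monotone decreasing in activity
  e_grid <- seq(0, 30, by = 5)
  k <- sapply(e_grid, function(e)
    effective_conversion_rate(tpmt_activity(e, 30, 100)))
  expect_true(all(diff(k) < 0))
})

test_that("equilibrium and mass conservation of the gut/plasma subsystem", {
  p <- mean_params()
  tr <- simulate_pk(p, dose_schedule(), times = 0:10)
  expect_true(all(tr$x_g == 0 & tr$x_c == 0 & tr$x_m == 0))

  # with negligible elimination and conversion, a bolus is conserved
  p2 <- pk_params(k_ab = 2, k_el = 1e-12, k_cm = 1e-12, K = 15, k_me = 0.1)
  tr2 <- simulate_pk(p2, dose_schedule(0, 500), times = c(0, 0.5, 1, 5, 10))
  expect_equal(tr2$x_g + tr2$x_c, rep(500, 5), tolerance = 1e-6)
})

test_that("adaptive solver matches the fixed-step RK4 oracle", {
  p <- mean_params()
  doses <- daily_doses(113, 75)
  times <- c(1, 5, 20, 50, 75)
  tr <- simulate_pk(p, doses, c(0, times))
  oracle <- rk4_pk(p, doses, times, h = 1e-3)
  expect_equal(tr$x_m[-1], oracle[, "x_m"], tolerance = 1e-4)

  # random parameter draws, shorter horizon
  set.seed(7)
  theta <- sample_population(20, seed = 7)
  d10 <- daily_doses(113, 10)
  for (i in seq_len(20)) {
    pp <- pk_params(theta[i, 1], theta[i, 2], theta[i, 3], theta[i, 4],
                    theta[i, 5])
    got <- simulate_pk(pp, d10, c(0, 3, 10))$x_m[-1]
    want <- rk4_pk(pp, d10, c(3, 10), h = 1e-3)[, "x_m"]
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("superposition holds in the linear (large-K) regime", {
  # K -> inf with k_cm/K fixed makes the whole system linear
  Kbig <- 1e9
  p <- pk_params(4.2, 3.8, 2 * Kbig, Kbig, 0.08)
  t_out <- c(0, 1, 2, 5, 10)
  a <- simulate_pk(p, dose_schedule(0, 100), t_out)
  b <- simulate_pk(p, dose_schedule(3, 250), t_out)
  ab <- simulate_pk(p, dose_schedule(c(0, 3), c(100, 250)), t_out)
  expect_equal(ab$x_m, a$x_m + b$x_m, tolerance = 1e-6)
})

test_that("steady state: closed form agrees with long-horizon integration", {
  p <- mean_params()
  expect_equal(steady_state_tgn(p, 0), 0)

  # saturated Michaelis-Menten limit: x_m* -> nu_cm k_cm / k_me
  psat <- pk_params(4.2, 3.8, 39.4, 1e-8, 0.08)
  expect_equal(steady_state_tgn(psat, 80), 39.4 / 0.08, tolerance = 1e-6)

  u <- 113
  ss <- steady_state_tgn(p, u)
  long <- simulate_pk(p, dose_schedule(infusion = u), times = c(0, 400))
  expect_equal(long$x_m[2], ss, tolerance = 1e-3)

  # infeasible: no elimination and infusion above conversion capacity
  p0 <- pk_params(4.2, 1e-14, 39.4, 15.11, 0.08)
  expect_error(steady_state_tgn(pk_params(4.2, 1, 39.4, 15.11, 0.08,
                                          nu_cm = 1), -1))
})

test_that("states stay non-negative and 6-TGN decreases with TPMT activity", {
  doses <- daily_doses(113, 30)
  set.seed(3)
  theta <- sample_population(10, seed = 3)
  for (i in seq_len(10)) {
    pp <- pk_params(theta[i, 1], theta[i, 2], theta[i, 3], theta[i, 4],
                    theta[i, 5])
    tr <- simulate_pk(pp, doses, seq(0, 30, by = 1))
    expect_true(all(tr$x_g >= 0 & tr$x_c >= 0 & tr$x_m >= 0))
  }
  # higher activity -> lower conversion rate -> pointwise lower x_m
  xm <- sapply(c(8, 15, 25), function(e) {
    kcm <- effective_conversion_rate(tpmt_activity(e, 30, 100))
    simulate_pk(pk_params(4.2, 3.8, kcm, 15.11, 0.08), doses,
                seq(0, 30, by = 5))$x_m
  })
  expect_true(all(xm[-1, 1] > xm[-1, 2] & xm[-1, 2] > xm[-1, 3]))
})

test_that("dose schedules validate and serialize", {
  expect_error(dose_schedule(-1, 10), "non-negative")
  d <- dose_schedule(c(3, 1), c(5, 10))
  expect_equal(d$times, c(1, 3))      # sorted with amounts carried along
  expect_equal(d$amounts, c(10, 5))

  tmp <- tempfile(fileext = ".json")
  write_pk_json(mean_params(), tmp)
  p2 <- read_pk_json(tmp, "params")
  expect_equal(unclass(p2), unclass(mean_params()))
  write_pk_json(d, tmp)
  d2 <- read_pk_json(tmp, "doses")
  expect_equal(d2$amounts, d$amounts)
  unlink(tmp)
})
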