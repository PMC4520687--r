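test_that("forward sensitivities agree with central finite differences", {
  p <- mean_params()
  doses <- daily_doses(113, 100)
  times <- c(1, 20, 50, 90)
  sens <- output_sensitivities(p, doses, times,
                               param_subset = c("k_cm", "k_el", "k_me"))
  for (nm in c("k_cm", "k_el", "k_me")) {
    base <- unlist(p[c("k_ab", "k_el", "k_cm", "K", "k_me")])
    h <- base[[nm]] * 1e-5
    up <- base; up[nm] <- up[nm] + h
    dn <- base; dn[nm] <- dn[nm] - h
    fu <- simulate_pk(pk_params(up[1], up[2], up[3], up[4], up[5]), doses,
                      c(0, times))$x_m[-1]
    fd <- simulate_pk(pk_params(dn[1], dn[2], dn[3], dn[4], dn[5]), doses,
                      c(0, times))$x_m[-1]
    expect_equal(sens$S[, nm], (fu - fd) / (2 * h), tolerance = 1e-3)
  }
  # with no drug input every sensitivity vanishes
  s0 <- output_sensitivities(p, dose_schedule(), c(5, 10), "k_cm")
  expect_equal(unname(s0$S[, 1]), c(0, 0))
})

test_that("Fisher information assembles as inverse-variance-weighted outer products", {
  # linear toy: yhat = theta * t gives sensitivity column t
  tt <- c(1, 2, 4)
  S <- matrix(tt, ncol = 1)
  err <- error_params(1, 0)
  I <- fisher_information(S, err, predictions = rep(1, 3))
  expect_equal(as.numeric(I), sum(tt^2))

  # two-parameter toy vs direct assembly
  S2 <- cbind(c(1, 2, 3), c(0.5, -1, 2))
  yh <- c(10, 20, 30)
  err2 <- error_params(2, 0.1)
  sig <- 2 + 0.1 * yh
  want <- matrix(0, 2, 2)
  for (k in 1:3)
    want <- want + tcrossprod(S2[k, ]) / sig[k]^2
  expect_equal(fisher_information(S2, err2, yh), want)

  # adding a measurement never decreases the determinant
  d2 <- det(fisher_information(S2[1:2, ], err2, yh[1:2]))
  d3 <- det(fisher_information(S2, err2, yh))
  expect_gte(d3, d2 - 1e-12)

  # permutation of measurement order leaves the information unchanged
  perm <- c(3, 1, 2)
  expect_equal(fisher_information(S2[perm, ], err2, yh[perm]),
               fisher_information(S2, err2, yh))

  expect_error(fisher_information(S, error_params(0, 0.1), rep(0, 3)),
               "zero")
})

test_that("expected information grows toward steady state and selects t*", {
  # single prior draw: the profile is that draw's deterministic profile
  one <- posterior_samples(matrix(c(4.2, 3.8, 39.4, 15.11, 0.08, 10, 0.05),
                                  1, 7, dimnames = list(NULL, all_names)))
  days <- c(5, 15, 35, 60, 90)
  prof1 <- expected_information_profile(one, days, n_draws = 3, seed = 1)
  sens <- output_sensitivities(mean_params(), daily_doses(113, 90), days,
                               "k_cm", rtol = 1e-6, atol = 1e-8)
  sig <- 10 + 0.05 * sens$yhat
  expect_equal(prof1$expected_information, (sens$S[, 1] / sig)^2,
               tolerance = 1e-6)
  # information accumulates toward the plateau of the response
  expect_true(all(diff(prof1$expected_information) > 0))

  # robust profile under the population prior keeps the same shape
  prof <- expected_information_profile(default_prior(), days,
                                       n_draws = 30, seed = 2)
  expect_true(all(diff(prof$expected_information) > 0))
  expect_true(all(prof$expected_information >= 0))

  # selection rules
  expect_equal(select_sampling_time(prof, 0), 90)
  flat <- prof; flat$expected_information <- rep(1, 5)
  expect_equal(select_sampling_time(flat, 0), 5)
  plateau <- prof
  plateau$expected_information <- c(0.2, 0.6, 0.97, 0.99, 1.0)
  expect_equal(select_sampling_time(plateau, 0.05), 35)
  # compromising a fraction of the information buys an earlier day
  expect_lte(select_sampling_time(prof, 0.05), 90)
})

test_that("the D-optimal single time matches an exhaustive scalar scan", {
  set.seed(4)
  theta <- sample_population(5, seed = 4)
  days <- seq(5, 90, by = 5)
  doses <- daily_doses(113, 90)
  err <- error_params(10, 0.05)
  # oracle: per-draw argmax of sigma_t^-2 (dyhat/dk_cm)^2 via direct scan
  for (i in 1:3) {
    pp <- pk_params(theta[i, 1], theta[i, 2], theta[i, 3], theta[i, 4],
                    theta[i, 5])
    sens <- output_sensitivities(pp, doses, days, "k_cm")
    crit <- (sens$S[, 1] / (10 + 0.05 * sens$yhat))^2
    one <- posterior_samples(matrix(c(theta[i, ], 10, 0.05), 1, 7,
                                    dimnames = list(NULL, all_names)))
    prof <- expected_information_profile(one, days, n_draws = 2, seed = 1)
    expect_equal(prof$day[which.max(prof$expected_information)],
                 days[which.max(crit)])
  }
})
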