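test_that("log-likelihood reduces to the Gaussian density term by term", {
  # zero dose, zero prediction, observation equal to prediction, sd 1
  p <- mean_params()
  d0 <- dose_schedule()
  one <- measurement_series("a", 5, 0, d0)
  expect_equal(log_likelihood(one, p, error_params(1, 0)),
               -0.5 * log(2 * pi))

  # independence: two points sum their individual contributions
  doses <- daily_doses(113, 30)
  s1 <- measurement_series("a", 10, 200, doses)
  s2 <- measurement_series("a", 25, 260, doses)
  s12 <- measurement_series("a", c(10, 25), c(200, 260), doses)
  err <- error_params(10, 0.05)
  expect_equal(log_likelihood(s12, p, err),
               log_likelihood(s1, p, err) + log_likelihood(s2, p, err),
               tolerance = 1e-10)

  # literal term-by-term evaluation on a 3-point toy
  tt <- c(7, 21, 30)
  y <- c(150, 240, 280)
  ser <- measurement_series("a", tt, y, doses)
  yh <- simulate_pk(p, doses, c(0, tt))$x_m[-1]
  sig <- 10 + 0.05 * yh
  direct <- sum(-log(sqrt(2 * pi) * sig) - (y - yh)^2 / (2 * sig^2))
  expect_equal(log_likelihood(ser, p, err), direct, tolerance = 1e-10)
})

test_that("MLE recovers the conversion rate from dense noise-free data", {
  truth <- c(k_ab = 4.2, k_el = 3.8, k_cm = 55, K = 15.11, k_me = 0.08,
             sigma_add = 10, sigma_prop = 0.05)
  pat <- make_patient(truth, times = seq(2, 56, by = 2), noise = FALSE)
  fit <- suppressWarnings(
    fit_mle(pat, nominal = truth, estimate = c("k_cm", "sigma_add"),
            n_starts = 3, seed = 2))
  expect_equal(fit$theta[["k_cm"]], 55, tolerance = 0.01)
  # optimality: at least as good as the truth itself
  ll_truth <- log_likelihood(pat, pk_params(4.2, 3.8, 55, 15.11, 0.08),
                             error_params(fit$theta[["sigma_add"]], 0.05),
                             rtol = 1e-6, atol = 1e-8)
  expect_gte(fit$logLik + 1e-6, ll_truth)
})

test_that("MLE degrades gracefully on underdetermined data", {
  doses <- daily_doses(113, 30)
  pat <- measurement_series("a", 30, 250, doses)
  expect_warning(fit <- fit_mle(pat, seed = 1), "fixing insensitive")
  # only the sparse fallback set was freed
  expect_true(all(fit$estimate %in% c("k_cm", "sigma_add")))
  expect_s3_class(fit$params, "pk_params")
})

test_that("MH sampler reproduces a conjugate Gaussian posterior", {
  # prior N(1, 2^2); 5 obs y ~ N(theta, 1): closed-form posterior
  y <- c(2.1, 1.4, 3.0, 2.6, 1.9)
  s0sq <- 4; m0 <- 1
  post_var <- 1 / (1 / s0sq + length(y))
  post_mean <- post_var * (m0 / s0sq + sum(y))
  lp <- function(x) -0.5 * (x - m0)^2 / s0sq - 0.5 * sum((y - x)^2)
  res <- mh_sample(lp, c(theta = 0), n_iter = 8000, n_chains = 4, seed = 5)
  n_eff <- nrow(res$draws) / 10        # conservative for autocorrelation
  mc_se <- sqrt(post_var / n_eff)
  expect_lt(abs(mean(res$draws) - post_mean), 3 * mc_se)
  expect_equal(var(as.numeric(res$draws)), post_var, tolerance = 0.25)
  expect_true(res$converged)
})

test_that("with no data the posterior returns the prior", {
  pr <- lognormal_prior(c(k_cm = 39.4, k_me = 0.08),
                        matrix(c(100, 0.1, 0.1, 4e-4), 2, 2,
                               dimnames = list(c("k_cm", "k_me"),
                                               c("k_cm", "k_me"))))
  lp <- function(x) prior_logpdf(pr, setNames(x, c("k_cm", "k_me")))
  res <- mh_sample(lp, pr$log_mean, n_iter = 6000, n_chains = 4,
                   prop_cov = pr$log_cov, seed = 9)
  expect_equal(colMeans(res$draws), pr$log_mean, tolerance = 0.05)
  expect_equal(apply(res$draws, 2, sd), sqrt(diag(pr$log_cov)),
               tolerance = 0.15)
})

test_that("posterior SD of k_cm does not grow with more observations", {
  truth <- c(k_ab = 4.2, k_el = 3.8, k_cm = 50, K = 15.11, k_me = 0.085,
             sigma_add = 10, sigma_prop = 0.05)
  pr <- default_prior()
  many <- make_patient(truth, times = c(4, 14, 28, 42, 49, 56), seed = 11)
  keep <- c(2, 6)                      # nested design: same y on shared days
  few <- measurement_series("sub", many$times[keep], many$y[keep],
                            many$doses)
  post_few <- suppressWarnings(
    sample_posterior_mcmc(few, pr, n_draws = 800, n_chains = 2, seed = 3))
  post_many <- suppressWarnings(
    sample_posterior_mcmc(many, pr, n_draws = 800, n_chains = 2, seed = 3))
  sd_few <- sd(post_few$draws[, "k_cm"])
  sd_many <- sd(post_many$draws[, "k_cm"])
  expect_lt(sd_many, sd_few * 1.15)    # Monte-Carlo slack
})

test_that("variational engine is exact on a Gaussian target", {
  mu <- c(a = 1.5, b = -0.5)
  S <- matrix(c(0.5, 0.2, 0.2, 0.4), 2, 2)
  Si <- solve(S)
  const <- 2.3
  lp <- function(x) const - 0.5 * as.numeric(t(x - mu) %*% Si %*% (x - mu))
  fit <- vb_gaussian(lp, c(a = 0, b = 0), diag(1, 2), n_mc = 16,
                     n_iter = 300, lr = 0.05, n_final = 2000, seed = 2)
  expect_equal(as.numeric(fit$mean), as.numeric(mu), tolerance = 0.05)
  expect_equal(diag(fit$cov), diag(S), tolerance = 0.15)
  # evidence of c * N(mu, S) integrates to c * (2 pi)^{d/2} |S|^{1/2}
  log_evid <- const + 0.5 * (2 * log(2 * pi) + determinant(S)$modulus[1])
  expect_equal(fit$elbo, log_evid, tolerance = 0.05)
})

test_that("the ELBO never exceeds the log evidence (quadrature check)", {
  # non-Gaussian 2-parameter target: banana-shaped density
  lp <- function(x) -0.5 * (x[1]^2 + 4 * (x[2] - 0.3 * x[1]^2)^2)
  g <- seq(-6, 6, length.out = 301)
  h <- g[2] - g[1]
  dens <- outer(g, g, Vectorize(function(a, b) exp(lp(c(a, b)))))
  log_evid <- log(sum(dens) * h^2)
  fit <- vb_gaussian(lp, c(0, 0), diag(0.5, 2), n_mc = 16, n_iter = 150,
                     n_final = 4000, seed = 4)
  expect_lt(fit$elbo, log_evid + 0.02)  # MC slack on the estimate
})

test_that("population prior pools patient posteriors with n-weighting", {
  p1 <- fake_posterior(c(k_cm = 30, k_me = 0.07), seed = 1)
  p2 <- fake_posterior(c(k_cm = 60, k_me = 0.10), seed = 2)

  single <- build_population_prior(list(p1), 3, seed = 5)
  expect_equal(single$weights, 1)
  expect_equal(single$mean, posterior_mean(p1), tolerance = 0.02)

  both <- build_population_prior(list(p1, p2), c(1, 3), seed = 5)
  expect_equal(both$weights, c(0.25, 0.75))
  # pooled mean equals the weighted average of component means
  want <- 0.25 * posterior_mean(p1) + 0.75 * posterior_mean(p2)
  expect_equal(both$mean, want, tolerance = 0.02)
  # MVN approximation is centred on the pooled draws exactly
  expect_equal(both$log_mean, colMeans(log(both$draws)), tolerance = 1e-8)

  expect_error(build_population_prior(list(), integer(0)))
  expect_error(build_population_prior(list(p1), 0), "positive")
})

test_that("group priors partition patients by activity window", {
  posts <- lapply(1:6, function(i)
    fake_posterior(c(k_cm = 20 + 10 * i, k_me = 0.08), seed = i))
  acts <- c(8, 8.5, 10, 12.2, 14.9, 16)

  g1 <- build_group_prior(posts, acts, c(7, 9), seed = 1)
  expect_equal(attr(g1, "members"), c(1L, 2L))
  g2 <- build_group_prior(posts, acts, c(9, 11), seed = 1)
  expect_equal(attr(g2, "members"), 3L)
  expect_error(build_group_prior(posts, acts, c(29, 31)), "empty group")

  # disjoint windows partition the patient set exactly
  members <- unlist(lapply(list(c(7, 9), c(9, 11), c(11, 13), c(13, 15),
                                c(15, 17)), function(w)
    attr(build_group_prior(posts, acts, w, seed = 1), "members")))
  expect_equal(sort(members), 1:6)

  # a window covering everyone reproduces the population mixture
  gall <- build_group_prior(posts, acts, c(7, 17), seed = 3)
  pop <- build_population_prior(posts, rep(1L, 6), seed = 3)
  expect_equal(posterior_mean(gall), pop$mean, tolerance = 0.03)
})

test_that("predictive bands are HPD intervals of the simulated predictive", {
  doses <- daily_doses(113, 30)
  # degenerate: a single draw with zero noise collapses the band
  one <- posterior_samples(matrix(c(4.2, 3.8, 39.4, 15.11, 0.08, 1e-9,
                                    1e-12),
                                  1, 7, dimnames = list(NULL, all_names)))
  b1 <- suppressWarnings(predictive_band(one, doses, c(10, 20), n_sim = 1))
  expect_equal(b1$lower, b1$upper, tolerance = 1e-6)
  expect_equal(b1$lower, simulate_pk(mean_params(), doses,
                                     c(0, 10, 20))$x_m[-1],
               tolerance = 1e-5)

  # Gaussian predictive: same kinetic draw, unit additive noise
  same <- posterior_samples(matrix(rep(c(4.2, 3.8, 39.4, 15.11, 0.08, 1,
                                         1e-12),
                                       each = 4000), 4000, 7,
                                   dimnames = list(NULL, all_names)))
  b <- predictive_band(same, doses, 20, level = 0.95, seed = 8)
  yh <- simulate_pk(mean_params(), doses, c(0, 20))$x_m[2]
  expect_equal(b$lower, yh - 1.96, tolerance = 0.08)
  expect_equal(b$upper, yh + 1.96, tolerance = 0.08)

  # level 1 spans the simulated extremes
  bfull <- predictive_band(same, doses, 20, level = 1, seed = 8)
  expect_lt(bfull$lower, b$lower)
  expect_gt(bfull$upper, b$upper)
})

test_that("lack-of-fit confidence follows the binomial tail convention", {
  band <- data.frame(time = 1:20, lower = rep(0, 20), upper = rep(1, 20))
  inside <- lack_of_fit(rep(0.5, 20), band)
  expect_equal(inside$n_inside, 20)
  expect_true(inside$adequate)

  allout <- lack_of_fit(rep(2, 20), band)
  expect_equal(allout$n_inside, 0)
  expect_gt(allout$confidence, 0.99)
  expect_false(allout$adequate)

  # calibration: model-generated data land inside a 95% band ~95% of the time
  doses <- daily_doses(113, 56)
  post <- fake_posterior(c(k_ab = 4.2, k_el = 3.8, k_cm = 39.4, K = 15.11,
                           k_me = 0.08, sigma_add = 10, sigma_prop = 0.05),
                         sdlog = 0.05, n = 400, seed = 3)
  tt <- c(7, 14, 28, 42, 56)
  band95 <- predictive_band(post, doses, tt, level = 0.95, seed = 4)
  set.seed(9)
  frac <- replicate(40, {
    th <- post$draws[sample.int(400, 1), ]
    yh <- simulate_pk(pk_params(th[1], th[2], th[3], th[4], th[5]),
                      doses, c(0, tt))$x_m[-1]
    y <- yh + rnorm(5, 0, th["sigma_add"] + th["sigma_prop"] * yh)
    mean(y >= band95$lower & y <= band95$upper)
  })
  expect_gt(mean(frac), 0.85)
  expect_lt(mean(frac), 1.0)
})

test_that("informative priors narrow predictive bands", {
  doses <- daily_doses(113, 56)
  tt <- seq(7, 56, by = 7)
  tight <- fake_posterior(c(k_ab = 4.2, k_el = 3.8, k_cm = 39.4, K = 15.11,
                            k_me = 0.08, sigma_add = 10, sigma_prop = 0.05),
                          sdlog = 0.08, n = 300, seed = 5)
  diffuse <- fake_posterior(c(k_ab = 4.2, k_el = 3.8, k_cm = 39.4, K = 15.11,
                              k_me = 0.08, sigma_add = 10,
                              sigma_prop = 0.05),
                            sdlog = 0.45, n = 300, seed = 5)
  b_tight <- predictive_band(tight, doses, tt, seed = 2)
  b_diffuse <- predictive_band(diffuse, doses, tt, seed = 2)
  expect_true(all(b_tight$upper - b_tight$lower <
                  b_diffuse$upper - b_diffuse$lower))
})

test_that("td_fit front-end exposes the standard modelling methods", {
  truth <- c(k_ab = 4.2, k_el = 3.8, k_cm = 45, K = 15.11, k_me = 0.08,
             sigma_add = 10, sigma_prop = 0.05)
  pat <- make_patient(truth, seed = 21)
  fit <- suppressWarnings(td_fit(pat, n_draws = 400, n_chains = 2, seed = 2))
  expect_s3_class(fit, "td_fit")
  co <- coef(fit)
  expect_named(co, all_names)
  expect_true(all(co > 0))
  sm <- summary(fit)
  expect_true(all(sm$coefficients[, "lower"] <= sm$coefficients[, "upper"]))
  pr <- predict(fit, times = c(0, 10, 20))
  expect_equal(nrow(pr), 3)
  rs <- residuals(fit)
  expect_length(rs, 4)
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(ncol(sim), 4)
  mle <- suppressWarnings(td_fit(pat, method = "mle", seed = 2))
  expect_true(is.finite(mle$mle$logLik))
})
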