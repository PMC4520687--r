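# S3 front-end: one fitting function for a patient's 6-TGN series,
# returning a classed model object with the usual methods.

#' Fit the 6-MP metabolism model to one patient
#'
#' The central estimation interface: given a patient's sparse 6-TGN series
#' and a prior, fits the seven-parameter model (five kinetic parameters
#' plus the two residual-error parameters) by MCMC (default), variational
#' Bayes, or maximum likelihood.
#'
#' @param data a [measurement_series()].
#' @param prior a prior object (see [prior_logpdf()]); default the
#'   moment-matched lognormal built from the published population
#'   statistics.
#' @param method `"mcmc"`, `"vb"` or `"mle"`.
#' @param estimate names of free parameters (rest fixed at the prior mean).
#' @param seed RNG seed.
#' @param ... further arguments passed to [sample_posterior_mcmc()],
#'   [fit_variational()] or [fit_mle()].
#' @return object of class `td_fit` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `simulate` and `residuals` methods.
#' @export
#' @examples
#' \donttest{
#' doses <- daily_doses(113, 56)
#' truth <- pk_params(4.2, 3.8, 39.4, 15.11, 0.08)
#' tr <- simulate_pk(truth, doses, c(0, 14, 28, 42, 56))
#' pat <- measurement_series("P01", c(14, 28, 42, 56), tr$x_m[-1] + 5, doses)
#' fit <- td_fit(pat, n_draws = 500, seed = 7)
#' coef(fit)["k_cm"]
#' }
td_fit <- function(data, prior = default_prior(),
                   method = c("mcmc", "vb", "mle"),
                   estimate = NULL, seed = 1, ...) {
  method <- match.arg(method)
  stopifnot(inherits(data, "measurement_series"))
  if (is.null(estimate)) estimate <- .ALL_NAMES
  res <- switch(method,
    mcmc = sample_posterior_mcmc(data, prior, seed = seed,
                                 estimate = estimate, ...),
    vb = fit_variational(data, prior, seed = seed, estimate = estimate, ...),
    mle = fit_mle(data, seed = seed, estimate = estimate, ...))
  post <- if (method == "mle") NULL else res
  mle <- if (method == "mle") res else NULL
  structure(list(data = data, prior = prior, method = method,
                 posterior = post, mle = mle, estimate = estimate,
                 seed = seed, call = match.call()),
            class = "td_fit")
}

#' @export
print.td_fit <- function(x, ...) {
  cat(sprintf("6-MP model fit (%s) for patient %s, %d observation(s)\n",
              x$method, x$data$patient_id, length(x$data$y)))
  print(signif(coef(x), 4))
  invisible(x)
}

#' @export
coef.td_fit <- function(object, ...) {
  if (object$method == "mle") object$mle$theta
  else posterior_mean(object$posterior)
}

#' @export
summary.td_fit <- function(object, level = 0.95, ...) {
  if (object$method == "mle") {
    out <- list(coefficients = object$mle$theta, logLik = object$mle$logLik,
                method = "mle")
  } else {
    post <- object$posterior
    ci <- t(apply(post$draws, 2, hpd_interval, level = level))
    out <- list(coefficients = cbind(mean = posterior_mean(post),
                                     sd = posterior_sd(post),
                                     lower = ci[, 1], upper = ci[, 2]),
                diagnostics = post$diagnostics, method = object$method,
                level = level)
  }
  class(out) <- "summary.td_fit"
  out
}

#' @export
print.summary.td_fit <- function(x, ...) {
  cat(sprintf("method: %s\n", x$method))
  print(signif(x$coefficients, 4))
  if (!is.null(x$diagnostics$acceptance))
    cat(sprintf("MCMC acceptance %.2f, max split-Rhat %.3f\n",
                x$diagnostics$acceptance, max(x$diagnostics$rhat)))
  invisible(x)
}

#' @export
predict.td_fit <- function(object, times = NULL, doses = NULL,
                           interval = c("none", "band"), level = 0.95,
                           seed = 1, ...) {
  interval <- match.arg(interval)
  if (is.null(doses)) doses <- object$data$doses
  if (is.null(times))
    times <- seq(0, max(object$data$times, doses$times), length.out = 101)
  th <- coef(object)
  tr <- simulate_pk(as_pk_params(th), doses, times)
  if (interval == "none")
    return(data.frame(time = times, x_m = tr$x_m))
  if (is.null(object$posterior))
    stop("interval bands require a Bayesian fit")
  band <- predictive_band(object$posterior, doses, times, level = level,
                          seed = seed)
  band$fit <- tr$x_m
  band
}

#' @export
residuals.td_fit <- function(object, ...) {
  th <- coef(object)
  yhat <- predict_series(object$data, as_pk_params(th))
  setNames(object$data$y - yhat, object$data$times)
}

#' @export
simulate.td_fit <- function(object, nsim = 1, seed = NULL, times = NULL,
                            ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$posterior)) stop("simulate requires a Bayesian fit")
  if (is.null(times)) times <- sort(unique(c(0, object$data$times)))
  draws <- sample_prior(object$posterior, nsim)
  out <- sapply(seq_len(nsim), function(k) {
    th <- draws[k, ]
    yh <- simulate_pk(as_pk_params(th), object$data$doses, times)$x_m
    sig <- th[["sigma_add"]] + th[["sigma_prop"]] * yh
    yh + rnorm(length(yh), 0, pmax(sig, 0))
  })
  data.frame(time = times, as.data.frame(out))
}

#' @export
plot.td_fit <- function(x, level = 0.95, ...) {
  doses <- x$data$doses
  times <- seq(0, max(x$data$times), length.out = 101)
  if (!is.null(x$posterior)) {
    band <- predictive_band(x$posterior, doses, times, level = level)
    plot(NA, xlim = range(times), ylim = range(c(band$lower, band$upper,
                                                 x$data$y)),
         xlab = "time (days)", ylab = "6-TGN (pmol/8e8 RBCs)",
         main = sprintf("patient %s", x$data$patient_id), ...)
    graphics::polygon(c(times, rev(times)), c(band$lower, rev(band$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(times, band$mean, col = "steelblue4")
  } else {
    pr <- predict(x, times = times)
    plot(pr$time, pr$x_m, type = "l", xlab = "time (days)",
         ylab = "6-TGN (pmol/8e8 RBCs)", ...)
  }
  graphics::points(x$data$times, x$data$y, pch = 19)
  invisible(x)
}
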