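# Gaussian variational approximation by direct ELBO maximization.
#
# The family is a full-covariance Gaussian on the log-parameter scale.
# Optimization is stochastic: reparameterized draws x = m + D C z with a
# fixed correlation factor C (from a Laplace initialisation), free mean m and
# free log-scales s (D = diag(exp(s))). Gradients use the pathwise estimator
# with one-sided finite differences of the log-posterior, common random
# numbers per step, and Adam updates.

#' Gaussian variational approximation of an arbitrary log-density
#'
#' Maximizes the evidence lower bound
#' `L(q) = E_q[log p(x)] + H(q)` over Gaussians `q = N(m, Sigma)`.
#' `Sigma` is parameterized as `D C C' D` with `C` the (fixed) Cholesky-based
#' correlation factor of `init_cov` and `D` a free diagonal scale, so the
#' optimized family is full-covariance with the initial correlation
#' structure. The achieved bound satisfies `L(q) <= log integral p(x) dx`.
#'
#' @param logpost function: numeric vector -> unnormalized log density.
#' @param init_mean,init_cov initial Gaussian (e.g. a Laplace fit).
#' @param n_mc Monte Carlo draws per gradient step.
#' @param n_iter Adam steps.
#' @param lr Adam learning rate.
#' @param n_final draws for the final ELBO estimate.
#' @param seed RNG seed.
#' @return list with `mean`, `cov`, `elbo`, `converged`, `trace`.
#' @export
vb_gaussian <- function(logpost, init_mean, init_cov, n_mc = 8, n_iter = 80,
                        lr = 0.08, n_final = 200, seed = 1) {
  d <- length(init_mean)
  set.seed(seed)
  S0 <- nearest_psd(init_cov)
  sd0 <- sqrt(diag(S0))
  Ccor <- t(chol(nearest_psd(stats::cov2cor(S0))))
  m <- as.numeric(init_mean)
  s <- log(sd0)
  # Adam state
  mom1 <- numeric(2 * d); mom2 <- numeric(2 * d)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  h <- 1e-5
  elbo_step <- function(m, s, Z) {
    # returns list(elbo_datafit, grad_m, grad_s) for one batch of draws
    D <- exp(s)
    gm <- numeric(d); gs <- numeric(d); ef <- 0
    for (k in seq_len(nrow(Z))) {
      cz <- as.numeric(Ccor %*% Z[k, ])
      x <- m + D * cz
      f0 <- logpost(x)
      if (!is.finite(f0)) { ef <- ef - 1e6; next }
      g <- numeric(d)
      for (j in seq_len(d)) {
        fj <- logpost(x + h * (abs(x[j]) + 1) * (seq_len(d) == j))
        g[j] <- if (is.finite(fj)) (fj - f0) / (h * (abs(x[j]) + 1)) else 0
      }
      ef <- ef + f0
      gm <- gm + g
      gs <- gs + g * D * cz
    }
    n <- nrow(Z)
    list(ef = ef / n, gm = gm / n, gs = gs / n + 1)  # +1: entropy gradient
  }
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    Z <- matrix(rnorm(n_mc * d), n_mc, d)
    st <- elbo_step(m, s, Z)
    g <- c(st$gm, st$gs)
    mom1 <- b1 * mom1 + (1 - b1) * g
    mom2 <- b2 * mom2 + (1 - b2) * g^2
    step <- lr * (mom1 / (1 - b1^it)) / (sqrt(mom2 / (1 - b2^it)) + eps)
    m <- m + step[1:d]
    s <- s + step[(d + 1):(2 * d)]
    trace[it] <- st$ef + sum(s) + 0.5 * d * log(2 * pi * exp(1)) +
      sum(log(diag(Ccor)))
  }
  D <- exp(s)
  L <- D * Ccor
  Sigma <- tcrossprod(L)
  # final ELBO with a larger sample
  Z <- matrix(rnorm(n_final * d), n_final, d)
  ef <- mean(apply(Z, 1, function(z) {
    v <- logpost(m + as.numeric(L %*% z)); if (is.finite(v)) v else -1e6
  }))
  entropy <- 0.5 * d * log(2 * pi * exp(1)) + sum(log(diag(L)))
  tail_tr <- tail(trace, 10)
  converged <- n_iter >= 20 &&
    abs(mean(tail_tr) - mean(trace[(n_iter - 19):(n_iter - 10)])) <
      0.05 * (abs(mean(tail_tr)) + 1)
  list(mean = setNames(m, names(init_mean)), cov = Sigma,
       elbo = ef + entropy, converged = converged, trace = trace)
}

#' Variational posterior for one patient
#'
#' Laplace initialisation (posterior mode and curvature on the log scale)
#' followed by stochastic ELBO maximization with [vb_gaussian()]. The
#' resulting Gaussian lives on the log-parameter scale; returned draws are on
#' the natural scale so that first and second moments can be compared
#' directly with [sample_posterior_mcmc()] output — the package's (and the
#' study design's) verification route for the variational approximation.
#'
#' @inheritParams sample_posterior_mcmc
#' @param n_mc,n_iter,lr settings passed to [vb_gaussian()].
#' @param n_draws draws returned from the fitted Gaussian.
#' @return a [posterior_samples()]; the fitted approximation (variational
#'   mean/covariance on the log scale and achieved bound) is attached as
#'   attribute `vb`.
#' @export
fit_variational <- function(data, prior, n_draws = 2000, seed = 1,
                            estimate = .ALL_NAMES, fixed = NULL,
                            n_mc = 8, n_iter = 80, lr = 0.08,
                            rtol = 1e-6, atol = 1e-8) {
  pm <- prior_moments(prior)
  if (is.null(fixed)) fixed <- pm$mean
  lp <- make_logpost(data, prior, estimate = estimate, fixed = fixed,
                     rtol = rtol, atol = atol)
  init <- pm$log_mean[estimate]
  # Laplace initialisation: MAP + curvature
  map <- try(optim(init, function(x) -lp(x), method = "BFGS",
                   control = list(maxit = 200)), silent = TRUE)
  if (!inherits(map, "try-error") && is.finite(map$value)) {
    mu0 <- map$par
    H <- try(stats::optimHess(mu0, function(x) -lp(x)), silent = TRUE)
    S0 <- if (!inherits(H, "try-error"))
      tryCatch(solve(nearest_psd(H)), error = function(e) NULL) else NULL
    if (is.null(S0) || any(!is.finite(S0)))
      S0 <- pm$log_cov[estimate, estimate, drop = FALSE]
  } else {
    mu0 <- init
    S0 <- pm$log_cov[estimate, estimate, drop = FALSE]
  }
  S0 <- nearest_psd(S0)
  fit <- vb_gaussian(lp, mu0, S0, n_mc = n_mc, n_iter = n_iter, lr = lr,
                     seed = seed)
  set.seed(seed + 1L)
  z <- MASS::mvrnorm(n_draws, fit$mean, fit$cov)
  if (n_draws == 1L) z <- matrix(z, nrow = 1)
  colnames(z) <- estimate
  full <- matrix(rep(fixed[.ALL_NAMES], each = n_draws),
                 ncol = 7, dimnames = list(NULL, .ALL_NAMES))
  full[, estimate] <- exp(z)
  out <- posterior_samples(full, provenance = "patient",
                           diagnostics = list(converged = fit$converged,
                                              elbo = fit$elbo))
  attr(out, "vb") <- fit
  out
}
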