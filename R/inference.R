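# Per-patient likelihood, priors, MLE, MCMC and variational posteriors.
#
# All inference runs on log-parameters: the seven quantities
# (k_ab, k_el, k_cm, K, k_me, sigma_add, sigma_prop) are positive, and the
# lognormal population prior is exactly Gaussian on that scale.

#' Residual error model
#'
#' Heteroscedastic measurement error for 6-TGN observations: the standard
#' deviation at a predicted concentration `yhat` is
#' `sigma_add + sigma_prop * yhat` (additive plus proportional components,
#' the standard PK error model).
#'
#' @param sigma_add additive SD, pmol/8e8 RBCs.
#' @param sigma_prop proportional SD, dimensionless.
#' @return object of class `error_params`.
#' @export
error_params <- function(sigma_add, sigma_prop) {
  if (sigma_add < 0 || sigma_prop < 0 || (sigma_add == 0 && sigma_prop == 0))
    stop("error SDs must be >= 0 and not both zero")
  structure(list(sigma_add = sigma_add, sigma_prop = sigma_prop),
            class = "error_params")
}

#' Sparse 6-TGN measurement series for one patient
#'
#' @param patient_id identifier.
#' @param times observation times, days (sorted).
#' @param y observed 6-TGN, pmol/8e8 RBCs (non-negative).
#' @param doses the patient's [dose_schedule()].
#' @param activity optional [tpmt_activity()].
#' @return object of class `measurement_series`.
#' @export
measurement_series <- function(patient_id, times, y, doses, activity = NULL) {
  if (length(times) < 1L || length(times) != length(y))
    stop("need at least one observation; times and y must match")
  if (is.unsorted(times)) stop("observation times must be sorted")
  if (any(y < 0)) stop("observed concentrations must be non-negative")
  stopifnot(inherits(doses, "dose_schedule"))
  structure(list(patient_id = patient_id, times = times, y = y,
                 doses = doses, activity = activity),
            class = "measurement_series")
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("patient %s: %d observation(s) over days %.4g-%.4g\n",
              x$patient_id, length(x$y), min(x$times), max(x$times)))
  invisible(x)
}

# model prediction at the observation times
predict_series <- function(data, params, rtol = 1e-8, atol = 1e-10) {
  simulate_pk(params, data$doses, times = sort(unique(c(0, data$times))),
              rtol = rtol, atol = atol)$x_m[
    match(data$times, sort(unique(c(0, data$times))))]
}

#' Gaussian log-likelihood of a measurement series
#'
#' Sum over observations of the normal log-density with mean given by the
#' simulated 6-TGN concentration and SD `sigma_add + sigma_prop * yhat`.
#'
#' @param data a [measurement_series()].
#' @param params a [pk_params()].
#' @param err an [error_params()].
#' @param rtol,atol integration tolerances used for the model prediction.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(data, params, err, rtol = 1e-8, atol = 1e-10) {
  yhat <- predict_series(data, params, rtol = rtol, atol = atol)
  if (any(!is.finite(yhat)))
    stop("non-finite model prediction in log_likelihood")
  sig <- err$sigma_add + err$sigma_prop * yhat
  if (any(sig <= 0)) stop("non-positive residual SD")
  sum(dnorm(data$y, mean = yhat, sd = sig, log = TRUE))
}

# ---- priors ------------------------------------------------------------

# Gaussian log-density via Cholesky
dmvnorm_log <- function(x, mean, cov) {
  L <- chol(cov)
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(L))) - 0.5 * length(x) * log(2 * pi)
}

#' Moment-matched lognormal prior
#'
#' Given a mean vector and covariance on the natural parameter scale,
#' constructs the multivariate lognormal with those first two moments:
#' `mu_log = log(m) - diag(S_log)/2`, `S_log[i,j] = log(1 + C[i,j]/(m_i m_j))`.
#' The density is Gaussian on the log scale, where all sampling runs.
#'
#' @param mean named mean vector on the natural scale (subset of the seven
#'   canonical parameters; see Details).
#' @param cov covariance matrix on the natural scale (same order as `mean`).
#' @return object of class `td_prior` with fields `log_mean`, `log_cov`,
#'   `mean`, `cov`.
#' @export
lognormal_prior <- function(mean, cov) {
  m <- as.numeric(mean); nm <- names(mean)
  if (is.null(nm)) stop("mean must be named")
  C <- as.matrix(cov)
  if (any(m <= 0)) stop("lognormal moment matching needs positive means")
  S_log <- log(1 + C / tcrossprod(m))
  if (any(!is.finite(S_log))) stop("covariance incompatible with positive means")
  S_log <- nearest_psd(S_log)
  mu_log <- log(m) - diag(S_log) / 2
  structure(list(log_mean = setNames(mu_log, nm), log_cov = S_log,
                 mean = setNames(m, nm), cov = C, names = nm),
            class = "td_prior")
}

# smallest symmetric PSD repair (eigenvalue clipping)
nearest_psd <- function(S, eps = 1e-10) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) > eps) return(S)
  v <- pmax(e$values, eps * max(abs(e$values)))
  e$vectors %*% (v * t(e$vectors))
}

#' Log prior density on the log-parameter scale
#' @param prior a prior object (`td_prior`, `population_prior`, or
#'   `posterior_samples` carrying a Gaussian log-scale approximation).
#' @param log_theta named log-parameter vector.
#' @export
prior_logpdf <- function(prior, log_theta) UseMethod("prior_logpdf")

#' @export
prior_logpdf.td_prior <- function(prior, log_theta) {
  nm <- prior$names
  dmvnorm_log(log_theta[nm], prior$log_mean[nm], prior$log_cov)
}

#' Draw parameters from a prior (natural scale)
#' @param prior a prior object.
#' @param n number of draws.
#' @export
sample_prior <- function(prior, n) UseMethod("sample_prior")

#' @export
sample_prior.td_prior <- function(prior, n) {
  z <- MASS::mvrnorm(n, prior$log_mean, prior$log_cov)
  if (n == 1L) z <- matrix(z, nrow = 1, dimnames = list(NULL, prior$names))
  exp(z)
}

# marginal quantile on the natural scale (lognormal marginal)
prior_marginal_quantile <- function(prior, name, p) {
  i <- match(name, prior$names)
  qlnorm(p, meanlog = prior$log_mean[i], sdlog = sqrt(prior$log_cov[i, i]))
}

#' Default joint prior over model and error parameters
#'
#' Combines natural-scale kinetic statistics (see [population_stats()]) with a
#' weak lognormal prior on the residual-error parameters
#' (`sigma_add`: mean 10, SD 5; `sigma_prop`: mean 0.05, SD 0.03).
#'
#' @param stats a [population_stats()] for the five kinetic parameters.
#' @param err_mean,err_sd length-2 mean/SD for `(sigma_add, sigma_prop)`.
#' @export
default_prior <- function(stats = population_stats(),
                          err_mean = c(10, 0.05), err_sd = c(5, 0.03)) {
  m <- c(stats$mean, setNames(err_mean, .ERR_NAMES))
  C <- matrix(0, 7, 7, dimnames = list(.ALL_NAMES, .ALL_NAMES))
  C[1:5, 1:5] <- stats$cov
  C[6, 6] <- err_sd[1]^2
  C[7, 7] <- err_sd[2]^2
  lognormal_prior(m, C)
}

# ---- posterior containers ---------------------------------------------

#' Weighted posterior draws over (theta, xi)
#'
#' @param draws matrix of positive draws, one row per draw, columns named
#'   among the seven canonical parameters.
#' @param weights non-negative weights (normalized internally).
#' @param provenance `"patient"`, `"population"` or `"group"`.
#' @param diagnostics optional list (acceptance rate, split-Rhat, ...).
#' @export
posterior_samples <- function(draws, weights = NULL,
                              provenance = c("patient", "population", "group"),
                              diagnostics = list()) {
  provenance <- match.arg(provenance)
  draws <- as.matrix(draws)
  if (any(draws <= 0)) stop("parameter draws must be positive")
  if (is.null(weights)) weights <- rep(1, nrow(draws))
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  structure(list(draws = draws, weights = weights / sum(weights),
                 provenance = provenance, diagnostics = diagnostics),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("%s posterior: %d weighted draws over {%s}\n", x$provenance,
              nrow(x$draws), paste(colnames(x$draws), collapse = ", ")))
  invisible(x)
}

# weighted posterior moments
posterior_mean <- function(post) {
  colSums(post$draws * post$weights)
}
posterior_sd <- function(post) {
  m <- posterior_mean(post)
  sqrt(colSums(sweep(post$draws, 2, m)^2 * post$weights))
}

#' @export
prior_logpdf.posterior_samples <- function(prior, log_theta) {
  ap <- attr(prior, "log_approx")
  if (is.null(ap)) {
    lw <- log(prior$draws)
    ap <- list(mean = colSums(lw * prior$weights),
               cov = nearest_psd(stats::cov.wt(lw, wt = prior$weights)$cov))
  }
  nm <- names(ap$mean)
  dmvnorm_log(log_theta[nm], ap$mean, ap$cov[nm, nm])
}

#' @export
sample_prior.posterior_samples <- function(prior, n) {
  idx <- sample.int(nrow(prior$draws), n, replace = TRUE, prob = prior$weights)
  prior$draws[idx, , drop = FALSE]
}

# ---- log-posterior assembly -------------------------------------------

# returns function(log_theta_est) -> unnormalized log posterior, where
# `estimate` names the free parameters and `fixed` holds the rest on the
# natural scale.
make_logpost <- function(data, prior, estimate = .ALL_NAMES, fixed = NULL,
                         rtol = 1e-6, atol = 1e-8) {
  if (inherits(prior, "posterior_samples") &&
      is.null(attr(prior, "log_approx"))) {
    pm <- prior_moments(prior)
    attr(prior, "log_approx") <- list(mean = pm$log_mean, cov = pm$log_cov)
  }
  full <- setNames(numeric(length(.ALL_NAMES)), .ALL_NAMES)
  if (!is.null(fixed)) full[names(fixed)] <- fixed
  # trim to +/- 6 prior log-SDs: negligible prior mass outside, and keeps
  # the stiff solver away from absurd rate constants
  pm <- prior_moments(prior)
  lt_lo <- (pm$log_mean - 6 * sqrt(diag(pm$log_cov)))[estimate]
  lt_hi <- (pm$log_mean + 6 * sqrt(diag(pm$log_cov)))[estimate]
  function(lt) {
    if (any(lt < lt_lo) || any(lt > lt_hi)) return(-Inf)
    th <- full
    th[estimate] <- exp(lt)
    if (any(!is.finite(th)) || any(th[.PK_NAMES] <= 0)) return(-Inf)
    lth <- log(th)
    lp <- tryCatch(prior_logpdf(prior, lth), error = function(e) -Inf)
    if (!is.finite(lp)) return(-Inf)
    ll <- tryCatch({
      par <- as_pk_params(th)
      er <- error_params(th[["sigma_add"]], th[["sigma_prop"]])
      log_likelihood(data, par, er, rtol = rtol, atol = atol)
    }, error = function(e) -Inf)
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }
}

# ---- maximum likelihood -----------------------------------------------

#' Default box constraints for estimation (natural scale)
#' @export
default_bounds <- function() {
  list(lower = c(k_ab = 0.1, k_el = 0.1, k_cm = 1, K = 0.5, k_me = 0.005,
                 sigma_add = 0.1, sigma_prop = 1e-4),
       upper = c(k_ab = 50, k_el = 50, k_cm = 500, K = 200, k_me = 2,
                 sigma_add = 100, sigma_prop = 1))
}

#' Maximum-likelihood estimation for one patient
#'
#' Box-constrained multi-start maximization of [log_likelihood()] on the log
#' scale (`optim` L-BFGS-B). With fewer observations than free parameters the
#' problem is underdetermined: a warning is issued and all parameters except
#' `estimate_sparse` are fixed at `nominal`.
#'
#' @param data a [measurement_series()].
#' @param bounds list with named `lower`/`upper` vectors (natural scale).
#' @param n_starts number of random multi-starts (plus the box centre).
#' @param seed RNG seed for the starts.
#' @param nominal named nominal values used when fixing parameters.
#' @param estimate names of free parameters.
#' @param estimate_sparse fallback free set for underdetermined data.
#' @return list with `params` ([pk_params()]), `err` ([error_params()]),
#'   `logLik`, `estimate`, `theta` (full named vector).
#' @export
fit_mle <- function(data, bounds = default_bounds(), n_starts = 5, seed = 1,
                    nominal = NULL, estimate = .ALL_NAMES,
                    estimate_sparse = c("k_cm", "sigma_add")) {
  if (is.null(nominal))
    nominal <- c(population_stats()$mean, sigma_add = 10, sigma_prop = 0.05)
  if (length(data$y) < 2L) {
    warning("fewer than 2 observations: fixing insensitive parameters at nominal values")
    estimate <- intersect(estimate, estimate_sparse)
  } else if (length(data$y) < length(estimate)) {
    warning("fewer observations than free parameters: fixing insensitive parameters at nominal values")
    estimate <- intersect(estimate, estimate_sparse)
  }
  lo <- log(bounds$lower[estimate]); hi <- log(bounds$upper[estimate])
  full <- nominal[.ALL_NAMES]; names(full) <- .ALL_NAMES
  obj <- function(lt) {
    th <- full; th[estimate] <- exp(lt)
    -tryCatch(log_likelihood(data, as_pk_params(th),
                             error_params(th[["sigma_add"]], th[["sigma_prop"]]),
                             rtol = 1e-6, atol = 1e-8),
              error = function(e) -Inf)
  }
  set.seed(seed)
  starts <- rbind((lo + hi) / 2,
                  matrix(runif(n_starts * length(estimate), lo, hi),
                         ncol = length(estimate), byrow = TRUE))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- try(optim(starts[k, ], obj, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(maxit = 300)), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("MLE failed from all starts")
  th <- full; th[estimate] <- exp(best$par)
  list(params = as_pk_params(th),
       err = error_params(th[["sigma_add"]], th[["sigma_prop"]]),
       logLik = -best$value, estimate = estimate, theta = th)
}

# ---- Metropolis-Hastings engine ---------------------------------------

#' Adaptive random-walk Metropolis-Hastings sampler
#'
#' Generic engine used by [sample_posterior_mcmc()]: Gaussian random-walk
#' proposals whose global scale adapts toward a 30% acceptance rate during
#' burn-in, multiple chains, split-Rhat convergence diagnostic.
#'
#' @param logpost function of a numeric vector returning the unnormalized log
#'   posterior density.
#' @param init named initial vector (one chain start; chains are jittered).
#' @param n_iter iterations per chain (including burn-in).
#' @param n_chains number of chains.
#' @param burn_frac fraction discarded as burn-in.
#' @param prop_cov proposal covariance shape (scaled by `2.38^2/d` and the
#'   adaptive factor).
#' @param seed RNG seed.
#' @return list with post-burn-in `draws` (all chains stacked), `acceptance`,
#'   `rhat` (per coordinate), `converged`.
#' @export
mh_sample <- function(logpost, init, n_iter = 2000, n_chains = 4,
                      burn_frac = 0.5, prop_cov = NULL, seed = 1) {
  d <- length(init)
  if (is.null(prop_cov)) prop_cov <- diag(0.05, d)
  set.seed(seed)
  Lp <- t(chol(nearest_psd(prop_cov) * 2.38^2 / d))
  n_burn <- floor(n_iter * burn_frac)
  keep <- n_iter - n_burn
  chains <- vector("list", n_chains)
  acc_tot <- 0
  for (c in seq_len(n_chains)) {
    x <- init + rnorm(d, 0, 0.05)
    lp <- logpost(x)
    tries <- 0
    while (!is.finite(lp) && tries < 50) {
      x <- init + rnorm(d, 0, 0.05); lp <- logpost(x); tries <- tries + 1
    }
    if (!is.finite(lp)) stop("could not find a finite-density start")
    log_s <- 0
    out <- matrix(NA_real_, keep, d)
    hist <- matrix(NA_real_, n_burn, d)
    Lc <- Lp
    acc <- 0
    for (i in seq_len(n_iter)) {
      prop <- x + exp(log_s) * as.numeric(Lc %*% rnorm(d))
      lpp <- logpost(prop)
      if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
        x <- prop; lp <- lpp; a <- 1
      } else a <- 0
      if (i <= n_burn) {
        log_s <- log_s + (a - 0.3) / sqrt(i)  # Robbins-Monro scale adaptation
        hist[i, ] <- x
        if (i == floor(n_burn / 2) && i > 10 * d) {
          # re-shape the proposal from the burn-in history
          Ch <- cov(hist[seq_len(i), , drop = FALSE])
          if (all(is.finite(Ch)) && min(diag(Ch)) > 0)
            Lc <- t(chol(nearest_psd(Ch) * 2.38^2 / d +
                           diag(1e-10, d)))
        }
      } else { out[i - n_burn, ] <- x; acc <- acc + a }
    }
    chains[[c]] <- out
    acc_tot <- acc_tot + acc / keep
  }
  acceptance <- acc_tot / n_chains
  if (acceptance < 0.05 || acceptance > 0.8)
    warning(sprintf("MCMC acceptance rate %.2f outside [0.05, 0.8]", acceptance))
  rhat <- split_rhat(chains)
  draws <- do.call(rbind, chains)
  colnames(draws) <- names(init)
  list(draws = draws, acceptance = acceptance, rhat = rhat,
       converged = all(is.finite(rhat)) && max(rhat) < 1.05)
}

# split-Rhat over a list of equal-length chain matrices
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch); h <- floor(n / 2)
    halves <- c(halves, list(ch[1:h, , drop = FALSE],
                             ch[(n - h + 1):n, , drop = FALSE]))
  }
  d <- ncol(halves[[1]])
  sapply(seq_len(d), function(j) {
    mns <- sapply(halves, function(h) mean(h[, j]))
    vrs <- sapply(halves, function(h) var(h[, j]))
    W <- mean(vrs); B <- var(mns) * nrow(halves[[1]])
    if (W <= 0) return(1)
    sqrt((nrow(halves[[1]]) - 1) / nrow(halves[[1]]) + B / W / nrow(halves[[1]]))
  })
}

#' Posterior sampling by Metropolis-Hastings MCMC
#'
#' Random-walk Metropolis-Hastings on log-parameters targeting
#' prior x likelihood for one patient.
#'
#' @param data a [measurement_series()].
#' @param prior a prior object (see [prior_logpdf()]).
#' @param n_draws total post-burn-in draws returned (across chains).
#' @param seed RNG seed.
#' @param n_chains,burn_frac chain settings.
#' @param estimate names of free parameters; the rest are fixed at `fixed`.
#' @param fixed named natural-scale values for non-estimated parameters
#'   (defaults to the prior mean).
#' @param rtol,atol integration tolerances inside the likelihood.
#' @return a [posterior_samples()] with MCMC diagnostics attached.
#' @export
sample_posterior_mcmc <- function(data, prior, n_draws = 2000, seed = 1,
                                  n_chains = 4, burn_frac = 0.5,
                                  estimate = .ALL_NAMES, fixed = NULL,
                                  laplace_init = TRUE,
                                  rtol = 1e-6, atol = 1e-8) {
  stopifnot(n_draws > 0)
  pm <- prior_moments(prior)
  if (is.null(fixed)) fixed <- pm$mean
  lp <- make_logpost(data, prior, estimate = estimate, fixed = fixed,
                     rtol = rtol, atol = atol)
  init <- pm$log_mean[estimate]
  pc <- pm$log_cov[estimate, estimate, drop = FALSE]
  if (laplace_init) {
    # posterior mode and curvature make a far better start/proposal shape
    # than the prior, at the cost of a few hundred extra evaluations
    map <- try(optim(init, function(x) -lp(x), method = "BFGS",
                     control = list(maxit = 150)), silent = TRUE)
    if (!inherits(map, "try-error") && is.finite(map$value)) {
      init <- map$par
      H <- try(stats::optimHess(init, function(x) -lp(x)), silent = TRUE)
      if (!inherits(H, "try-error")) {
        S <- tryCatch(solve(nearest_psd(H)), error = function(e) NULL)
        if (!is.null(S) && all(is.finite(S))) pc <- nearest_psd(S)
      }
    }
  }
  n_iter <- ceiling(n_draws / n_chains / (1 - burn_frac))
  res <- mh_sample(lp, init, n_iter = n_iter, n_chains = n_chains,
                   burn_frac = burn_frac, prop_cov = pc, seed = seed)
  full <- matrix(rep(fixed[.ALL_NAMES], each = nrow(res$draws)),
                 ncol = 7, dimnames = list(NULL, .ALL_NAMES))
  full[, estimate] <- exp(res$draws)
  posterior_samples(full, provenance = "patient",
                    diagnostics = res[c("acceptance", "rhat", "converged")])
}

# log-scale and natural-scale first two moments of any prior object
prior_moments <- function(prior) {
  if (inherits(prior, "td_prior"))
    return(list(mean = prior$mean, log_mean = prior$log_mean,
                log_cov = prior$log_cov))
  if (inherits(prior, "population_prior"))
    return(list(mean = prior$mean, log_mean = prior$log_mean,
                log_cov = prior$log_cov))
  if (inherits(prior, "posterior_samples")) {
    lw <- log(prior$draws)
    cw <- stats::cov.wt(lw, wt = prior$weights)
    return(list(mean = posterior_mean(prior), log_mean = cw$center,
                log_cov = nearest_psd(cw$cov)))
  }
  stop("unsupported prior object")
}
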