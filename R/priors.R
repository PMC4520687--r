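# Pooled population prior and TPMT-activity group priors: mixtures of
# individual patient posteriors weighted by data quantity, with a
# multivariate-normal approximation (on the log scale) for density
# evaluation as a prior in later fits.

#' Pooled population prior from patient posteriors
#'
#' Forms the mixture `M(theta, xi) = sum_i w_i p_i(theta, xi | D_i)` with
#' weights proportional to each patient's number of data points, pools
#' `draws_per_point * n_i` resampled draws per patient, and fits a
#' multivariate normal approximation to the pooled draws (Gaussian on the
#' log scale, used when the object serves as a prior density; natural-scale
#' moments are also recorded).
#'
#' @param posteriors list of [posterior_samples()].
#' @param n_points integer vector: data points per patient (mixture weights
#'   are `n_i / sum(n)`).
#' @param draws_per_point pooled draws contributed per data point.
#' @param seed RNG seed for the resampling.
#' @return object of class `population_prior` with fields `components`,
#'   `weights`, `draws` (pooled, natural scale), `mean`, `cov` (natural),
#'   `log_mean`, `log_cov` (MVN approximation).
#' @export
build_population_prior <- function(posteriors, n_points,
                                   draws_per_point = 2000, seed = 1) {
  if (length(posteriors) < 1L) stop("need at least one posterior")
  if (length(n_points) != length(posteriors) || any(n_points <= 0))
    stop("n_points must be positive, one per posterior")
  for (p in posteriors)
    if (!inherits(p, "posterior_samples") || nrow(p$draws) == 0)
      stop("empty or invalid posterior")
  set.seed(seed)
  w <- n_points / sum(n_points)
  pooled <- do.call(rbind, lapply(seq_along(posteriors), function(i) {
    p <- posteriors[[i]]
    idx <- sample.int(nrow(p$draws), draws_per_point * n_points[i],
                      replace = TRUE, prob = p$weights)
    p$draws[idx, , drop = FALSE]
  }))
  lw <- log(pooled)
  structure(list(components = posteriors, weights = w,
                 n_points = n_points,
                 draws = pooled,
                 mean = colMeans(pooled), cov = cov(pooled),
                 log_mean = colMeans(lw),
                 log_cov = nearest_psd(cov(lw))),
            class = "population_prior")
}

#' @export
print.population_prior <- function(x, ...) {
  cat(sprintf("population prior: %d component(s), weights %s\n",
              length(x$components),
              paste(signif(x$weights, 3), collapse = "/")))
  cat("pooled means:\n"); print(signif(x$mean, 4))
  invisible(x)
}

#' @export
prior_logpdf.population_prior <- function(prior, log_theta) {
  nm <- names(prior$log_mean)
  dmvnorm_log(log_theta[nm], prior$log_mean, prior$log_cov[nm, nm])
}

#' @export
sample_prior.population_prior <- function(prior, n) {
  prior$draws[sample.int(nrow(prior$draws), n, replace = TRUE), ,
              drop = FALSE]
}

#' TPMT-activity group prior
#'
#' Restricts the population mixture to patients whose TPMT activity falls in
#' the half-open window `(lo, hi]`, with the same data-quantity weighting as
#' [build_population_prior()]. Returns the pooled group draws as a
#' [posterior_samples()] object (provenance `"group"`) carrying a Gaussian
#' log-scale approximation so it can serve directly as a prior.
#'
#' @param posteriors list of [posterior_samples()], one per patient.
#' @param activities numeric TPMT activities (U/ml/hr), one per patient.
#' @param window length-2 numeric `(lo, hi]`.
#' @param n_points data points per patient (default 1 each).
#' @param draws_per_point pooled draws per data point.
#' @param seed RNG seed.
#' @export
build_group_prior <- function(posteriors, activities, window,
                              n_points = rep(1L, length(posteriors)),
                              draws_per_point = 2000, seed = 1) {
  stopifnot(length(activities) == length(posteriors), length(window) == 2L)
  inside <- activities > window[1] & activities <= window[2]
  if (!any(inside))
    stop(sprintf("empty group: no patient with activity in (%g, %g]",
                 window[1], window[2]))
  set.seed(seed)
  idx <- which(inside)
  w <- n_points[idx] / sum(n_points[idx])
  pooled <- do.call(rbind, lapply(idx, function(i) {
    p <- posteriors[[i]]
    k <- sample.int(nrow(p$draws), draws_per_point * n_points[i],
                    replace = TRUE, prob = p$weights)
    p$draws[k, , drop = FALSE]
  }))
  out <- posterior_samples(pooled, provenance = "group")
  lw <- log(pooled)
  attr(out, "log_approx") <- list(mean = colMeans(lw),
                                  cov = nearest_psd(cov(lw)))
  attr(out, "members") <- idx
  attr(out, "weights_by_member") <- w
  attr(out, "window") <- window
  out
}
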