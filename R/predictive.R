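# Posterior-predictive concentration bands (highest-density intervals) and
# the global lack-of-fit test based on band coverage.

#' Shortest (highest-density) interval from samples
#'
#' For a unimodal scalar predictive the 100*level% HPD interval is the
#' shortest window containing `ceiling(level * n)` of the sorted samples.
#'
#' @param x numeric samples.
#' @param level probability content in (0, 1].
#' @return length-2 numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, level = 0.95) {
  stopifnot(level > 0, level <= 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) stop("no finite samples")
  m <- ceiling(level * n)
  if (m >= n) return(c(x[1], x[n]))
  i <- which.min(x[(m):n] - x[1:(n - m + 1)])
  c(x[i], x[i + m - 1])
}

#' Posterior-predictive HPD band for 6-TGN concentration
#'
#' Simulates one trajectory per posterior draw under the given dosing
#' schedule, adds measurement noise from the draw's own error parameters,
#' and returns the per-time highest-density interval of the predictive
#' distribution.
#'
#' @param post a [posterior_samples()] (or `population_prior`).
#' @param doses a [dose_schedule()].
#' @param times evaluation times, days.
#' @param level band probability content.
#' @param n_sim number of draws used (weighted resampling); default all
#'   draws up to 500.
#' @param noise include measurement noise (predictive band) or not
#'   (trajectory credible band).
#' @param seed RNG seed.
#' @param rtol,atol integration tolerances.
#' @return data.frame `time, lower, upper, mean` of class `predictive_band`.
#' @export
predictive_band <- function(post, doses, times, level = 0.95, n_sim = NULL,
                            noise = TRUE, seed = 1, rtol = 1e-6, atol = 1e-8) {
  stopifnot(level > 0, level <= 1)
  draws <- if (inherits(post, "population_prior")) post$draws else post$draws
  wts <- if (inherits(post, "population_prior"))
    rep(1 / nrow(draws), nrow(draws)) else post$weights
  set.seed(seed)
  if (is.null(n_sim)) n_sim <- min(nrow(draws), 500L)
  if (n_sim < 100) warning("fewer than 100 draws for predictive band")
  idx <- if (n_sim == nrow(draws) && all(abs(wts - wts[1]) < 1e-12))
    seq_len(n_sim)
  else sample.int(nrow(draws), n_sim, replace = TRUE, prob = wts)
  sims <- matrix(NA_real_, n_sim, length(times))
  for (k in seq_len(n_sim)) {
    th <- draws[idx[k], ]
    tr <- simulate_pk(as_pk_params(th), doses,
                      times = sort(unique(c(0, times))),
                      rtol = rtol, atol = atol)
    yh <- tr$x_m[match(times, tr$time)]
    if (noise) {
      sig <- th[["sigma_add"]] + th[["sigma_prop"]] * yh
      yh <- yh + rnorm(length(yh), 0, pmax(sig, 0))
    }
    sims[k, ] <- yh
  }
  band <- t(apply(sims, 2, hpd_interval, level = level))
  out <- data.frame(time = times, lower = band[, 1], upper = band[, 2],
                    mean = colMeans(sims))
  class(out) <- c("predictive_band", "data.frame")
  out
}

# average band width (used for the uncertainty-nesting checks)
band_width <- function(band) mean(band$upper - band$lower)

#' Global lack-of-fit test from band coverage
#'
#' Counts observations inside a 100*(1-alpha)% predictive band and computes
#' a one-sided binomial tail on the outside count: `confidence =
#' P(Binom(n, alpha) < n_outside)`. Small confidence (the observed misses
#' are no more than chance at miss rate `alpha`) indicates an adequate
#' model; the adequacy criterion used here is `confidence < 0.05`. The tail
#' convention is documented in the methods vignette.
#'
#' @param y observed concentrations.
#' @param band a [predictive_band()] evaluated at the observation times.
#' @param alpha nominal miss rate of the band (1 - level).
#' @return list `n_inside`, `n_total`, `confidence`, `adequate`.
#' @export
lack_of_fit <- function(y, band, alpha = 0.05) {
  stopifnot(length(y) == nrow(band))
  inside <- y >= band$lower & y <= band$upper
  n_out <- sum(!inside)
  conf <- if (n_out == 0) 0 else pbinom(n_out - 1, length(y), alpha)
  list(n_inside = sum(inside), n_total = length(y),
       confidence = conf, adequate = conf < 0.05)
}
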