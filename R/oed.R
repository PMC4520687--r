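# Robust D-optimal selection of the blood-sampling day: forward sensitivity
# equations, Fisher information of the 6-TGN measurement, and the expected
# information profile over a population prior.

# analytic pieces of the model right-hand side used by the sensitivity ODEs
.pk_rhs_jac <- function(x, p) {
  denom <- (p[["K"]] + x[2])
  J <- matrix(0, 3, 3)
  J[1, 1] <- -p[["k_ab"]]
  J[2, 1] <- p[["k_ab"]]
  J[2, 2] <- -p[["k_el"]] - p[["k_cm"]] * p[["K"]] / denom^2
  J[3, 2] <- p[["nu_cm"]] * p[["k_cm"]] * p[["K"]] / denom^2
  J[3, 3] <- -p[["k_me"]]
  J
}

.pk_rhs_dtheta <- function(x, p, name) {
  denom <- (p[["K"]] + x[2])
  mm <- x[2] / denom
  switch(name,
    k_ab = c(-x[1], x[1], 0),
    k_el = c(0, -x[2], 0),
    k_cm = c(0, -mm, p[["nu_cm"]] * mm),
    K    = c(0,  p[["k_cm"]] * x[2] / denom^2,
                -p[["nu_cm"]] * p[["k_cm"]] * x[2] / denom^2),
    k_me = c(0, 0, -x[3]),
    nu_cm = c(0, 0, p[["k_cm"]] * mm),
    stop("unknown parameter: ", name))
}

#' Output sensitivities by forward sensitivity equations
#'
#' Integrates the model states together with the sensitivity states
#' `s_k = d x / d theta_k` (ODE `ds/dt = J_x s + df/dtheta`) and returns the
#' sensitivity of the observed output `x_m` at each requested time. Bolus
#' events increment `x_g` only and leave the sensitivities continuous.
#'
#' @param params a [pk_params()].
#' @param doses a [dose_schedule()].
#' @param times output times, days.
#' @param param_subset parameter names among
#'   `k_ab, k_el, k_cm, K, k_me, nu_cm`.
#' @param init initial model state.
#' @param rtol,atol integration tolerances.
#' @return list with `S` (length(times) x length(param_subset) matrix of
#'   `d x_m / d theta`), `yhat` (predicted `x_m`), `times`.
#' @export
output_sensitivities <- function(params, doses, times,
                                 param_subset = c("k_cm"),
                                 init = c(0, 0, 0),
                                 rtol = 1e-7, atol = 1e-9) {
  stopifnot(length(param_subset) >= 1)
  p <- unlist(params[c(.PK_NAMES, "nu_cm")])
  np <- length(param_subset)
  rhs <- function(t, y, parms) {
    x <- y[1:3]
    denom <- p[["K"]] + x[2]
    conv <- p[["k_cm"]] * x[2] / denom
    f <- c(-p[["k_ab"]] * x[1] + doses$infusion,
           p[["k_ab"]] * x[1] - p[["k_el"]] * x[2] - conv,
           p[["nu_cm"]] * conv - p[["k_me"]] * x[3])
    J <- .pk_rhs_jac(x, p)
    Smat <- matrix(y[-(1:3)], nrow = 3)
    dS <- J %*% Smat
    for (k in seq_len(np))
      dS[, k] <- dS[, k] + .pk_rhs_dtheta(x, p, param_subset[k])
    list(c(f, as.numeric(dS)))
  }
  ynames <- c("x_g", "x_c", "x_m",
              paste0("s", rep(1:3, np), "_", rep(seq_len(np), each = 3)))
  y0 <- setNames(c(init, numeric(3 * np)), ynames)
  t0 <- min(0, times)                 # state (and zero sensitivity) at day 0
  pre <- doses$times <= t0
  y0["x_g"] <- y0["x_g"] + sum(doses$amounts[pre])
  ev_t <- doses$times[!pre & doses$times <= max(times)]
  ev_a <- doses$amounts[!pre & doses$times <= max(times)]
  grid <- sort(unique(c(t0, times, ev_t)))
  args <- list(y = y0, times = grid, func = rhs, parms = NULL,
               rtol = rtol, atol = atol, maxsteps = 20000)
  if (length(ev_t))
    args$events <- list(data = data.frame(var = "x_g", time = ev_t,
                                          value = ev_a, method = "add"))
  out <- try(suppressWarnings(do.call(deSolve::lsoda, args)), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(grid)) {
    # retry once with relaxed tolerances before giving up
    args$rtol <- args$rtol * 100
    args$atol <- args$atol * 100
    args$maxsteps <- 100000
    out <- try(suppressWarnings(do.call(deSolve::lsoda, args)),
               silent = TRUE)
  }
  if (inherits(out, "try-error") || nrow(out) < length(grid))
    stop("integration error in output_sensitivities")
  out <- as.data.frame(out)
  rows <- match(times, out$time)
  S <- as.matrix(out[rows, paste0("s3_", seq_len(np)), drop = FALSE])
  dimnames(S) <- list(NULL, param_subset)
  list(S = S, yhat = out$x_m[rows], times = times)
}

#' Fisher information of 6-TGN measurements
#'
#' `I = sum_t sigma_t^{-2} s(t) s(t)'` with
#' `sigma_t = sigma_add + sigma_prop * yhat(t)`: symmetric positive
#' semi-definite, additive over measurements.
#'
#' @param S sensitivity matrix (rows = measurement times, columns =
#'   parameters), e.g. from [output_sensitivities()].
#' @param err an [error_params()].
#' @param predictions predicted `x_m` at the measurement times.
#' @return information matrix (p x p).
#' @export
fisher_information <- function(S, err, predictions) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == length(predictions))
  sig <- err$sigma_add + err$sigma_prop * predictions
  if (any(sig <= 0)) stop("zero or negative residual SD in fisher_information")
  crossprod(S / sig)
}

#' Expected-information profile over candidate sampling days
#'
#' For each candidate single sampling day, averages the determinant of the
#' Fisher information of that one measurement over draws from the
#' population prior (a new, data-less patient: the likelihood weighting of
#' the robust design degenerates to the prior, so draws are weighted
#' uniformly by their prior resampling weights).
#'
#' @param prior a prior object (`population_prior`, [posterior_samples()] or
#'   [lognormal_prior()] over the seven parameters).
#' @param candidate_times candidate sampling days.
#' @param doses a [dose_schedule()]; default standard daily dosing across
#'   the candidate horizon.
#' @param param_subset parameters under estimation (typically the
#'   GSA-sensitive set, e.g. `"k_cm"`).
#' @param n_draws prior draws to average over.
#' @param seed RNG seed.
#' @param rtol,atol integration tolerances.
#' @return object of class `design_result`: data.frame
#'   `day, expected_information` with the chosen settings as attributes.
#' @export
expected_information_profile <- function(prior, candidate_times = 1:100,
                                         doses = NULL,
                                         param_subset = "k_cm",
                                         n_draws = 100, seed = 1,
                                         rtol = 1e-6, atol = 1e-8) {
  stopifnot(length(candidate_times) >= 1)
  if (is.null(doses)) doses <- daily_doses(113, ceiling(max(candidate_times)))
  set.seed(seed)
  draws <- sample_prior(prior, n_draws)
  dets <- matrix(0, n_draws, length(candidate_times))
  for (k in seq_len(n_draws)) {
    th <- draws[k, ]
    pars <- as_pk_params(th)
    err <- if (all(.ERR_NAMES %in% names(th)))
      error_params(th[["sigma_add"]], th[["sigma_prop"]])
    else error_params(10, 0.05)
    sens <- output_sensitivities(pars, doses, candidate_times,
                                 param_subset = param_subset,
                                 rtol = rtol, atol = atol)
    for (j in seq_along(candidate_times)) {
      I <- fisher_information(sens$S[j, , drop = FALSE], err, sens$yhat[j])
      dets[k, j] <- det(I)
    }
  }
  out <- data.frame(day = candidate_times,
                    expected_information = colMeans(dets))
  attr(out, "param_subset") <- param_subset
  attr(out, "n_draws") <- n_draws
  class(out) <- c("design_result", "data.frame")
  out
}

#' Select the sampling day from an information profile
#'
#' Returns the earliest candidate whose expected information is within
#' `compromise_fraction` of the maximum (`fraction = 0` gives the argmax;
#' ties resolve to the earliest day). Trading a small fraction of the
#' maximum information buys a much earlier patient-specific model.
#'
#' @param profile a `design_result` from [expected_information_profile()].
#' @param compromise_fraction fraction of the maximum information given up.
#' @return chosen day `t*`.
#' @export
select_sampling_time <- function(profile, compromise_fraction = 0.05) {
  stopifnot(nrow(profile) >= 1, compromise_fraction >= 0,
            compromise_fraction < 1)
  ei <- profile$expected_information
  thr <- (1 - compromise_fraction) * max(ei)
  profile$day[which(ei >= thr - .Machine$double.eps * abs(thr))[1]]
}
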