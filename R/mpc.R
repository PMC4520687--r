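# Robust model-predictive dose control: block-constant daily 6-MP doses
# minimizing expected squared deviation of 6-TGN from the therapeutic
# target over a posterior (or group-prior) draw set, under box and slew
# constraints; receding-horizon closed loop with Bayesian re-estimation.

#' MPC configuration
#'
#' @param setpoint target 6-TGN concentration, pmol/8e8 RBCs.
#' @param window therapeutic window, pmol/8e8 RBCs.
#' @param horizon prediction horizon, days.
#' @param block control block length, days (dose is a constant daily bolus
#'   within each block; patients visit every two weeks).
#' @param n_samples posterior draws frozen per optimization
#'   (sample-average approximation).
#' @param standard_dose nominal daily dose, pmol.
#' @param u_min,u_max daily dose bounds, pmol (defaults 0 and 2.5x the
#'   standard dose, mirroring the 25-200% clinical dose spread).
#' @param du_min,du_max slew bounds per block, pmol (defaults +/- 50% of
#'   the standard dose).
#' @param reltol relative cost-change tolerance for the optimizer.
#' @param n_starts optimizer multi-starts.
#' @return object of class `control_config`.
#' @export
control_config <- function(setpoint = 300, window = c(235, 400),
                           horizon = 75, block = 15, n_samples = 50,
                           standard_dose = 113,
                           u_min = 0, u_max = 2.5 * standard_dose,
                           du_min = -0.5 * standard_dose,
                           du_max = 0.5 * standard_dose,
                           reltol = 1e-6, n_starts = 3) {
  stopifnot(u_min <= u_max, window[1] < setpoint, setpoint < window[2],
            horizon %% block == 0, du_min <= 0, du_max >= 0)
  structure(list(setpoint = setpoint, window = window, horizon = horizon,
                 block = block, n_blocks = horizon %/% block,
                 n_samples = n_samples, standard_dose = standard_dose,
                 u_min = u_min, u_max = u_max,
                 du_min = du_min, du_max = du_max,
                 reltol = reltol, n_starts = n_starts),
            class = "control_config")
}

# block-constant U -> daily dose schedule over the horizon
blocks_to_doses <- function(U, cfg, start = 0) {
  daily <- rep(U, each = cfg$block)[seq_len(cfg$horizon)]
  dose_schedule(times = start + seq(0, cfg$horizon - 1),
                amounts = daily)
}

# x_m at days 0..horizon for a matrix of parameter draws in one compiled
# call (fixed-step RK4; the controller's inner loop)
sim_daily_batch <- function(draws, daily, horizon, init = c(0, 0, 0),
                            nsteps = 25L) {
  theta <- cbind(draws[, .PK_NAMES, drop = FALSE], nu_cm = 1)
  xm <- .Call("pk_batch_sim", as.matrix(theta),
              as.double(daily[seq_len(horizon)]), as.double(init),
              as.integer(nsteps))
  if (any(!is.finite(xm))) {
    bad <- which(!stats::complete.cases(xm))[1]
    stop("simulation failed for draw ", bad)
  }
  xm
}

#' Expected tracking cost of a dose plan
#'
#' Sample-average of the squared deviation of the simulated 6-TGN
#' concentration from the setpoint at daily resolution over the horizon,
#' weighted by the posterior draw weights.
#'
#' @param U per-block daily dose, pmol (length `cfg$n_blocks`).
#' @param posterior a [posterior_samples()] (or matrix of draws).
#' @param cfg a [control_config()].
#' @param draws optional frozen draw matrix overriding `posterior`.
#' @param weights weights matching `draws`.
#' @param init initial model state.
#' @return scalar cost `J`.
#' @export
tracking_cost <- function(U, posterior, cfg, draws = NULL, weights = NULL,
                          init = c(0, 0, 0)) {
  stopifnot(length(U) == cfg$n_blocks)
  if (is.null(draws)) {
    draws <- posterior$draws
    weights <- posterior$weights
  }
  if (is.null(weights)) weights <- rep(1 / nrow(draws), nrow(draws))
  daily <- rep(U, each = cfg$block)[seq_len(cfg$horizon)]
  xm <- sim_daily_batch(draws, daily, cfg$horizon, init = init)
  sum(weights * rowSums((cfg$setpoint - xm[, -1, drop = FALSE])^2))
}

# linear constraint system ui %*% U >= ci for constrOptim
.mpc_constraints <- function(cfg, u_prev) {
  n <- cfg$n_blocks
  ui <- rbind(diag(n), -diag(n))
  ci <- c(rep(cfg$u_min, n), rep(-cfg$u_max, n))
  D <- diff(diag(n))                      # U_k - U_{k-1}, k >= 2
  step <- rbind(diag(n)[1, , drop = FALSE], D)
  off <- c(u_prev, numeric(n - 1))
  ui <- rbind(ui, step, -step)
  ci <- c(ci, cfg$du_min + off * c(1, numeric(n - 1)),
          -(cfg$du_max + off * c(1, numeric(n - 1))))
  list(ui = ui, ci = ci)
}

# project a target constant dose into the strict interior of the feasible set
.feasible_start <- function(target, cfg, u_prev, shrink = 1e-4) {
  n <- cfg$n_blocks
  pad <- shrink * max(cfg$u_max - cfg$u_min, 1)
  u <- numeric(n)
  prev <- u_prev
  for (k in seq_len(n)) {
    lo <- max(cfg$u_min, prev + cfg$du_min) + pad
    hi <- min(cfg$u_max, prev + cfg$du_max) - pad
    u[k] <- min(max(target, lo), hi)
    prev <- u[k]
  }
  u
}

#' Feasibility check for a dose plan
#' @param U per-block doses.
#' @param cfg a [control_config()].
#' @param u_prev dose of the preceding block.
#' @param tol constraint tolerance.
#' @export
plan_feasible <- function(U, cfg, u_prev, tol = 1e-6) {
  all(U >= cfg$u_min - tol) && all(U <= cfg$u_max + tol) &&
    all(diff(c(u_prev, U)) >= cfg$du_min - tol) &&
    all(diff(c(u_prev, U)) <= cfg$du_max + tol)
}

#' Robust dose optimization over one horizon
#'
#' Minimizes [tracking_cost()] over block-constant daily doses by
#' constrained smooth optimization (multi-start `constrOptim` on the linear
#' box and slew constraints) over a frozen set of posterior draws.
#'
#' @param posterior a [posterior_samples()] or `population_prior`.
#' @param cfg a [control_config()].
#' @param u_prev preceding block dose (anchors the first slew constraint).
#' @param init initial model state at the start of the horizon.
#' @param seed RNG seed (freezes the draw set and the random starts).
#' @return object of class `control_plan`: `U`, `J`, `doses`, predicted
#'   `band` (95% interval and mean at daily resolution), `feasible`.
#' @export
optimize_dose <- function(posterior, cfg = control_config(),
                          u_prev = NULL, init = c(0, 0, 0), seed = 1) {
  if (is.null(u_prev)) u_prev <- cfg$standard_dose
  set.seed(seed)
  draws <- sample_prior(posterior, cfg$n_samples)
  if (!all(.ERR_NAMES %in% colnames(draws))) {
    draws <- cbind(draws,
                   matrix(rep(c(10, 0.05), each = nrow(draws)), ncol = 2,
                          dimnames = list(NULL, .ERR_NAMES)))
  }
  w <- rep(1 / nrow(draws), nrow(draws))
  cons <- .mpc_constraints(cfg, u_prev)
  obj <- function(U) tracking_cost(U, NULL, cfg, draws = draws, weights = w,
                                   init = init)
  if (cfg$n_blocks == 1L) {
    lo <- max(cfg$u_min, u_prev + cfg$du_min)
    hi <- min(cfg$u_max, u_prev + cfg$du_max)
    if (lo > hi) stop("infeasible constraint set")
    op <- stats::optimize(function(u) obj(u), c(lo, hi), tol = 1e-6)
    best <- list(par = op$minimum, value = op$objective)
  } else {
  starts <- list(.feasible_start(cfg$standard_dose, cfg, u_prev),
                 .feasible_start(u_prev, cfg, u_prev))
  if (cfg$n_starts > 2)
    for (k in seq_len(cfg$n_starts - 2))
      starts <- c(starts, list(.feasible_start(
        runif(1, cfg$u_min, cfg$u_max), cfg, u_prev)))
  best <- NULL
  # degenerate feasible sets (no strict interior) admit only the projection
  if (all(vapply(starts, function(s)
    !all(cons$ui %*% s - cons$ci > 0), logical(1)))) {
    U0 <- .feasible_start(cfg$standard_dose, cfg, u_prev, shrink = 0)
    best <- list(par = U0, value = obj(U0))
  } else
  for (s in starts) {
    if (!all(cons$ui %*% s - cons$ci > 0)) next
    fit <- try(stats::constrOptim(s, obj, grad = NULL,
                                  ui = cons$ui, ci = cons$ci,
                                  control = list(reltol = cfg$reltol,
                                                 maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  }
  if (is.null(best)) stop("infeasible constraint set or optimizer failure")
  U <- pmin(pmax(best$par, cfg$u_min), cfg$u_max)
  doses <- blocks_to_doses(U, cfg)
  # predicted band under the frozen draw set
  sims <- sim_daily_batch(draws, rep(U, each = cfg$block), cfg$horizon,
                          init = init)
  band <- t(apply(sims, 2, hpd_interval, level = 0.95))
  structure(list(U = U, J = best$value, doses = doses,
                 band = data.frame(time = 0:cfg$horizon,
                                   lower = band[, 1], upper = band[, 2],
                                   mean = colMeans(sims)),
                 u_prev = u_prev,
                 feasible = plan_feasible(U, cfg, u_prev)),
            class = "control_plan")
}

#' @export
print.control_plan <- function(x, ...) {
  cat("MPC dose plan (pmol/day per block):",
      paste(signif(x$U, 4), collapse = ", "), "\n")
  cat(sprintf("cost J = %.4g; feasible: %s\n", x$J, x$feasible))
  invisible(x)
}

#' Receding-horizon closed loop on a virtual patient
#'
#' At each measurement day the true patient is simulated forward under the
#' applied doses, a (noisy) 6-TGN measurement is taken, the posterior is
#' updated by MCMC (estimating `estimate`, all other parameters fixed at
#' the prior mean), and the remaining horizon is re-optimized from the
#' current state. Only implemented control actions are kept.
#'
#' @param true_params,true_err ground-truth patient ([pk_params()],
#'   [error_params()]).
#' @param prior prior used before the first measurement (group prior or
#'   population prior).
#' @param cfg a [control_config()].
#' @param measurement_days sorted days at which 6-TGN is measured.
#' @param seed RNG seed.
#' @param estimate parameters re-estimated from the measurements.
#' @param measure_noise add measurement noise to the observations.
#' @param n_mcmc MCMC draws per update.
#' @return list of class `closed_loop_history`: `doses` (daily vector),
#'   `measurements`, `plans`, `posteriors`, `trajectory`.
#' @export
closed_loop <- function(true_params, true_err, prior,
                        cfg = control_config(), measurement_days = 35,
                        seed = 1, estimate = "k_cm",
                        measure_noise = TRUE, n_mcmc = 1000, fixed = NULL) {
  stopifnot(!is.unsorted(measurement_days))
  measurement_days <- measurement_days[measurement_days < cfg$horizon]
  pm <- prior_moments(prior)
  if (is.null(fixed)) fixed <- pm$mean
  set.seed(seed)
  daily <- numeric(cfg$horizon)
  state <- c(0, 0, 0)
  t_cur <- 0
  post <- prior
  plans <- list()
  posteriors <- list()
  meas <- data.frame(day = numeric(0), y = numeric(0))
  th_true <- c(unlist(true_params[.PK_NAMES]),
               sigma_add = true_err$sigma_add,
               sigma_prop = true_err$sigma_prop)
  seg_ends <- c(measurement_days, cfg$horizon)
  for (seg in seq_along(seg_ends)) {
    t_end <- seg_ends[seg]
    remaining <- cfg$horizon - t_cur
    n_blocks <- max(1L, ceiling(remaining / cfg$block))
    cfg_seg <- cfg
    cfg_seg$horizon <- n_blocks * cfg$block
    cfg_seg$n_blocks <- n_blocks
    u_prev <- if (t_cur == 0) cfg$standard_dose else daily[t_cur]
    plan <- optimize_dose(post, cfg_seg, u_prev = u_prev, init = state,
                          seed = seed + seg)
    plans[[seg]] <- plan
    # implement the plan until the next measurement
    n_apply <- t_end - t_cur
    daily[(t_cur + 1):t_end] <- plan$doses$amounts[seq_len(n_apply)]
    doses_seg <- dose_schedule(times = t_cur + seq(0, n_apply - 1),
                               amounts = daily[(t_cur + 1):t_end])
    tr <- simulate_pk(true_params, doses_seg, times = c(t_cur, t_end),
                      init = state, rtol = 1e-8, atol = 1e-10)
    state <- as.numeric(tr[2, c("x_g", "x_c", "x_m")])
    t_cur <- t_end
    if (t_end %in% measurement_days) {
      sig <- true_err$sigma_add + true_err$sigma_prop * state[3]
      y <- state[3] + if (measure_noise) rnorm(1, 0, sig) else 0
      meas <- rbind(meas, data.frame(day = t_end, y = max(y, 0)))
      data <- measurement_series("closed-loop", meas$day, meas$y,
                                 dose_schedule(seq(0, t_end - 1),
                                               daily[1:t_end]))
      post <- sample_posterior_mcmc(data, prior, n_draws = n_mcmc,
                                    seed = seed + 100 + seg,
                                    estimate = estimate, fixed = fixed)
      posteriors[[length(posteriors) + 1L]] <- post
    }
  }
  traj <- simulate_pk(true_params, dose_schedule(seq(0, cfg$horizon - 1),
                                                 daily),
                      times = 0:cfg$horizon, rtol = 1e-8, atol = 1e-10)
  structure(list(doses = daily, measurements = meas, plans = plans,
                 posteriors = posteriors, trajectory = traj,
                 true_params = true_params),
            class = "closed_loop_history")
}
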