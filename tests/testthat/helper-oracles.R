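# Independent fixed-step 4th-order Runge-Kutta integrator for the
# three-state model, used as a brute-force oracle against the adaptive
# solver. Implemented directly from the model equations, sharing no code
# with the package's solver path.

pk_deriv_r <- function(x, p, infusion = 0) {
  conv <- p[["k_cm"]] * x[2] / (p[["K"]] + x[2])
  c(-p[["k_ab"]] * x[1] + infusion,
    p[["k_ab"]] * x[1] - p[["k_el"]] * x[2] - conv,
    p[["nu_cm"]] * conv - p[["k_me"]] * x[3])
}

rk4_pk <- function(params, doses, times, h = 1e-3, init = c(0, 0, 0)) {
  p <- unlist(params[c("k_ab", "k_el", "k_cm", "K", "k_me", "nu_cm")])
  brk <- sort(unique(c(0, times, doses$times)))
  brk <- brk[brk <= max(times)]
  x <- init
  # fold events at t = 0 into the initial state
  x[1] <- x[1] + sum(doses$amounts[doses$times <= 0])
  out <- matrix(NA_real_, length(times), 3)
  if (0 %in% times) out[match(0, times), ] <- x
  for (s in seq_len(length(brk) - 1)) {
    t0 <- brk[s]; t1 <- brk[s + 1]
    n <- max(1L, ceiling((t1 - t0) / h))
    hh <- (t1 - t0) / n
    for (k in seq_len(n)) {
      k1 <- pk_deriv_r(x, p, doses$infusion)
      k2 <- pk_deriv_r(x + hh / 2 * k1, p, doses$infusion)
      k3 <- pk_deriv_r(x + hh / 2 * k2, p, doses$infusion)
      k4 <- pk_deriv_r(x + hh * k3, p, doses$infusion)
      x <- x + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    hit <- which(doses$times == t1)
    if (length(hit)) x[1] <- x[1] + sum(doses$amounts[hit])
    if (t1 %in% times) out[match(t1, times), ] <- x
  }
  colnames(out) <- c("x_g", "x_c", "x_m")
  out
}

# canonical test fixtures
mean_params <- function() pk_params(4.2, 3.8, 39.4, 15.11, 0.08)

# one synthetic patient with a spread sampling design
make_patient <- function(theta, times = c(4, 14, 35, 56), dose = 113,
                         sigma_add = 10, sigma_prop = 0.05, seed = 1,
                         noise = TRUE) {
  doses <- daily_doses(dose, max(times))
  pars <- pk_params(theta[["k_ab"]], theta[["k_el"]], theta[["k_cm"]],
                    theta[["K"]], theta[["k_me"]])
  yh <- simulate_pk(pars, doses, c(0, times))$x_m[-1]
  set.seed(seed)
  y <- if (noise)
    pmax(yh + rnorm(length(times), 0, sigma_add + sigma_prop * yh), 0)
  else yh
  measurement_series(sprintf("sim-%d", seed), times, y, doses)
}

# quick posterior_samples object from lognormal draws (no MCMC)
fake_posterior <- function(center, sdlog = 0.1, n = 500, seed = 1,
                           provenance = "patient") {
  set.seed(seed)
  nm <- names(center)
  draws <- exp(matrix(rnorm(n * length(center), log(center), sdlog),
                      n, length(center), byrow = TRUE))
  colnames(draws) <- nm
  posterior_samples(draws, provenance = provenance)
}

all_names <- c("k_ab", "k_el", "k_cm", "K", "k_me", "sigma_add", "sigma_prop")
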