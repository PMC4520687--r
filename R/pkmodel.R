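#' @useDynLib thiodose
#' @importFrom stats dnorm pbinom qlnorm quantile rnorm runif sd var cor
#'   optim cov setNames qnorm dlnorm
#' @importFrom utils head tail
#' @importFrom graphics lines points polygon
#' @importFrom grDevices adjustcolor
NULL

# canonical parameter ordering used across the package
.PK_NAMES  <- c("k_ab", "k_el", "k_cm", "K", "k_me")
.ERR_NAMES <- c("sigma_add", "sigma_prop")
.ALL_NAMES <- c(.PK_NAMES, .ERR_NAMES)

#' Kinetic parameters of the 6-MP / 6-TGN model
#'
#' The model tracks 6-MP in the gut (`x_g`, pmol) and plasma (`x_c`, pmol) and
#' the active metabolite 6-TGN in red blood cells (`x_m`, pmol/8e8 RBCs).
#' 6-MP is absorbed at rate `k_ab`, cleared at rate `k_el`, and converted to
#' 6-TGN by Michaelis-Menten kinetics with maximal rate `k_cm` and constant
#' `K`; 6-TGN is eliminated at rate `k_me`.
#'
#' @param k_ab absorption rate of 6-MP from the gut, 1/day.
#' @param k_el plasma elimination rate of 6-MP, 1/day.
#' @param k_cm effective 6-MP to 6-TGN conversion rate, pmol/day. When built
#'   from a TPMT activity (see [effective_conversion_rate()]) this is already
#'   the activity-modulated rate; it is never modulated twice.
#' @param K Michaelis-Menten constant, pmol.
#' @param k_me 6-TGN elimination rate, 1/day.
#' @param nu_cm stoichiometric yield, (pmol 6-TGN per 8e8 RBCs) per pmol 6-MP.
#'   Not separately identifiable from `k_cm` with 6-TGN data alone; default 1.
#' @return object of class `pk_params`.
#' @export
pk_params <- function(k_ab, k_el, k_cm, K, k_me, nu_cm = 1) {
  x <- c(k_ab = k_ab, k_el = k_el, k_cm = k_cm, K = K, k_me = k_me)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all kinetic parameters must be finite and strictly positive")
  if (!is.finite(nu_cm) || nu_cm < 0)
    stop("nu_cm must be >= 0")
  structure(list(k_ab = as.numeric(k_ab)[1], k_el = as.numeric(k_el)[1],
                 k_cm = as.numeric(k_cm)[1], K = as.numeric(K)[1],
                 k_me = as.numeric(k_me)[1], nu_cm = as.numeric(nu_cm)[1]),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("6-MP kinetic parameters:\n")
  print(unlist(x[c(.PK_NAMES, "nu_cm")]))
  invisible(x)
}

# build pk_params from a named vector on the natural scale
as_pk_params <- function(theta, nu_cm = 1) {
  pk_params(theta[["k_ab"]], theta[["k_el"]], theta[["k_cm"]],
            theta[["K"]], theta[["k_me"]], nu_cm = nu_cm)
}

#' TPMT enzyme activity
#'
#' Thiopurine methyltransferase (TPMT) diverts 6-MP away from the 6-TGN
#' pathway, so high activity suppresses 6-TGN production. The measured
#' activity `e` (U/ml/hr) is expressed relative to the population maximum
#' `e_max`; the default `e_max = 30` corresponds to the top of the activity
#' range modelled here (7-30 U/ml/hr).
#'
#' @param e measured TPMT activity, U/ml/hr.
#' @param e_max maximum activity, U/ml/hr; must satisfy `0 <= e <= e_max`.
#' @param k_cm_max maximal conversion rate at zero activity, pmol/day.
#' @return object of class `tpmt_activity`.
#' @export
tpmt_activity <- function(e, e_max = 30, k_cm_max = 100) {
  if (!is.finite(e_max) || e_max <= 0)
    stop("invalid TPMT activity: e_max must be > 0")
  if (!is.finite(e) || e < 0 || e > e_max)
    stop("invalid TPMT activity: need 0 <= e <= e_max")
  if (!is.finite(k_cm_max) || k_cm_max <= 0)
    stop("k_cm_max must be > 0")
  structure(list(e = e, e_max = e_max, k_cm_max = k_cm_max),
            class = "tpmt_activity")
}

#' Relative TPMT activity
#'
#' @param act a [tpmt_activity()].
#' @return `e / e_max`, a fraction in \[0, 1\].
#' @export
relative_activity <- function(act) {
  stopifnot(inherits(act, "tpmt_activity"))
  act$e / act$e_max
}

#' Activity-modulated conversion rate
#'
#' The fraction of 6-MP routed to 6-TGN is taken proportional to
#' `(1 - e/e_max)`, so the effective conversion rate is
#' `k_cm = k_cm_max * (1 - e/e_max)`: monotone decreasing in activity.
#'
#' @inheritParams relative_activity
#' @return effective conversion rate, pmol/day.
#' @export
effective_conversion_rate <- function(act) {
  act$k_cm_max * (1 - relative_activity(act))
}

#' Dosing schedule
#'
#' Timed oral boluses of 6-MP (delivered to the gut compartment) plus an
#' optional constant infusion into the gut. Boluses are treated as
#' instantaneous additions to `x_g`: oral intake is fast relative to the
#' daily dynamics being modelled.
#'
#' @param times bolus times, days (non-negative; sorted internally).
#' @param amounts bolus amounts, pmol of 6-MP (recycled to `length(times)`).
#' @param infusion constant gut input rate, pmol/day.
#' @return object of class `dose_schedule`.
#' @export
dose_schedule <- function(times = numeric(0), amounts = numeric(0),
                          infusion = 0) {
  if (length(amounts) == 1L && length(times) > 1L)
    amounts <- rep(amounts, length(times))
  if (length(times) != length(amounts))
    stop("times and amounts must have equal length")
  if (any(times < 0) || any(amounts < 0) || infusion < 0)
    stop("dose times, amounts and infusion must be non-negative")
  o <- order(times)
  structure(list(times = times[o], amounts = amounts[o], infusion = infusion),
            class = "dose_schedule")
}

#' Daily constant-dose schedule
#'
#' Convenience constructor: one bolus of `dose` pmol at each integer day
#' `0, 1, ..., n_days - 1`.
#'
#' @param dose daily 6-MP bolus, pmol.
#' @param n_days number of dosing days.
#' @param start first dosing day.
#' @export
daily_doses <- function(dose, n_days, start = 0) {
  dose_schedule(times = seq(start, by = 1, length.out = n_days),
                amounts = rep(dose, n_days))
}

#' Simulate the 6-MP metabolism model
#'
#' Integrates the three-state model with `lsoda` (compiled right-hand side);
#' bolus events are applied as instantaneous increments to the gut state,
#' with the integration restarted at each event time.
#'
#' @param params a [pk_params()].
#' @param doses a [dose_schedule()].
#' @param times output times, days, sorted and non-negative.
#' @param init initial state `c(x_g, x_c, x_m)`, non-negative.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return a `pk_trajectory`: data.frame with columns `time, x_g, x_c, x_m`.
#' @export
simulate_pk <- function(params, doses, times, init = c(0, 0, 0),
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "pk_params"), inherits(doses, "dose_schedule"))
  if (is.unsorted(times) || any(times < 0))
    stop("times must be sorted and non-negative")
  if (length(init) != 3L || any(init < 0))
    stop("init must be 3 non-negative state values")
  y0 <- c(x_g = init[1], x_c = init[2], x_m = init[3])
  t0 <- times[1]
  # events at or before t0 are folded into the initial state
  pre <- doses$times <= t0
  y0["x_g"] <- y0["x_g"] + sum(doses$amounts[pre])
  ev_t <- doses$times[!pre]
  ev_a <- doses$amounts[!pre]
  keep <- ev_t <= max(times)          # events after the horizon are irrelevant
  ev_t <- ev_t[keep]; ev_a <- ev_a[keep]
  p <- c(params$k_ab, params$k_el, params$k_cm, params$K, params$k_me,
         params$nu_cm, doses$infusion)
  grid <- sort(unique(c(times, ev_t)))
  args <- list(y = y0, times = grid, func = "pk6mp_deriv", parms = p,
               dllname = "thiodose", initfunc = "pk6mp_init",
               rtol = rtol, atol = atol)
  if (length(ev_t))
    args$events <- list(data = data.frame(var = "x_g", time = ev_t,
                                          value = ev_a, method = "add"))
  out <- try(suppressWarnings(do.call(deSolve::lsoda, args)), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(grid))
    stop("integration error in simulate_pk: ", attr(out, "condition")$message)
  out <- as.data.frame(out)
  out <- out[match(times, out$time), , drop = FALSE]
  # clamp solver-tolerance negatives
  for (cn in c("x_g", "x_c", "x_m")) out[[cn]] <- pmax(out[[cn]], 0)
  rownames(out) <- NULL
  class(out) <- c("pk_trajectory", "data.frame")
  out
}

#' Steady-state 6-TGN concentration under constant infusion
#'
#' Closed-form companion to the dynamic model: solves
#' `0 = u - k_el x_c - k_cm x_c / (K + x_c)` for the non-negative plasma
#' steady state and returns the implied 6-TGN level
#' `nu_cm k_cm x_c / (K + x_c) / k_me`. A constant daily oral dose `D`
#' behaves like an infusion `u = D` pmol/day once averaged over days.
#'
#' @param params a [pk_params()].
#' @param infusion constant gut input, pmol/day.
#' @return steady-state `x_m`, pmol/8e8 RBCs.
#' @export
steady_state_tgn <- function(params, infusion) {
  stopifnot(inherits(params, "pk_params"), infusion >= 0)
  if (infusion == 0) return(0)
  kel <- params$k_el; kcm <- params$k_cm; K <- params$K
  if (kel > 0) {
    b <- kel * K + kcm - infusion
    disc <- b^2 + 4 * kel * infusion * K
    xc <- (-b + sqrt(disc)) / (2 * kel)
  } else {
    if (infusion >= kcm)
      stop("infeasible steady state: infusion exceeds conversion capacity")
    xc <- infusion * K / (kcm - infusion)
  }
  if (!is.finite(xc) || xc < 0)
    stop("infeasible steady state: no non-negative plasma root")
  params$nu_cm * kcm * xc / (K + xc) / params$k_me
}

#' Write / read trajectories as CSV
#' @param traj a `pk_trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("time", "x_g", "x_c", "x_m")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialize parameters and schedules as JSON
#' @param x a `pk_params` or `dose_schedule`.
#' @param path file path.
#' @export
write_pk_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pk_json
#' @param what `"params"` or `"doses"`.
#' @export
read_pk_json <- function(path, what = c("params", "doses")) {
  what <- match.arg(what)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (what == "params")
    pk_params(x$k_ab, x$k_el, x$k_cm, x$K, x$k_me, nu_cm = x$nu_cm %||% 1)
  else
    dose_schedule(x$times %||% numeric(0), x$amounts %||% numeric(0),
                  infusion = x$infusion %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
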