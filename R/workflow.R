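# Orchestration of the two phases: offline population-model building
# (MLE -> prior -> per-patient posteriors -> population prior -> Sobol
# reduction -> sampling-day design) and the online new-patient protocol
# (activity group prior, dose optimization to the design day, posterior
# update from the single measurement, individualized re-optimization).

#' Offline population-model building
#'
#' Runs the full offline chain on a cohort of measurement series:
#' per-patient MLE; a moment-matched lognormal prior from the MLE
#' statistics (unless one is supplied); per-patient MCMC posteriors; the
#' pooled population prior; the Sobol sensitivity report whose partition
#' feeds the sampling-day design; and the robust D-optimal sampling day.
#'
#' @param cohort list of [measurement_series()] (>= 2 patients).
#' @param prior optional prior object; default built from the cohort MLEs.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_draws posterior draws per patient.
#' @param gsa_n_base Sobol base sample size.
#' @param oed_draws prior draws for the information profile.
#' @param oed_grid candidate sampling days.
#' @param compromise_fraction information fraction given up for earliness.
#' @return object of class `study_run` with the offline artifacts.
#' @export
run_offline <- function(cohort, prior = NULL, seed = 1,
                        n_draws = 1000, gsa_n_base = 256,
                        oed_draws = 50, oed_grid = seq(1, 100, by = 3),
                        compromise_fraction = 0.05) {
  if (length(cohort) < 2L) stop("offline stage needs >= 2 patients")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  mles <- stage("mle", lapply(seq_along(cohort), function(i)
    fit_mle(cohort[[i]], seed = seed + i)))
  if (is.null(prior)) prior <- stage("prior", {
    est <- do.call(rbind, lapply(mles, `[[`, "theta"))
    m <- colMeans(est)
    C <- nearest_psd(cov(est))
    # guard against degenerate spread from bound-hitting fits
    C <- C + diag(pmax(1e-4 * m^2, 1e-8))
    lognormal_prior(m, C)
  })
  posteriors <- stage("posterior", lapply(seq_along(cohort), function(i)
    sample_posterior_mcmc(cohort[[i]], prior, n_draws = n_draws,
                          seed = seed + 100 + i)))
  n_points <- vapply(cohort, function(s) length(s$y), integer(1))
  pop_prior <- stage("population_prior",
                     build_population_prior(posteriors, n_points,
                                            seed = seed + 7))
  gsa <- stage("gsa", pk_sobol_report(pop_prior, n_base = gsa_n_base,
                                      seed = seed + 11))
  est <- gsa$partition$estimate
  oed_param <- est[which.max(gsa$bound[est])]
  profile <- stage("oed",
                   expected_information_profile(pop_prior,
                                                candidate_times = oed_grid,
                                                param_subset = oed_param,
                                                n_draws = oed_draws,
                                                seed = seed + 13))
  t_star <- select_sampling_time(profile, compromise_fraction)
  activities <- vapply(cohort, function(s)
    if (is.null(s$activity)) NA_real_ else s$activity$e, numeric(1))
  structure(list(mles = mles, prior = prior, posteriors = posteriors,
                 n_points = n_points, population_prior = pop_prior,
                 gsa = gsa, oed_profile = profile, t_star = t_star,
                 oed_param = oed_param, activities = activities,
                 seed = seed),
            class = "study_run")
}

#' @export
print.study_run <- function(x, ...) {
  cat(sprintf("offline study run: %d patients\n", length(x$posteriors)))
  cat("population-prior means:\n"); print(signif(x$population_prior$mean, 4))
  cat("sensitive:", paste(x$gsa$partition$sensitive, collapse = ", "),
      "| estimated online:", x$oed_param, "\n")
  cat(sprintf("optimal sampling day: %d\n", x$t_star))
  invisible(x)
}

# activity window (lo, hi] for a group id
group_window <- function(group) c(7 + 2 * (group - 1), 9 + 2 * (group - 1))

#' Online protocol for a new patient
#'
#' Measures TPMT activity at presentation, places the patient in the
#' matching 2 U/ml/hr activity group, optimizes dosing under the group
#' prior until the design day, simulates the (virtual) patient and takes
#' the 6-TGN measurement, updates to a patient-specific posterior
#' (estimating only the sensitivity-selected parameter; all others fixed
#' at the population-prior mean), and re-optimizes with the
#' patient-specific model.
#'
#' @param activity a [tpmt_activity()] or numeric activity in U/ml/hr.
#' @param offline a `study_run` from [run_offline()].
#' @param true_patient list with `params` ([pk_params()]) and `err`
#'   ([error_params()]) — the simulated ground truth.
#' @param cfg a [control_config()].
#' @param seed RNG seed.
#' @param measure_noise add measurement noise.
#' @param n_mcmc MCMC draws for the online update.
#' @return list of class `patient_run`: `group`, `prior_used`,
#'   `pre_plan`, `measurement`, `posterior`, `post_plan`, `history`.
#' @export
run_new_patient <- function(activity, offline, true_patient,
                            cfg = control_config(), seed = 1,
                            measure_noise = TRUE, n_mcmc = 1000) {
  e <- if (inherits(activity, "tpmt_activity")) activity$e else activity
  group <- assign_activity_group(e)
  gp <- tryCatch(
    build_group_prior(offline$posteriors, offline$activities,
                      group_window(group), n_points = offline$n_points,
                      seed = seed + 3),
    error = function(err) {
      warning("empty activity group; falling back to population prior")
      NULL
    })
  prior_used <- if (is.null(gp)) offline$population_prior else gp
  hist <- closed_loop(true_patient$params, true_patient$err, prior_used,
                      cfg = cfg, measurement_days = offline$t_star,
                      seed = seed, estimate = offline$oed_param,
                      measure_noise = measure_noise, n_mcmc = n_mcmc,
                      fixed = offline$population_prior$mean)
  structure(list(group = group, prior_used = prior_used,
                 pre_plan = hist$plans[[1]],
                 measurement = hist$measurements,
                 posterior = if (length(hist$posteriors))
                   hist$posteriors[[1]] else NULL,
                 post_plan = if (length(hist$plans) > 1)
                   hist$plans[[2]] else NULL,
                 history = hist),
            class = "patient_run")
}
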