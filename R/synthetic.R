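# Virtual-patient generator: cohorts with the statistical structure of the
# three literature datasets the population model is built from —
# D1: 23 patients, up to 4 sparse samples over 8 weeks;
# D2: 8 patients, biweekly samples over 20 weeks;
# D3: 102 paired TPMT-activity / 6-TGN measurements, activity 7-30 U/ml/hr.

#' Population kinetic-parameter statistics
#'
#' Mean vector and inter-patient covariance for
#' `(k_ab, k_el, k_cm, K, k_me)` on the natural scale. Defaults are the
#' published population statistics (means 4.2, 3.8, 39.4, 15.11, 0.08); the
#' default covariance carries the published variances (4.1, 4.4, 382, 11.8)
#' and cross-covariances, with the `k_me` row completed so that
#' `cor(k_cm, k_me) = 0.96` — the strong correlation this pair is known to
#' exhibit — and the matrix is positive semi-definite.
#'
#' @param mean named length-5 mean vector.
#' @param cov 5x5 covariance matrix (same order).
#' @return object of class `population_stats`.
#' @export
population_stats <- function(mean = NULL, cov = NULL) {
  if (is.null(mean))
    mean <- c(k_ab = 4.2, k_el = 3.8, k_cm = 39.4, K = 15.11, k_me = 0.08)
  if (is.null(cov)) {
    v_kme <- (0.42 / (0.96 * sqrt(382)))^2
    cov <- matrix(c(
      4.1,   0.43,  1.67,   0.67, 0.003,
      0.43,  4.4,   2.12,  -0.74, 0.0059,
      1.67,  2.12,  382,   13.21, 0.42,
      0.67, -0.74,  13.21, 11.8,  0.03,
      0.003, 0.0059, 0.42,  0.03, v_kme), 5, 5,
      dimnames = list(.PK_NAMES, .PK_NAMES))
  }
  mean <- mean[.PK_NAMES]
  cov <- as.matrix(cov)
  dimnames(cov) <- list(.PK_NAMES, .PK_NAMES)
  if (any(abs(cov - t(cov)) > 1e-8)) stop("covariance must be symmetric")
  if (min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("covariance must be positive semi-definite")
  structure(list(mean = mean, cov = cov), class = "population_stats")
}

#' Sample virtual-patient kinetic parameters
#'
#' Draws from the moment-matched multivariate lognormal with the given
#' natural-scale mean and covariance; all draws are positive.
#'
#' @param n number of parameter vectors.
#' @param stats a [population_stats()].
#' @param seed RNG seed.
#' @return `n x 5` matrix with columns `k_ab, k_el, k_cm, K, k_me`.
#' @export
sample_population <- function(n, stats = population_stats(), seed = 1) {
  stopifnot(n >= 1)
  pr <- lognormal_prior(stats$mean, stats$cov)
  set.seed(seed)
  sample_prior(pr, n)
}

#' TPMT activity group assignment
#'
#' Half-open 2 U/ml/hr windows anchored at 7.01: group 1 is
#' `(7.00, 9.00]`, group 2 `(9.00, 11.00]`, and so on; the eleventh group
#' closes the modelled 7-30 range (activities above 29 fold into it).
#'
#' @param e TPMT activity, U/ml/hr (vectorized).
#' @return integer group id(s), 1-based.
#' @export
assign_activity_group <- function(e) {
  if (any(e <= 7))
    stop("activity out of modelled range: need e > 7 U/ml/hr")
  pmin(as.integer(ceiling((e - 7) / 2)), 11L)
}

#' Genotype class from TPMT activity
#'
#' Activity below 10 U/ml/hr is classed heterozygous (TPMT H/L); 10 and
#' above homozygous-high (TPMT H/H) — the boundary value is assigned to the
#' homozygous-high class by convention.
#'
#' @param e TPMT activity, U/ml/hr (vectorized).
#' @return character vector, `"heterozygous"` or `"homozygous-high"`.
#' @export
genotype_from_activity <- function(e) {
  stopifnot(all(e > 0))
  ifelse(e < 10, "heterozygous", "homozygous-high")
}

# truncated-normal sampler by rejection (ranges here make this cheap)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Default generator configuration
#'
#' @param dose daily 6-MP bolus, pmol (default 113, which puts a
#'   population-mean patient's steady-state 6-TGN near the centre of the
#'   therapeutic window).
#' @param sigma_add,sigma_prop measurement-noise parameters.
#' @param e_max maximum TPMT activity, U/ml/hr.
#' @param k_cm_max maximal conversion rate, pmol/day.
#' @param activity_mean,activity_sd truncated-normal activity distribution.
#' @param jitter_cv lognormal CV of the activity-to-rate link noise.
#' @export
synth_config <- function(dose = 113, sigma_add = 10, sigma_prop = 0.05,
                         e_max = 30, k_cm_max = 100,
                         activity_mean = 18, activity_sd = 5,
                         jitter_cv = 0.2) {
  list(dose = dose, sigma_add = sigma_add, sigma_prop = sigma_prop,
       e_max = e_max, k_cm_max = k_cm_max, activity_mean = activity_mean,
       activity_sd = activity_sd, jitter_cv = jitter_cv)
}

#' Generate a synthetic clinical dataset
#'
#' Emulates the structure of the three source datasets:
#' * `"D1"`: 23 patients, 1-4 observations each within 56 days;
#' * `"D2"`: 8 patients, biweekly observations to 140 days;
#' * `"D3"`: 102 patients, one TPMT activity and one 6-TGN observation each.
#'
#' Kinetic parameters are drawn from the moment-matched lognormal population
#' distribution. Every patient gets a TPMT activity consistent with their
#' conversion rate through the activity link
#' `k_cm = k_cm_max (1 - e/e_max)`: for D1/D2 the activity is back-derived
#' from the sampled `k_cm`, for D3 the activity is drawn first and `k_cm`
#' derived with multiplicative lognormal jitter (so within-activity-group
#' heterogeneity exists). Observations are simulated truth plus
#' heteroscedastic noise, floored at zero.
#'
#' @param design `"D1"`, `"D2"` or `"D3"`.
#' @param stats a [population_stats()].
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @return list of [measurement_series()]; per-patient ground truth
#'   (`virtual_patient` objects) in attribute `truth`.
#' @export
generate_dataset <- function(design = c("D1", "D2", "D3"),
                             stats = population_stats(),
                             config = synth_config(), seed = 1) {
  design <- match.arg(design)
  set.seed(seed)
  n_pat <- switch(design, D1 = 23L, D2 = 8L, D3 = 102L)
  theta <- sample_population(n_pat, stats, seed = seed + 1L)
  if (design == "D3") {
    e <- rtruncnorm(n_pat, config$activity_mean, config$activity_sd, 7, config$e_max)
    sdlog <- sqrt(log(1 + config$jitter_cv^2))
    jit <- exp(rnorm(n_pat, -sdlog^2 / 2, sdlog))
    theta[, "k_cm"] <- pmax(config$k_cm_max * (1 - e / config$e_max) * jit, 0.5)
  } else {
    # back-derive an activity consistent with the sampled conversion rate
    e <- pmin(pmax(config$e_max * (1 - theta[, "k_cm"] / config$k_cm_max),
                   7.01), config$e_max)
  }
  horizon <- switch(design, D1 = 56, D2 = 140, D3 = 56)
  series <- vector("list", n_pat)
  truth <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    obs_t <- switch(design,
      D1 = sort(sample(7:56, sample(1:4, 1))),
      D2 = seq(14, 140, by = 14),
      D3 = 56)
    pars <- as_pk_params(theta[i, ])
    # a noise-free config still needs a valid (positive) error model
    err <- error_params(max(config$sigma_add, 1e-12), config$sigma_prop)
    doses <- daily_doses(config$dose, horizon)
    grid <- sort(unique(c(0, obs_t)))
    tr <- simulate_pk(pars, doses, grid, rtol = 1e-6, atol = 1e-8)
    yhat <- tr$x_m[match(obs_t, grid)]
    noise_sd <- config$sigma_add + config$sigma_prop * yhat
    y <- pmax(yhat + rnorm(length(yhat), 0, noise_sd), 0)
    act <- tpmt_activity(e[i], e_max = config$e_max,
                         k_cm_max = config$k_cm_max)
    series[[i]] <- measurement_series(sprintf("%s-%02d", design, i),
                                      obs_t, y, doses, activity = act)
    truth[[i]] <- structure(
      list(params = pars, err = err, activity = act,
           group = assign_activity_group(max(e[i], 7.01)),
           genotype = genotype_from_activity(e[i])),
      class = "virtual_patient")
  }
  attr(series, "truth") <- truth
  attr(series, "design") <- design
  attr(series, "config") <- config
  series
}

#' Write a synthetic dataset as CSV bundles
#'
#' Emits `measurements.csv` (patient_id, time_day, y_pmol_per_8e8RBC),
#' `doses.csv`, `activities.csv` and a manifest JSON with seed/config.
#'
#' @param series output of [generate_dataset()].
#' @param dir output directory.
#' @param seed seed recorded in the manifest.
#' @export
write_dataset <- function(series, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meas <- do.call(rbind, lapply(series, function(s)
    data.frame(patient_id = s$patient_id, time_day = s$times,
               y_pmol_per_8e8RBC = s$y)))
  utils::write.csv(meas, file.path(dir, "measurements.csv"), row.names = FALSE)
  dos <- do.call(rbind, lapply(series, function(s)
    data.frame(patient_id = s$patient_id, time_day = s$doses$times,
               amount_pmol = s$doses$amounts)))
  utils::write.csv(dos, file.path(dir, "doses.csv"), row.names = FALSE)
  act <- do.call(rbind, lapply(series, function(s)
    data.frame(patient_id = s$patient_id,
               activity_U_ml_hr = if (is.null(s$activity)) NA else s$activity$e)))
  utils::write.csv(act, file.path(dir, "activities.csv"), row.names = FALSE)
  jsonlite::write_json(list(design = attr(series, "design"), seed = seed,
                            config = attr(series, "config")),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
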