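#' Parameter names for the treatment-response design
#'
#' Column order is `[baseline factors | medications | intercept]`, giving
#' `P = n_factors + 4 + 1` free parameters.
#'
#' @param n_factors number of baseline latent factors (default 14).
#' @return Character vector of length `n_factors + 5`.
#' @export
parameter_names <- function(n_factors = 14) {
  c(paste0("f", sprintf("%02d", seq_len(n_factors))),
    "med_irmph", "med_xrmph", "med_dex", "med_atom", "intercept")
}

#' Configuration for the synthetic titration cohort generator
#'
#' Defines the statistical structure of a simulated dose-optimization
#' titration cohort: standardized baseline latent factors, subject-specific
#' response vectors with negative medication effects (medication lowers
#' symptom scores), a stepwise dose ramp over the first appointments
#' followed by a plateau, additive Gaussian observation noise, and
#' remission thresholds on the two symptom dimensions.
#'
#' The default population parameters are calibrated so that the visit-level
#' inattentiveness remission prevalence is close to 14% under the default
#' thresholds (-0.97 inattentiveness, -0.92 hyperactivity), matching the
#' imbalance regime a titration clinic exhibits.
#'
#' @param n_subjects number of subjects to simulate.
#' @param n_factors number of baseline latent factors L (default 14).
#' @param appointment_range integer pair, min/max appointments per subject,
#'   within `[1, 22]`.
#' @param omega_population_mean numeric P-vector of population means for
#'   the subject-specific response vectors (medication entries must be
#'   <= 0). Default: baseline factors 0, medications -1 per unit of
#'   normalized combined EDD (doses are expressed as fractions of the
#'   maximum daily dose, so coefficients are on the unit scale the prior
#'   elicitation assumes), intercept 0.75.
#' @param omega_population_sd numeric P-vector of nonnegative population
#'   spreads. Default: baseline factors 0.15, medications 0.008,
#'   intercept 0.3.
#' @param noise_sd nonnegative observation noise standard deviation
#'   (default 0.35).
#' @param dose_ramp list with `target_edd` (per-appointment combined
#'   equivalent-daily-dose targets; the last value is held for later
#'   appointments) and `switch_prob` (per-appointment probability of
#'   switching medication).
#' @param remission_thresholds numeric pair: score at or below which a
#'   visit counts as remission, per dimension.
#' @param seed integer seed; the generator is fully deterministic given
#'   the config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          n_factors = 14,
                          appointment_range = c(1L, 22L),
                          omega_population_mean = NULL,
                          omega_population_sd = NULL,
                          noise_sd = 0.35,
                          dose_ramp = list(
                            target_edd = c(0.2, 0.4, 0.6, 0.8, 1.0),
                            switch_prob = 0.05),
                          remission_thresholds = c(inattentiveness = -0.97,
                                                   hyperactivity = -0.92),
                          seed = 1L) {
  P <- n_factors + 5L
  if (is.null(omega_population_mean))
    omega_population_mean <- c(rep(0, n_factors), rep(-1, 4), 0.75)
  if (is.null(omega_population_sd))
    omega_population_sd <- c(rep(0.15, n_factors), rep(0.35, 4), 0.3)
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects),
         n_factors = as.integer(n_factors),
         appointment_range = as.integer(appointment_range),
         omega_population_mean = as.numeric(omega_population_mean),
         omega_population_sd = as.numeric(omega_population_sd),
         noise_sd = as.numeric(noise_sd),
         dose_ramp = dose_ramp,
         remission_thresholds = remission_thresholds,
         seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  P <- cfg$n_factors + 5L
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (cfg$n_factors < 1) stop("n_factors must be >= 1", call. = FALSE)
  ar <- cfg$appointment_range
  if (length(ar) != 2 || ar[1] < 1 || ar[2] > 22 || ar[1] > ar[2])
    stop("appointment_range must satisfy 1 <= min <= max <= 22", call. = FALSE)
  if (length(cfg$omega_population_mean) != P)
    stop("omega_population_mean must have length P = ", P, call. = FALSE)
  if (length(cfg$omega_population_sd) != P)
    stop("omega_population_sd must have length P = ", P, call. = FALSE)
  med_idx <- cfg$n_factors + 1:4
  if (any(cfg$omega_population_mean[med_idx] > 0))
    stop("medication entries of omega_population_mean must be <= 0 ",
         "(medication lowers symptom scores)", call. = FALSE)
  if (any(cfg$omega_population_sd < 0))
    stop("omega_population_sd must be nonnegative", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (!is.numeric(cfg$dose_ramp$target_edd) ||
      any(cfg$dose_ramp$target_edd < 0))
    stop("dose_ramp$target_edd must be nonnegative", call. = FALSE)
  sp <- cfg$dose_ramp$switch_prob
  if (!is.numeric(sp) || sp < 0 || sp > 1)
    stop("dose_ramp$switch_prob must be in [0, 1]", call. = FALSE)
  if (length(cfg$remission_thresholds) != 2 ||
      any(!is.finite(cfg$remission_thresholds)))
    stop("remission_thresholds must be two finite values", call. = FALSE)
  invisible(cfg)
}

# run expr with a private RNG stream; restores the caller's RNG state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic titration cohort
#'
#' Simulates subjects attending a dose-optimization titration clinic.
#' For each subject: the number of appointments is drawn uniformly over
#' `appointment_range`; baseline latent factors are standard normal
#' (factor scores are standardized); the subject-specific response vector
#' is drawn per-coordinate from the population mean/sd; dosages follow the
#' stepwise ramp template with Bernoulli medication switching; outcomes are
#' `X omega + eps` with i.i.d. Gaussian noise per symptom dimension.
#'
#' @param config a [cohort_config()].
#' @return A list of class `cohort`; each element is a `subject` list with
#'   `subject_id`, `baseline`, `dosages` (A x 4), `outcomes` (A x 2,
#'   columns `score_ina`, `score_hyp`) and `true_omega` (simulation ground
#'   truth). The config is attached as attribute `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 5, seed = 42))
#' length(coh)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  L <- config$n_factors
  P <- L + 5L
  ramp <- config$dose_ramp$target_edd
  .with_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(s) {
      A <- sample(seq(config$appointment_range[1],
                      config$appointment_range[2]), 1)
      baseline <- stats::rnorm(L)
      omega <- stats::rnorm(P, config$omega_population_mean,
                            config$omega_population_sd)
      med <- sample.int(4, 1, prob = c(0.35, 0.35, 0.15, 0.15))
      dosages <- matrix(0, nrow = A, ncol = 4,
                        dimnames = list(NULL, c("dose_irmph", "dose_xrmph",
                                                "dose_dex", "dose_atom")))
      for (a in seq_len(A)) {
        if (a > 1 && stats::runif(1) < config$dose_ramp$switch_prob) {
          med <- sample(setdiff(1:4, med), 1)
        }
        dosages[a, med] <- ramp[min(a, length(ramp))]
      }
      X <- make_design(baseline, dosages)
      mu <- drop(X %*% omega)
      outcomes <- cbind(
        score_ina = mu + stats::rnorm(A, 0, config$noise_sd),
        score_hyp = mu + stats::rnorm(A, 0, config$noise_sd))
      structure(list(subject_id = sprintf("S%04d", s),
                     baseline = baseline,
                     dosages = dosages,
                     outcomes = outcomes,
                     true_omega = omega),
                class = "subject")
    })
  }) -> subjects
  structure(subjects, class = "cohort", config = config)
}

#' @export
print.cohort <- function(x, ...) {
  A <- vapply(x, function(s) nrow(s$dosages), integer(1))
  cat("Synthetic titration cohort: ", length(x), " subjects, ",
      sum(A), " visits (", min(A), "-", max(A),
      " appointments per subject)\n", sep = "")
  invisible(x)
}

#' Label visits as remission
#'
#' A visit is labeled remission (1) on a dimension iff its symptom score is
#' at or below the dimension's threshold (the boundary is inclusive: a
#' score exactly at the threshold counts as remission).
#'
#' @param outcomes A x 2 matrix of symptom scores (inattentiveness,
#'   hyperactivity), or a numeric vector for a single dimension.
#' @param thresholds numeric pair (or scalar matching a vector input).
#' @return Binary matrix (or vector) of the same shape; 1 = remission.
#' @export
label_remission <- function(outcomes,
                            thresholds = c(-0.97, -0.92)) {
  if (any(!is.finite(thresholds)))
    stop("thresholds must be finite", call. = FALSE)
  if (is.matrix(outcomes)) {
    if (ncol(outcomes) != length(thresholds))
      stop("one threshold per outcome column is required", call. = FALSE)
    out <- outcomes
    for (j in seq_len(ncol(outcomes)))
      out[, j] <- as.integer(outcomes[, j] <= thresholds[j])
    out
  } else {
    as.integer(outcomes <= thresholds[1])
  }
}

# visit-level remission prevalence of a cohort, per dimension
.cohort_prevalence <- function(cohort) {
  cfg <- attr(cohort, "config")
  lab <- do.call(rbind, lapply(cohort, function(s)
    label_remission(s$outcomes, cfg$remission_thresholds)))
  colMeans(lab)
}

#' Calibrate the generator to a target remission prevalence
#'
#' Searches over an additive offset to the population intercept mean so
#' that the visit-level inattentiveness remission prevalence, averaged
#' over `n_trials` seeded replicates, lands within +/- 2 percentage points
#' of the target. Raising the intercept raises symptom scores and lowers
#' prevalence, so the search is a monotone bisection.
#'
#' @param config a [cohort_config()] to adjust.
#' @param target_prevalence desired visit-level remission fraction,
#'   strictly between 0 and 1.
#' @param n_trials number of seeded replicate cohorts to average over.
#' @param bounds search bounds for the intercept offset.
#' @param tol acceptable absolute deviation from the target (default 0.02).
#' @return The adjusted `cohort_config`.
#' @export
calibrate_prevalence <- function(config, target_prevalence, n_trials = 20,
                                 bounds = c(-5, 5), tol = 0.02) {
  validate_cohort_config(config)
  if (!is.numeric(target_prevalence) || length(target_prevalence) != 1 ||
      target_prevalence <= 0 || target_prevalence >= 1)
    stop("calibration error: target_prevalence must be strictly between 0 and 1",
         call. = FALSE)
  P <- config$n_factors + 5L
  prev_at <- function(delta) {
    cfg <- config
    cfg$omega_population_mean[P] <- cfg$omega_population_mean[P] + delta
    mean(vapply(seq_len(n_trials), function(i) {
      cfg$seed <- config$seed + i - 1L
      .cohort_prevalence(generate_cohort(cfg))[1]
    }, numeric(1)))
  }
  lo <- bounds[1]; hi <- bounds[2]
  p_lo <- prev_at(lo); p_hi <- prev_at(hi)   # p_lo high, p_hi low
  if (target_prevalence > p_lo + tol || target_prevalence < p_hi - tol)
    stop("calibration error: target prevalence ", target_prevalence,
         " unreachable within offset bounds [", lo, ", ", hi,
         "] (achievable range ~[", round(p_hi, 3), ", ", round(p_lo, 3), "])",
         call. = FALSE)
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    p_mid <- prev_at(mid)
    if (abs(p_mid - target_prevalence) <= tol) {
      cfg <- config
      cfg$omega_population_mean[P] <- cfg$omega_population_mean[P] + mid
      return(cfg)
    }
    if (p_mid > target_prevalence) lo <- mid else hi <- mid
  }
  stop("calibration error: bisection failed to reach target within tolerance",
       call. = FALSE)
}
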