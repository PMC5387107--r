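#' Patient-coherent fold assignment
#'
#' Randomly partitions subjects into `k` folds of sizes differing by at
#' most one, deterministic for a given seed. All of a subject's
#' appointments stay in the subject's single fold (patient coherence).
#'
#' @param subject_ids character vector of subject ids.
#' @param k number of folds (default 10); must not exceed the number of
#'   subjects.
#' @param seed integer seed.
#' @return Named integer vector mapping subject id to fold in `1..k`.
#' @export
make_folds <- function(subject_ids, k = 10, seed = 1) {
  n <- length(subject_ids)
  if (k < 1 || k > n)
    stop("k must be between 1 and the number of subjects (", n, ")",
         call. = FALSE)
  .with_seed(seed, {
    perm <- sample(subject_ids)
    folds <- rep(seq_len(k), length.out = n)  # sizes differ by <= 1
    stats::setNames(folds[match(subject_ids, perm)], subject_ids)
  })
}

#' Predict a subject's appointment course under one strategy
#'
#' Produces one Student-t predictive distribution per appointment for one
#' symptom dimension, honoring the prequential rule: the prediction at
#' appointment `a` never uses the outcome at appointment `a` or later.
#'
#' Strategies:
#' \describe{
#'   \item{AI (appointment-independent)}{every appointment is predicted
#'     from the virtual patient profile with no updating.}
#'   \item{BR (incremental Bayesian linear regression)}{appointment 1 is
#'     predicted from the virtual profile exactly as AI; appointment
#'     `a >= 2` is predicted from the *elicited prior* batch-updated on
#'     appointments `1..a-1`, i.e. refit from scratch, ignoring the
#'     profile. This benchmarks the value of the model-space pool.}
#'   \item{BU (incremental Bayesian update)}{appointment 1 as AI; the
#'     virtual profile is then sequentially updated with each observed
#'     appointment before predicting the next.}
#' }
#' Appointments with a missing outcome are still predicted but skipped
#' when updating.
#'
#' @param subject a `subject`.
#' @param strategy one of `"AI"`, `"BR"`, `"BU"`.
#' @param virtual_profile `nig` profile for this subject.
#' @param elicited_prior `nig` elicited prior (used by BR).
#' @param dimension outcome column to predict.
#' @return data.frame with one row per appointment: `appointment`,
#'   `dimension`, `y_true`, `y_hat` (predictive location), `scale_sq`,
#'   `nu`.
#' @export
predict_course <- function(subject, strategy = c("AI", "BR", "BU"),
                           virtual_profile, elicited_prior,
                           dimension = c("score_ina", "score_hyp")) {
  strategy <- match.arg(strategy)
  dimension <- match.arg(dimension)
  X <- make_design(subject$baseline, subject$dosages)
  y <- subject$outcomes[, dimension]
  A <- length(y)
  preds <- vector("list", A)
  state <- virtual_profile
  for (a in seq_len(A)) {
    if (strategy == "BR" && a > 1) {
      seen <- seq_len(a - 1)
      seen <- seen[!is.na(y[seen])]
      state <- nig_update(elicited_prior, X[seen, , drop = FALSE], y[seen])
    }
    preds[[a]] <- posterior_predictive(state, X[a, ])
    if (strategy == "BU" && !is.na(y[a])) {
      state <- nig_update(state, X[a, , drop = FALSE], y[a])
    }
  }
  data.frame(
    appointment = seq_len(A),
    dimension = dimension,
    y_true = as.numeric(y),
    y_hat = vapply(preds, `[[`, numeric(1), "location"),
    scale_sq = vapply(preds, `[[`, numeric(1), "scale_sq"),
    nu = vapply(preds, `[[`, numeric(1), "nu"),
    stringsAsFactors = FALSE)
}

#' Patient-coherent cross-validated prediction
#'
#' For each fold: fits patient models (batch conjugate updates from the
#' elicited prior) for all training subjects, constructs virtual patient
#' profiles for validation subjects from the *training pool only*, and
#' runs [predict_course()] for each validation subject and symptom
#' dimension. No validation outcome influences the pool fitting or the
#' profile mapping.
#'
#' @param cohort a `cohort`.
#' @param prior the elicited `nig` prior.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param method virtual-profile construction, 1 or 2.
#' @param strategy `"AI"`, `"BR"` or `"BU"`.
#' @param lambda,retain_fraction Method 2 kernel settings.
#' @param level central predictive-interval level for the `ci_low`/
#'   `ci_high` columns.
#' @param dimensions outcome columns to predict (default both).
#' @return data.frame of class `crossval_result` with columns
#'   `subject_id`, `appointment`, `dimension`, `y_true`, `y_hat`,
#'   `scale_sq`, `nu`, `ci_low`, `ci_high`, `fold`. The fold assignment is
#'   attached as attribute `folds`.
#' @export
run_crossval <- function(cohort, prior, k = 10, seed = 1, method = 2,
                         strategy = c("AI", "BR", "BU"),
                         lambda = 1.15, retain_fraction = 0.175,
                         level = 0.95,
                         dimensions = c("score_ina", "score_hyp")) {
  strategy <- match.arg(strategy)
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  names(cohort) <- ids
  folds <- make_folds(ids, k = k, seed = seed)
  out <- vector("list", 0)
  for (fold in seq_len(k)) {
    train_ids <- ids[folds != fold]
    val_ids <- ids[folds == fold]
    if (length(train_ids) == 0)
      stop("empty training set in fold ", fold, call. = FALSE)
    for (dimension in dimensions) {
      pool <- fit_patient_pool(cohort[train_ids], prior,
                               dimension = dimension)
      map <- if (method == 1) fit_method1(pool) else NULL
      for (id in val_ids) {
        subj <- cohort[[id]]
        profile <- virtual_profile(pool, subj$baseline, method = method,
                                   lambda = lambda,
                                   retain_fraction = retain_fraction,
                                   map = map)
        pc <- predict_course(subj, strategy = strategy,
                             virtual_profile = profile,
                             elicited_prior = prior,
                             dimension = dimension)
        half <- sqrt(pc$scale_sq) * stats::qt((1 + level) / 2, df = pc$nu)
        pc$ci_low <- pc$y_hat - half
        pc$ci_high <- pc$y_hat + half
        pc <- cbind(subject_id = id, pc, fold = fold,
                    stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- pc
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("crossval_result", "data.frame"),
            folds = folds, strategy = strategy, method = method, k = k,
            seed = seed)
}
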