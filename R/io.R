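#' Write a cohort to CSV
#'
#' Writes the long visit table `visits.csv` (subject_id, appointment,
#' dose_irmph, dose_xrmph, dose_dex, dose_atom, score_ina, score_hyp),
#' the wide baseline table `baselines.csv` (subject_id, f01..fLL) and,
#' when the cohort carries simulation ground truth, `truth.csv` with each
#' subject's response vector.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  visits <- do.call(rbind, lapply(cohort, function(s) {
    data.frame(subject_id = s$subject_id,
               appointment = seq_len(nrow(s$dosages)),
               s$dosages, s$outcomes,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  utils::write.csv(visits, file.path(dir, "visits.csv"), row.names = FALSE)
  L <- length(cohort[[1]]$baseline)
  baselines <- do.call(rbind, lapply(cohort, function(s) {
    b <- as.data.frame(t(s$baseline))
    names(b) <- paste0("f", sprintf("%02d", seq_len(L)))
    cbind(data.frame(subject_id = s$subject_id, stringsAsFactors = FALSE), b)
  }))
  utils::write.csv(baselines, file.path(dir, "baselines.csv"),
                   row.names = FALSE)
  if (!is.null(cohort[[1]]$true_omega)) {
    truth <- do.call(rbind, lapply(cohort, function(s) {
      w <- as.data.frame(t(s$true_omega))
      names(w) <- parameter_names(L)
      cbind(data.frame(subject_id = s$subject_id, stringsAsFactors = FALSE), w)
    }))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from CSV
#'
#' Reads and validates the visit/baseline tables written by
#' [write_cohort()] (or supplied externally in the same schema). Subjects
#' are sorted by id and appointments by index; appointment indices must be
#' contiguous `1..A_s` per subject; doses must be nonnegative; every
#' visit's subject must appear in the baseline table.
#'
#' @param visits_path path to the long visit CSV.
#' @param baselines_path path to the wide baseline CSV.
#' @return A `cohort` (subjects have `true_omega = NULL`).
#' @export
read_cohort <- function(visits_path, baselines_path) {
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE)
  baselines <- utils::read.csv(baselines_path, stringsAsFactors = FALSE)
  dose_cols <- c("dose_irmph", "dose_xrmph", "dose_dex", "dose_atom")
  need_v <- c("subject_id", "appointment", dose_cols,
              "score_ina", "score_hyp")
  miss <- setdiff(need_v, names(visits))
  if (length(miss))
    stop("schema error: visits table missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"subject_id" %in% names(baselines))
    stop("schema error: baselines table missing subject_id", call. = FALSE)
  fac_cols <- grep("^f[0-9]+$", names(baselines), value = TRUE)
  if (!length(fac_cols))
    stop("schema error: baselines table has no factor columns f01..", call. = FALSE)
  dup <- duplicated(visits[c("subject_id", "appointment")])
  if (any(dup))
    stop("schema error: duplicate (subject, appointment) rows at visit rows ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  neg <- which(apply(visits[dose_cols] < 0, 1, any))
  if (length(neg))
    stop("schema error: negative doses at visit rows ",
         paste(neg, collapse = ", "), call. = FALSE)
  orphan <- !visits$subject_id %in% baselines$subject_id
  if (any(orphan))
    stop("schema error: visit rows ",
         paste(which(orphan), collapse = ", "),
         " reference subjects absent from the baseline table", call. = FALSE)
  ids <- sort(unique(visits$subject_id))
  cohort <- lapply(ids, function(id) {
    v <- visits[visits$subject_id == id, , drop = FALSE]
    v <- v[order(v$appointment), , drop = FALSE]
    if (!identical(as.integer(v$appointment), seq_len(nrow(v))))
      stop("schema error: subject ", id,
           " has non-contiguous appointment indices", call. = FALSE)
    b <- baselines[match(id, baselines$subject_id), fac_cols]
    structure(list(subject_id = id,
                   baseline = as.numeric(b),
                   dosages = as.matrix(v[dose_cols]),
                   outcomes = as.matrix(v[c("score_ina", "score_hyp")]),
                   true_omega = NULL),
              class = "subject")
  })
  structure(cohort, class = "cohort")
}

#' Run the full simulate / elicit / cross-validate / evaluate pipeline
#'
#' Binds the pipeline stages behind one seeded, deterministic entry point:
#' simulate (or read) a cohort, build the elicited prior from an evidence
#' table (or the uninformed default), run patient-coherent k-fold
#' cross-validated prediction for the requested strategy and profile
#' method, and evaluate both symptom dimensions. Writes `predictions.csv`,
#' `metrics.json`, per-dimension ROC TSVs, the fitted prior and a run
#' manifest into `out_dir`.
#'
#' @param config named list (or path to a YAML file) with any of:
#'   `n_subjects` (default 150), `seed` (default 1), `k` (default 10),
#'   `method` (1 or 2, default 2), `strategy` ("AI"/"BR"/"BU", default
#'   "BU"), `lambda`, `retain_fraction`, `thresholds` (length-2),
#'   `evidence` (path, `"default"`, or `NULL` for uninformed),
#'   `visits`/`baselines` (paths; read instead of simulating),
#'   `sweep_type` ("quantile"/"additive").
#' @param out_dir output directory.
#' @return Invisibly, a list with `predictions`, `evaluation` (per
#'   dimension) and `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = "modelspace-run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    n_subjects = 150L, seed = 1L, k = 10L, method = 2L, strategy = "BU",
    lambda = 1.15, retain_fraction = 0.175,
    thresholds = c(-0.97, -0.92), evidence = "default",
    visits = NULL, baselines = NULL, sweep_type = "quantile"),
    config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$visits)) {
    cohort <- read_cohort(cfg$visits, cfg$baselines)
  } else {
    cohort <- generate_cohort(cohort_config(
      n_subjects = cfg$n_subjects, seed = cfg$seed,
      remission_thresholds = cfg$thresholds))
  }
  L <- length(cohort[[1]]$baseline)

  evidence <- if (is.null(cfg$evidence)) NULL
              else if (identical(cfg$evidence, "default")) default_evidence()
              else read_evidence(cfg$evidence)
  prior <- build_prior(evidence, parameter_names(L))
  nig_to_json(prior, file.path(out_dir, "prior.json"))

  result <- run_crossval(cohort, prior, k = cfg$k, seed = cfg$seed,
                         method = cfg$method, strategy = cfg$strategy,
                         lambda = cfg$lambda,
                         retain_fraction = cfg$retain_fraction)
  utils::write.csv(result, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)

  dims <- c(score_ina = cfg$thresholds[1], score_hyp = cfg$thresholds[2])
  evaluation <- lapply(seq_along(dims), function(i) {
    ev <- evaluate_crossval(result, dimension = names(dims)[i],
                            threshold = dims[i], type = cfg$sweep_type)
    utils::write.table(
      ev$roc$points[c("fpr", "tpr", "critical")],
      file.path(out_dir, paste0("roc_", names(dims)[i], ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    ev
  })
  names(evaluation) <- names(dims)

  metrics <- lapply(evaluation, function(ev)
    list(rms = ev$rms, prevalence = ev$prevalence,
         confusion = unclass(ev$confusion), metrics = ev$metrics,
         auc = ev$roc$auc))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  manifest <- list(
    package_version = as.character(utils::packageVersion("modelspace")),
    config = cfg[c("n_subjects", "seed", "k", "method", "strategy",
                   "lambda", "retain_fraction", "sweep_type")],
    thresholds = cfg$thresholds,
    folds = as.list(attr(result, "folds")),
    n_visits = nrow(result) / 2L)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(predictions = result, evaluation = evaluation,
                 manifest = manifest))
}
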