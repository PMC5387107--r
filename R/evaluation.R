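#' Cross-validated root-mean-squared prediction error
#'
#' The regression error pools appointments within subject first (each
#' subject's squared errors are averaged over their own appointments, so
#' subjects with long courses do not dominate), then averages over
#' subjects and folds, and finally takes the square root:
#' `rms = sqrt( (1/K) sum_k (1/|S_k|) sum_s (1/A_s) sum_a (y - yhat)^2 )`.
#'
#' @param y_true,y_hat numeric vectors of observed and predicted scores.
#' @param subject_id subject identifier per element.
#' @param fold fold index per element (default: all one fold).
#' @return The rms error (scalar, on the scale of the symptom scores).
#' @examples
#' # two subjects with per-subject mean squared errors 1 and 9 -> sqrt(5)
#' rms_error(c(0, 0), c(1, 3), subject_id = c("a", "b"))
#' @export
rms_error <- function(y_true, y_hat, subject_id, fold = NULL) {
  if (length(y_true) == 0) stop("no predictions supplied", call. = FALSE)
  stopifnot(length(y_hat) == length(y_true),
            length(subject_id) == length(y_true))
  if (is.null(fold)) fold <- rep(1L, length(y_true))
  sq <- (y_true - y_hat)^2
  per_subject <- tapply(sq, list(fold = fold, subject = subject_id), mean)
  per_fold <- apply(per_subject, 1, mean, na.rm = TRUE)
  sqrt(mean(per_fold))
}

#' @rdname rms_error
#' @param result a `crossval_result` from [run_crossval()].
#' @param dimension outcome column to score (one at a time).
#' @return `rms_crossval`: the rms error for one dimension.
#' @export
rms_crossval <- function(result, dimension = "score_ina") {
  r <- result[result$dimension == dimension, , drop = FALSE]
  rms_error(r$y_true, r$y_hat, r$subject_id, r$fold)
}

#' Dichotomous remission classification with a critical value
#'
#' A case is classified as remission iff
#' `point_estimate - critical_value <= threshold` (the boundary is
#' inclusive, matching the inclusive remission labeling rule). With
#' `critical_value = 0` this is plain point-estimate thresholding; larger
#' critical values classify more cases into remission, raising
#' sensitivity at the cost of specificity.
#'
#' Negative critical values are admitted for the ROC sweep (they tighten
#' the remission call, tracing the curve below the `c = 0` operating
#' point); operating points selected for deployment use the nonnegative
#' range.
#'
#' @param point_estimate numeric vector of predicted symptom scores.
#' @param threshold remission threshold on the symptom score.
#' @param critical_value offset (scalar or per-case vector).
#' @return Logical vector, `TRUE` = predicted remission.
#' @export
classify_remission <- function(point_estimate, threshold,
                               critical_value = 0) {
  (point_estimate - critical_value) <= threshold
}

#' Confusion matrix from binary truth and prediction
#'
#' @param truth logical/0-1 vector, `TRUE` = remission observed.
#' @param predicted logical/0-1 vector, `TRUE` = remission predicted.
#' @return A list of class `confusion` with counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  stopifnot(length(truth) == length(predicted))
  structure(list(tp = sum(truth & predicted),
                 fp = sum(!truth & predicted),
                 fn = sum(truth & !predicted),
                 tn = sum(!truth & !predicted)),
            class = "confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, balanced accuracy
#' `(sen+spc)/2`, positive/negative predictive values, overall accuracy
#' and Youden's J (`sen + spc - 1`). A metric whose denominator is zero is
#' reported as `NA` (explicitly undefined, never silently dropped).
#'
#' @param cm a `confusion` object, or a list/vector with elements
#'   `tp`, `fp`, `fn`, `tn`.
#' @return Named list: `sen`, `spc`, `bac`, `ppv`, `npv`, `accuracy`,
#'   `youden_j`.
#' @examples
#' m <- confusion_metrics(list(tp = 93, fp = 327, fn = 67, tn = 660))
#' round(100 * m$sen, 1)  # 58.1
#' @export
confusion_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  if (any(c(tp, fp, fn, tn) < 0))
    stop("confusion counts must be nonnegative", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sen <- ratio(tp, tp + fn)
  spc <- ratio(tn, tn + fp)
  list(sen = sen, spc = spc,
       bac = (sen + spc) / 2,
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn),
       accuracy = ratio(tp + tn, tp + fp + fn + tn),
       youden_j = sen + spc - 1)
}

# Per-case critical values for a grid parameter value.
# type "additive": the grid value is the critical value c itself, shared.
# type "quantile": the grid value is a probability level x in (0, 1); the
#   critical value is the offset from the predictive location to its lower
#   x-quantile bound, c_i = scale_i * qt(x, nu_i), so cases with more
#   predictive uncertainty get larger offsets (negative below x = 0.5).
.critical_values <- function(param, type, scale_sq = NULL, nu = NULL, n = 1) {
  if (type == "additive") return(rep(param, length.out = n))
  if (is.null(scale_sq) || is.null(nu))
    stop("quantile grid requires scale_sq and nu per case", call. = FALSE)
  sqrt(scale_sq) * stats::qt(pmin(pmax(param, 1e-12), 1 - 1e-12), df = nu)
}

# ROC sweep grid. The full grid spans both signs so the curve reaches
# (0,0) and (1,1); nonneg = TRUE restricts to the deployable range (the
# point-estimate operating point and looser).
.default_grid <- function(type, point_estimate, threshold, n_grid = 101,
                          nonneg = FALSE) {
  if (type == "quantile") {
    lo <- if (nonneg) 0.5 else 0.001
    return(seq(lo, 0.999, length.out = n_grid))
  }
  gaps <- sort(unique(point_estimate - threshold))
  mids <- if (length(gaps) > 1) (gaps[-1] + gaps[-length(gaps)]) / 2 else numeric(0)
  cand <- sort(unique(c(0, gaps, mids,
                        min(gaps) - 1, max(gaps) + 1)))
  if (nonneg) cand <- cand[cand >= 0]
  cand
}

#' ROC curve over the critical-value sweep
#'
#' Sweeps the critical value over a grid, classifying each case via
#' [classify_remission()] and collecting (false positive rate, true
#' positive rate) points; the area under the curve is computed by the
#' trapezoidal rule with endpoints (0,0) and (1,1) appended.
#'
#' Two sweep parameterizations are provided: `"quantile"` (default), in
#' which the grid is a probability level and each case's critical value is
#' its own predictive lower-bound offset (uncertainty-aware,
#' subject-specific); and `"additive"`, a shared offset subtracted from
#' every point estimate.
#'
#' @param point_estimate predicted symptom scores.
#' @param label logical/0-1 observed remission labels (both classes must
#'   be present).
#' @param threshold remission threshold.
#' @param grid numeric grid of sweep parameter values; defaults to 101
#'   quantile levels, or (additive) all distinct score gaps.
#' @param type `"quantile"` or `"additive"`.
#' @param scale_sq,nu per-case predictive squared scale and degrees of
#'   freedom (required for the quantile sweep).
#' @return A list of class `roc_curve` with `points` (data.frame
#'   `critical`, `fpr`, `tpr`, `sen`, `spc`, `bac`) and `auc`.
#' @export
roc_curve <- function(point_estimate, label, threshold, grid = NULL,
                      type = c("quantile", "additive"),
                      scale_sq = NULL, nu = NULL) {
  type <- match.arg(type)
  label <- as.logical(label)
  if (all(label) || !any(label))
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  if (is.null(grid))
    grid <- .default_grid(type, point_estimate, threshold)
  pts <- lapply(grid, function(g) {
    cv <- .critical_values(g, type, scale_sq, nu, length(point_estimate))
    m <- confusion_metrics(confusion_matrix(
      label, classify_remission(point_estimate, threshold, cv)))
    data.frame(critical = g, fpr = 1 - m$spc, tpr = m$sen,
               sen = m$sen, spc = m$spc, bac = m$bac)
  })
  pts <- do.call(rbind, pts)
  o <- order(pts$fpr, pts$tpr)
  fpr <- c(0, pts$fpr[o], 1)
  tpr <- c(0, pts$tpr[o], 1)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = pts, auc = auc, type = type,
                 threshold = threshold),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve (", x$type, " sweep, ", nrow(x$points),
      " points): AUC = ", format(round(100 * x$auc, 1)), "%\n", sep = "")
  invisible(x)
}

#' Select the operating point maximizing training balanced accuracy
#'
#' Sweeps the same grid as [roc_curve()] on *training* predictions and
#' returns the grid value with the highest balanced accuracy (equivalent
#' to maximizing Youden's J); ties are broken toward the smaller critical
#' value. The default grid is restricted to the nonnegative (deployable)
#' range: an operating point only loosens the point-estimate rule toward
#' sensitivity. The selected setting is then applied unchanged to
#' validation data, so validation outcomes never tune the classifier.
#'
#' @inheritParams roc_curve
#' @return A list of class `operating_point` with `critical` (grid value),
#'   `type`, `threshold` and the achieved training `bac`.
#' @export
select_operating_point <- function(point_estimate, label, threshold,
                                   grid = NULL,
                                   type = c("quantile", "additive"),
                                   scale_sq = NULL, nu = NULL) {
  type <- match.arg(type)
  if (is.null(grid))
    grid <- .default_grid(type, point_estimate, threshold, nonneg = TRUE)
  roc <- roc_curve(point_estimate, label, threshold, grid = grid,
                   type = type, scale_sq = scale_sq, nu = nu)
  pts <- roc$points
  best <- which(pts$bac == max(pts$bac, na.rm = TRUE))
  best <- best[which.min(pts$critical[best])]
  structure(list(critical = pts$critical[best], type = type,
                 threshold = threshold, bac = pts$bac[best]),
            class = "operating_point")
}

#' Expected hit rates of a random-guess null model
#'
#' A guesser that predicts remission independently with probability equal
#' to the prevalence has expected sensitivity equal to the prevalence and
#' expected specificity equal to one minus the prevalence.
#'
#' @param prevalence remission prevalence, strictly between 0 and 1.
#' @return List with `sen` and `spc`.
#' @examples
#' null_model_rates(0.1395)  # sen 13.95%, spc 86.05%
#' @export
null_model_rates <- function(prevalence) {
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must be strictly between 0 and 1", call. = FALSE)
  list(sen = prevalence, spc = 1 - prevalence)
}

#' Evaluate a cross-validation result for one dimension
#'
#' Computes the rms error and the remission-classification summary. The
#' operating point for each fold is chosen by maximizing balanced accuracy
#' on the predictions of all *other* folds and applied unchanged to the
#' fold being scored, so no fold's own outcomes tune its classifier; the
#' per-fold classifications are then pooled into one confusion matrix.
#' The ROC/AUC is computed on the pooled predictions over the full
#' critical-value sweep.
#'
#' @param result a `crossval_result`.
#' @param dimension outcome column.
#' @param threshold remission threshold for this dimension.
#' @param type sweep parameterization (see [roc_curve()]).
#' @return List with `rms`, `prevalence`, `confusion`, `metrics`,
#'   `operating_point`s per fold, and `roc` (pooled).
#' @export
evaluate_crossval <- function(result, dimension = "score_ina",
                              threshold = -0.97,
                              type = c("quantile", "additive")) {
  type <- match.arg(type)
  r <- result[result$dimension == dimension, , drop = FALSE]
  label <- r$y_true <= threshold
  rms <- rms_error(r$y_true, r$y_hat, r$subject_id, r$fold)
  roc <- roc_curve(r$y_hat, label, threshold, type = type,
                   scale_sq = r$scale_sq, nu = r$nu)
  pred <- logical(nrow(r))
  ops <- list()
  for (fold in sort(unique(r$fold))) {
    sel <- r$fold == fold
    if (all(label[!sel]) || !any(label[!sel])) {
      # degenerate held-out selection set: fall back to zero critical value
      op <- structure(list(critical = if (type == "quantile") 0.5 else 0,
                           type = type, threshold = threshold,
                           bac = NA_real_),
                      class = "operating_point")
    } else {
      op <- select_operating_point(r$y_hat[!sel], label[!sel], threshold,
                                   type = type,
                                   scale_sq = r$scale_sq[!sel],
                                   nu = r$nu[!sel])
    }
    cv <- .critical_values(op$critical, type, r$scale_sq[sel], r$nu[sel],
                           sum(sel))
    pred[sel] <- classify_remission(r$y_hat[sel], threshold, cv)
    ops[[as.character(fold)]] <- op
  }
  cm <- confusion_matrix(label, pred)
  list(rms = rms,
       prevalence = mean(label),
       confusion = cm,
       metrics = confusion_metrics(cm),
       operating_points = ops,
       roc = roc)
}
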