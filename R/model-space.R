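#' Half-vectorize a symmetric matrix
#'
#' A symmetric P x P matrix is fully determined by its diagonal plus one
#' triangle, a vector of length `P(P+1)/2`. The order is the upper
#' triangle, row-major (fixed for serialization stability).
#'
#' @param M symmetric matrix.
#' @param tol relative symmetry tolerance.
#' @return Numeric vector of length `P(P+1)/2`.
#' @examples
#' half_vectorize(diag(3))  # 1 0 0 1 0 1
#' @export
half_vectorize <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M))
    stop("matrix must be square", call. = FALSE)
  sc <- max(1, max(abs(M)))
  if (max(abs(M - t(M))) > tol * sc)
    stop("matrix is not symmetric within tolerance", call. = FALSE)
  # column-major lower triangle of a symmetric matrix == row-major upper
  M[lower.tri(M, diag = TRUE)]
}

#' Reconstruct a symmetric matrix from its half-vectorization
#'
#' Exact inverse of [half_vectorize()].
#'
#' @param u vector of length `P(P+1)/2`.
#' @return The symmetric P x P matrix.
#' @export
reconstruct_symmetric <- function(u) {
  m <- length(u)
  P <- (sqrt(8 * m + 1) - 1) / 2
  if (P != round(P))
    stop("length ", m, " is not a triangular number", call. = FALSE)
  P <- as.integer(P)
  M <- matrix(0, P, P)
  M[lower.tri(M, diag = TRUE)] <- u
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

#' Repair a nearly positive-semidefinite matrix
#'
#' Symmetrizes, then clips eigenvalues below `floor` up to `floor`. Used
#' after the linear profile reconstruction, which can leave the covariance
#' scale slightly indefinite.
#'
#' @param M square matrix.
#' @param floor eigenvalue floor (default 1e-8).
#' @return A symmetric positive-definite matrix.
#' @export
psd_repair <- function(M, floor = 1e-8) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  (out + t(out)) / 2
}

#' Fit a patient model
#'
#' Trains one subject's Normal-Inverse-Gamma posterior by a batch
#' conjugate update of the elicited prior on all of the subject's
#' appointments for one symptom dimension, and pairs it with the
#' subject's baseline factors. A pool of such models is the "model space"
#' from which profiles for new patients are constructed.
#'
#' @param subject a `subject` (see [generate_cohort()] / [read_cohort()]).
#' @param prior the elicited `nig` prior.
#' @param dimension outcome column, `"score_ina"` or `"score_hyp"`.
#' @return A list of class `patient_model` with `subject_id`, `baseline`
#'   and `posterior`.
#' @export
fit_patient_model <- function(subject, prior,
                              dimension = c("score_ina", "score_hyp")) {
  dimension <- match.arg(dimension)
  X <- make_design(subject$baseline, subject$dosages)
  y <- subject$outcomes[, dimension]
  keep <- !is.na(y)
  structure(list(subject_id = subject$subject_id,
                 baseline = subject$baseline,
                 posterior = nig_update(prior, X[keep, , drop = FALSE],
                                        y[keep])),
            class = "patient_model")
}

#' @rdname fit_patient_model
#' @param cohort a `cohort` (list of subjects).
#' @return `fit_patient_pool`: a list of `patient_model`s.
#' @export
fit_patient_pool <- function(cohort, prior,
                             dimension = c("score_ina", "score_hyp")) {
  dimension <- match.arg(dimension)
  lapply(cohort, fit_patient_model, prior = prior, dimension = dimension)
}

# Moore-Penrose least-squares solve of B Q = Y via SVD with singular value
# truncation; warns when B'B is rank deficient.
.pinv_solve <- function(B, Y, context = "profile map") {
  sv <- svd(B)
  tol <- max(dim(B)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  if (!all(pos))
    warning(context, ": rank-deficient baseline matrix (rank ", sum(pos),
            " of ", ncol(B), "); pseudo-inverse via singular-value truncation",
            call. = FALSE)
  d_inv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (d_inv * crossprod(sv$u, Y))
}

# optional polynomial expansion of the baseline vector/matrix (elementwise
# powers 1..degree); degree 1 is the identity
.poly_features <- function(B, degree) {
  if (degree <= 1) return(B)
  do.call(cbind, lapply(seq_len(degree), function(d) B^d))
}

#' Method 1: linear mapping from baselines to the model space
#'
#' Learns least-squares linear maps from baseline factor vectors to the
#' pooled subjects' posterior means (`Q_tau`) and to the half-vectorized
#' posterior covariance scales (`Q_u`), solved by the Moore-Penrose
#' pseudo-inverse `Q = (B'B)^{-1} B'Y`. The noise hyperparameters of the
#' profile are the pool averages of `alpha` and `beta`.
#'
#' Polynomial basis expansion (elementwise powers of the baselines) is
#' available behind `degree` but defaults off: higher degrees fit the
#' training pool more closely at the cost of generalization.
#'
#' @param pool list of `patient_model`s (the training pool).
#' @param degree polynomial degree for the baseline features (default 1,
#'   plain linear).
#' @return A list of class `profile_map` with `Q_tau`, `Q_u`,
#'   `alpha_star`, `beta_star`, `degree`.
#' @export
fit_method1 <- function(pool, degree = 1) {
  if (length(pool) < 1) stop("pool must be nonempty", call. = FALSE)
  B <- .poly_features(do.call(rbind, lapply(pool, `[[`, "baseline")), degree)
  Y_tau <- do.call(rbind, lapply(pool, function(m) m$posterior$tau))
  Y_u <- do.call(rbind, lapply(pool, function(m)
    half_vectorize(m$posterior$lambda_inv)))
  structure(list(
    Q_tau = .pinv_solve(B, Y_tau, "tau map"),
    Q_u = .pinv_solve(B, Y_u, "covariance map"),
    alpha_star = mean(vapply(pool, function(m) m$posterior$alpha, numeric(1))),
    beta_star = mean(vapply(pool, function(m) m$posterior$beta, numeric(1))),
    degree = degree),
    class = "profile_map")
}

#' Apply a Method 1 profile map to a new patient's baselines
#'
#' Evaluates the fitted linear maps at `b_star`, reconstructs the
#' covariance scale from its half-vectorization and repairs it to positive
#' definiteness (the linear reconstruction can be slightly indefinite).
#'
#' @param map a `profile_map` from [fit_method1()].
#' @param b_star numeric L-vector of the new patient's baseline factors.
#' @return A `nig` virtual patient profile.
#' @export
apply_method1 <- function(map, b_star) {
  stopifnot(inherits(map, "profile_map"))
  b <- .poly_features(matrix(as.numeric(b_star), nrow = 1), map$degree)
  tau <- drop(b %*% map$Q_tau)
  lambda_inv <- psd_repair(reconstruct_symmetric(drop(b %*% map$Q_u)))
  nig_state(tau, lambda_inv, map$alpha_star, map$beta_star)
}

#' Method 2: Gaussian-kernel weighted model averaging
#'
#' Builds a virtual patient profile as a weighted average of the fitted
#' models of the training subjects most similar to the new patient.
#' Dissimilarity is the Euclidean distance between baseline factor
#' vectors; the `retain_fraction` of subjects with the smallest distances
#' are kept (ceiling, floor of one subject, boundary ties all kept) and
#' weighted by a normalized Gaussian kernel `w_s ~ exp(-lambda d_s)`.
#' All four belief components (`tau`, `lambda_inv`, `alpha`, `beta`) are
#' the weighted averages over the retained subjects, so the result is a
#' convex combination of valid states and needs no repair.
#'
#' @param pool list of `patient_model`s.
#' @param b_star numeric L-vector of the new patient's baseline factors.
#' @param lambda kernel decay rate (default 1.15).
#' @param retain_fraction fraction of the pool retained (default 0.175).
#' @return A `nig` virtual patient profile; the retained subject ids and
#'   weights are attached as attribute `weights`.
#' @export
method2_profile <- function(pool, b_star, lambda = 1.15,
                            retain_fraction = 0.175) {
  if (length(pool) < 1) stop("pool must be nonempty", call. = FALSE)
  if (!(lambda > 0)) stop("lambda must be > 0", call. = FALSE)
  if (!(retain_fraction > 0 && retain_fraction <= 1))
    stop("retain_fraction must be in (0, 1]", call. = FALSE)
  b_star <- as.numeric(b_star)
  d <- vapply(pool, function(m) sqrt(sum((b_star - m$baseline)^2)),
              numeric(1))
  m_keep <- max(1L, ceiling(retain_fraction * length(pool)))
  cutoff <- sort(d)[m_keep]
  keep <- which(d <= cutoff)           # boundary ties all kept
  w <- exp(-lambda * d[keep])
  w <- w / sum(w)
  P <- length(pool[[1]]$posterior$tau)
  tau <- rep(0, P); lam <- matrix(0, P, P); a <- 0; b <- 0
  for (i in seq_along(keep)) {
    post <- pool[[keep[i]]]$posterior
    tau <- tau + w[i] * post$tau
    lam <- lam + w[i] * post$lambda_inv
    a <- a + w[i] * post$alpha
    b <- b + w[i] * post$beta
  }
  out <- nig_state(tau, lam, a, b)
  attr(out, "weights") <- stats::setNames(
    w, vapply(pool[keep], `[[`, character(1), "subject_id"))
  out
}

#' Construct a virtual patient profile
#'
#' Dispatches to [fit_method1()]/[apply_method1()] (`method = 1`) or
#' [method2_profile()] (`method = 2`).
#'
#' @param pool list of `patient_model`s (the training pool).
#' @param b_star new patient's baseline factor vector.
#' @param method 1 (linear map) or 2 (kernel averaging).
#' @param lambda,retain_fraction Method 2 kernel settings.
#' @param map optionally, a prefitted `profile_map` for Method 1 (avoids
#'   refitting per patient).
#' @return A `nig` virtual patient profile.
#' @export
virtual_profile <- function(pool, b_star, method = 2, lambda = 1.15,
                            retain_fraction = 0.175, map = NULL) {
  if (method == 1) {
    if (is.null(map)) map <- fit_method1(pool)
    apply_method1(map, b_star)
  } else if (method == 2) {
    method2_profile(pool, b_star, lambda = lambda,
                    retain_fraction = retain_fraction)
  } else stop("method must be 1 or 2", call. = FALSE)
}

#' Serialize a patient-model pool as JSON lines
#'
#' One `patient_model` per line; exact double-precision round-trip.
#'
#' @param pool list of `patient_model`s.
#' @param path output file.
#' @export
pool_to_jsonl <- function(pool, path) {
  lines <- vapply(pool, function(m) {
    as.character(jsonlite::toJSON(list(
      subject_id = m$subject_id,
      baseline = m$baseline,
      posterior = list(tau = unname(m$posterior$tau),
                       lambda_inv = as.numeric(t(m$posterior$lambda_inv)),
                       P = length(m$posterior$tau),
                       alpha = m$posterior$alpha,
                       beta = m$posterior$beta)),
      digits = I(17), auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pool_to_jsonl
#' @export
pool_from_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    obj <- jsonlite::fromJSON(line)
    P <- obj$posterior$P
    structure(list(
      subject_id = obj$subject_id,
      baseline = obj$baseline,
      posterior = nig_state(obj$posterior$tau,
                            matrix(obj$posterior$lambda_inv, P, byrow = TRUE),
                            obj$posterior$alpha, obj$posterior$beta)),
      class = "patient_model")
  })
}
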