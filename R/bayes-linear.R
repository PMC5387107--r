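#' Assemble a subject's design matrix
#'
#' Builds the appointment-by-parameter design matrix whose rows are
#' `[baseline factors | four medication dosages | 1]`. The baseline block is
#' identical in every row (baseline characteristics do not change over
#' appointments) while the medication block follows the titration regime.
#' The parameter dimension is `P = L + 4 + 1`, i.e. 19 for the default
#' L = 14 latent factors.
#'
#' @param baseline numeric L-vector of baseline latent factor scores.
#' @param dosages numeric n x 4 matrix of equivalent daily doses (columns
#'   IR-MPH, XR-MPH, DEX, ATOM).
#' @return n x P design matrix with column order
#'   `[baseline(1..L), medications(1..4), intercept]`.
#' @examples
#' X <- make_design(rnorm(14), matrix(10, nrow = 3, ncol = 4))
#' dim(X)  # 3 x 19
#' @export
make_design <- function(baseline, dosages) {
  baseline <- as.numeric(baseline)
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != 4)
    stop("dosages must have 4 columns (IR-MPH, XR-MPH, DEX, ATOM)", call. = FALSE)
  if (anyNA(baseline) || anyNA(dosages) || any(!is.finite(baseline)) ||
      any(!is.finite(dosages)))
    stop("baseline and dosages must be finite with no missing values",
         call. = FALSE)
  n <- nrow(dosages)
  L <- length(baseline)
  X <- cbind(matrix(baseline, nrow = n, ncol = L, byrow = TRUE),
             dosages, rep(1, n))
  colnames(X) <- c(paste0("f", sprintf("%02d", seq_len(L))),
                   "med_irmph", "med_xrmph", "med_dex", "med_atom",
                   "intercept")
  X
}

# Invert a symmetric PSD matrix; add diagonal jitter (1e-8 * trace / P)
# if the Cholesky fails, with a warning.
.sym_inverse <- function(M, context = "matrix") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- 1e-8 * sum(diag(M)) / nrow(M)
    if (!is.finite(jitter) || jitter <= 0) jitter <- 1e-10
    warning(context, " numerically singular; adding diagonal jitter ",
            format(jitter), call. = FALSE)
    ch <- chol(M + diag(jitter, nrow(M)))
  }
  chol2inv(ch)
}

#' Conjugate Normal-Inverse-Gamma posterior update
#'
#' Updates a `nig` belief state with a block of observed appointments via
#' the standard conjugate update for Bayesian linear regression:
#' `Lambda_n = Lambda_0 + X'X`, `tau_n = Lambda_n^{-1}(Lambda_0 tau_0 + X'y)`,
#' `alpha_n = alpha_0 + n/2`,
#' `beta_n = beta_0 + (y'y + tau_0' Lambda_0 tau_0 - tau_n' Lambda_n tau_n)/2`.
#' Updating with an empty block is the identity; sequential one-row updates
#' are algebraically identical to a single batch update.
#'
#' @param state a `nig` prior or posterior.
#' @param X n x P design matrix (see [make_design()]); `n = 0` allowed.
#' @param y numeric n-vector of observed symptom scores (one dimension).
#' @return The updated `nig` state.
#' @examples
#' prior <- nig_state(0, matrix(1), alpha = 1, beta = 1)
#' nig_update(prior, matrix(1), 2)  # tau 1, lambda_inv 0.5, alpha 1.5, beta 2
#' @export
nig_update <- function(state, X, y) {
  validate_nig(state)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (n == 0 || nrow(X) == 0) return(state)
  if (nrow(X) != n)
    stop("X and y disagree on the number of appointments", call. = FALSE)
  if (ncol(X) != length(state$tau))
    stop("X has ", ncol(X), " columns but the state has P = ",
         length(state$tau), call. = FALSE)
  if (anyNA(X) || anyNA(y))
    stop("X and y must not contain missing values", call. = FALSE)
  lambda0 <- .sym_inverse(state$lambda_inv, "prior covariance scale")
  lambda_n <- lambda0 + crossprod(X)
  lambda_n <- (lambda_n + t(lambda_n)) / 2
  lambda_n_inv <- .sym_inverse(lambda_n, "updated precision")
  lambda_n_inv <- (lambda_n_inv + t(lambda_n_inv)) / 2
  tau0 <- state$tau
  tau_n <- drop(lambda_n_inv %*% (lambda0 %*% tau0 + crossprod(X, y)))
  alpha_n <- state$alpha + n / 2
  beta_n <- state$beta + 0.5 * (sum(y * y) +
    drop(crossprod(tau0, lambda0 %*% tau0)) -
    drop(crossprod(tau_n, lambda_n %*% tau_n)))
  # guard against rounding pushing beta to or below zero in noiseless fits
  beta_n <- max(beta_n, .Machine$double.xmin)
  nig_state(tau_n, lambda_n_inv, alpha_n, beta_n)
}

#' Student-t posterior predictive distribution
#'
#' For a hypothetical appointment row `x`, the predicted symptom score has a
#' location-scale Student-t distribution with location `x tau`, squared
#' scale `(beta/alpha) (1 + x lambda_inv x')` and degrees of freedom
#' `nu = 2 alpha`.
#'
#' @param state a `nig` state (posterior or virtual profile).
#' @param x numeric P-vector, one design row.
#' @return An object of class `pred_dist` with elements `location`,
#'   `scale_sq` and `nu`.
#' @export
posterior_predictive <- function(state, x) {
  validate_nig(state)
  x <- as.numeric(x)
  if (length(x) != length(state$tau))
    stop("x has length ", length(x), " but the state has P = ",
         length(state$tau), call. = FALSE)
  q <- drop(crossprod(x, state$lambda_inv %*% x))
  structure(
    list(location = drop(sum(x * state$tau)),
         scale_sq = (state$beta / state$alpha) * (1 + q),
         nu = 2 * state$alpha),
    class = "pred_dist")
}

#' @export
print.pred_dist <- function(x, ...) {
  cat("Student-t predictive: location ", format(x$location),
      ", scale^2 ", format(x$scale_sq), ", nu ", format(x$nu), "\n", sep = "")
  invisible(x)
}

#' Central predictive interval
#'
#' Central interval of the location-scale Student-t posterior predictive,
#' symmetric about the location.
#'
#' @param dist a `pred_dist` object.
#' @param level coverage level in `[0, 1)`; `0` gives the degenerate point
#'   interval at the location.
#' @return Numeric vector `c(low, high)`.
#' @export
predictive_interval <- function(dist, level = 0.95) {
  stopifnot(inherits(dist, "pred_dist"))
  if (!is.numeric(level) || length(level) != 1 || level < 0 || level >= 1)
    stop("level must be a single value in [0, 1)", call. = FALSE)
  half <- sqrt(dist$scale_sq) * stats::qt((1 + level) / 2, df = dist$nu)
  c(low = dist$location - half, high = dist$location + half)
}
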