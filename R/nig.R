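#' Normal-Inverse-Gamma belief state
#'
#' The conjugate belief state for Bayesian linear regression with unknown
#' noise variance: `omega | sigma2 ~ N(tau, sigma2 * lambda_inv)` and
#' `sigma2 ~ Inv-Gamma(alpha, beta)`. A `nig` object represents either a
#' prior (elicited or uninformed) or a posterior after observing
#' appointment data, and also serves as a *virtual patient profile* when
#' estimated for a new patient from baselines alone.
#'
#' @param tau numeric P-vector, mean of the response-vector belief.
#' @param lambda_inv symmetric positive-semidefinite P x P matrix, the
#'   covariance scale of the response-vector belief.
#' @param alpha,beta positive scalars, Inverse-Gamma shape and rate for the
#'   noise variance.
#' @return An object of class `nig` with elements `tau`, `lambda_inv`,
#'   `alpha`, `beta`.
#' @examples
#' prior <- nig_state(rep(0, 3), diag(3), alpha = 1, beta = 1)
#' prior
#' @export
nig_state <- function(tau, lambda_inv, alpha, beta) {
  nms <- names(tau)
  tau <- as.numeric(tau)
  names(tau) <- nms
  lambda_inv <- as.matrix(lambda_inv)
  state <- structure(
    list(tau = tau, lambda_inv = lambda_inv,
         alpha = as.numeric(alpha), beta = as.numeric(beta)),
    class = "nig")
  validate_nig(state)
  state
}

#' Validate a Normal-Inverse-Gamma state
#'
#' Checks symmetry (within tolerance) and positive-semidefiniteness of the
#' covariance scale, positivity of `alpha` and `beta`, and dimensional
#' consistency.
#'
#' @param state a `nig` object.
#' @param tol symmetry / eigenvalue tolerance.
#' @return `state`, invisibly; errors if invalid.
#' @export
validate_nig <- function(state, tol = 1e-8) {
  stopifnot(inherits(state, "nig"))
  P <- length(state$tau)
  if (!is.numeric(state$tau) || anyNA(state$tau))
    stop("tau must be numeric with no missing values", call. = FALSE)
  L <- state$lambda_inv
  if (!is.matrix(L) || nrow(L) != P || ncol(L) != P)
    stop("lambda_inv must be a ", P, " x ", P, " matrix", call. = FALSE)
  sc <- max(1, max(abs(L)))
  if (max(abs(L - t(L))) > tol * sc)
    stop("lambda_inv is not symmetric within tolerance", call. = FALSE)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * sc)
    stop("lambda_inv is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  if (!(state$alpha > 0)) stop("alpha must be > 0", call. = FALSE)
  if (!(state$beta > 0)) stop("beta must be > 0", call. = FALSE)
  invisible(state)
}

#' @export
print.nig <- function(x, ...) {
  cat("Normal-Inverse-Gamma state (P = ", length(x$tau), ")\n", sep = "")
  cat("  alpha = ", format(x$alpha), ", beta = ", format(x$beta), "\n", sep = "")
  cat("  tau:  ", paste(format(x$tau, digits = 3), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Serialize / deserialize a `nig` state as JSON
#'
#' The covariance scale is stored row-major; round-trips are exact for
#' double precision values (`digits = NA`).
#'
#' @param state a `nig` object.
#' @param path file path; for `nig_to_json`, `NULL` returns the JSON string.
#' @return `nig_to_json`: the path (or JSON string) invisibly;
#'   `nig_from_json`: a `nig` object.
#' @export
nig_to_json <- function(state, path = NULL) {
  validate_nig(state)
  obj <- list(tau = unname(state$tau),
              lambda_inv = as.numeric(t(state$lambda_inv)),  # row-major
              P = length(state$tau),
              alpha = state$alpha, beta = state$beta)
  # digits = I(17): full double precision, exact round-trip
  if (is.null(path))
    return(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname nig_to_json
#' @param json a path to a JSON file or a JSON string produced by
#'   `nig_to_json`.
#' @export
nig_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  P <- obj$P
  nig_state(obj$tau,
            matrix(obj$lambda_inv, nrow = P, byrow = TRUE),
            obj$alpha, obj$beta)
}
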