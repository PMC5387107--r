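# Fixtures and independent oracles shared across test files.

# Cohort whose response vectors are exactly linear in the baselines,
# omega_s = W b_s, with configurable noise. `identifiable = TRUE` restricts
# W so that omega depends on b only through the single active medication
# and the intercept coefficient (every subject on medication 1, no
# switching): in that configuration the baseline -> posterior map is
# exactly linear and a linear profile map can recover it.
make_linear_cohort <- function(n, L = 14, seed = 1, noise = 0,
                               identifiable = TRUE) {
  set.seed(seed)
  W <- if (identifiable) {
    rbind(matrix(0, L, L),
          matrix(rnorm(L, 0, 0.01 / sqrt(L)), nrow = 1),  # med 1
          matrix(0, 3, L),
          rnorm(L, 0, 0.3 / sqrt(L)))                     # intercept
  } else {
    rbind(matrix(rnorm(L * L, 0, 0.1 / sqrt(L)), ncol = L),
          matrix(rnorm(4 * L, 0, 0.01 / sqrt(L)), ncol = L),
          rnorm(L, 0, 0.3 / sqrt(L)))
  }
  ramp <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  cohort <- lapply(seq_len(n), function(s) {
    A <- sample(3:15, 1)
    b <- rnorm(L)
    omega <- drop(W %*% b)
    D <- matrix(0, A, 4, dimnames = list(NULL, c(
      "dose_irmph", "dose_xrmph", "dose_dex", "dose_atom")))
    med <- if (identifiable) 1L else sample(1:4, 1)
    for (a in seq_len(A)) D[a, med] <- ramp[min(a, length(ramp))]
    X <- make_design(b, D)
    mu <- drop(X %*% omega)
    structure(list(subject_id = sprintf("S%03d", s), baseline = b,
                   dosages = D,
                   outcomes = cbind(score_ina = mu + rnorm(A, 0, noise),
                                    score_hyp = mu + rnorm(A, 0, noise)),
                   true_omega = omega),
              class = "subject")
  })
  structure(cohort, class = "cohort", W = W)
}

# Prior that encodes zero baseline effects (tiny variance on the pinned
# baseline block) and is weak on medication + intercept coefficients.
pinned_prior <- function(L = 14, pin = 1e-6, broad = 100) {
  nig_state(rep(0, L + 5), diag(c(rep(pin, L), rep(broad, 5))),
            alpha = 1, beta = 1)
}

# Independent conjugacy oracle: posterior moments of the NIG Bayesian
# linear regression by dense Gauss-Legendre product quadrature over the
# raw prior x likelihood (no conjugate algebra). P = 1 or 2. `center` and
# `spread` position the coefficient grid; the variance axis is integrated
# on the log scale.
nig_moments_by_integration <- function(tau0, lambda0_inv, alpha0, beta0,
                                       X, y, center, spread, s2_center,
                                       n_omega = 400, n_t = 400) {
  P <- length(tau0)
  stopifnot(P %in% c(1, 2))
  lambda0 <- solve(lambda0_inv)
  gt <- pracma::gaussLegendre(n_t, log(s2_center) - 22, log(s2_center) + 22)
  s2 <- exp(gt$x)
  if (P == 1) {
    g1 <- pracma::gaussLegendre(n_omega, center[1] - 20 * spread[1],
                                center[1] + 20 * spread[1])
    om <- g1$x
    sse <- vapply(om, function(w) sum((y - X[, 1] * w)^2), numeric(1))
    qf <- lambda0[1, 1] * (om - tau0[1])^2
    M <- beta0 + 0.5 * (qf + sse)      # t-independent part
    a_pow <- alpha0 + P / 2 + 1 + length(y) / 2 - 1  # -1: Jacobian of t = log(s2)
    LD <- outer(M, s2, function(m, v) -m / v) -
      matrix(a_pow * log(s2), length(om), length(s2), byrow = TRUE)
    LD <- LD - max(LD)
    D <- exp(LD)
    wgt <- outer(g1$w, gt$w)
    Z <- sum(D * wgt)
    W1 <- matrix(om, length(om), length(s2))
    V <- matrix(s2, length(om), length(s2), byrow = TRUE)
    list(E_omega = sum(W1 * D * wgt) / Z,
         Var_omega = matrix(sum((W1 - sum(W1 * D * wgt) / Z)^2 * D * wgt) / Z),
         E_sigma2 = sum(V * D * wgt) / Z)
  } else {
    g1 <- pracma::gaussLegendre(n_omega, center[1] - 15 * spread[1],
                                center[1] + 15 * spread[1])
    g2 <- pracma::gaussLegendre(n_omega, center[2] - 15 * spread[2],
                                center[2] + 15 * spread[2])
    W1 <- matrix(g1$x, n_omega, n_omega)
    W2 <- matrix(g2$x, n_omega, n_omega, byrow = TRUE)
    D1 <- W1 - tau0[1]; D2 <- W2 - tau0[2]
    qf <- lambda0[1, 1] * D1^2 + 2 * lambda0[1, 2] * D1 * D2 +
      lambda0[2, 2] * D2^2
    sse <- 0
    for (i in seq_along(y))
      sse <- sse + (y[i] - X[i, 1] * W1 - X[i, 2] * W2)^2
    M <- beta0 + 0.5 * (qf + sse)
    a_pow <- alpha0 + P / 2 + 1 + length(y) / 2 - 1
    wome <- outer(g1$w, g2$w)
    lmax <- max(vapply(seq_along(s2), function(k)
      max(-M / s2[k]) - a_pow * log(s2[k]), numeric(1)))
    Z <- Ew1 <- Ew2 <- Es2 <- 0
    M11 <- M22 <- M12 <- 0
    for (k in seq_along(s2)) {
      Dk <- exp(-M / s2[k] - a_pow * log(s2[k]) - lmax) * wome * gt$w[k]
      Z <- Z + sum(Dk)
      Ew1 <- Ew1 + sum(W1 * Dk); Ew2 <- Ew2 + sum(W2 * Dk)
      Es2 <- Es2 + s2[k] * sum(Dk)
      M11 <- M11 + sum(W1 * W1 * Dk)
      M22 <- M22 + sum(W2 * W2 * Dk)
      M12 <- M12 + sum(W1 * W2 * Dk)
    }
    Ew <- c(Ew1, Ew2) / Z
    V <- matrix(c(M11 / Z - Ew[1]^2, M12 / Z - Ew[1] * Ew[2],
                  M12 / Z - Ew[1] * Ew[2], M22 / Z - Ew[2]^2), 2)
    list(E_omega = Ew, Var_omega = V, E_sigma2 = Es2 / Z)
  }
}

# Mann-Whitney pairwise concordance AUC oracle (brute force over all
# positive-negative pairs; ties count one half).
concordance_auc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p < q) + 0.5 * (p == q)  # lower score = more remission-like
  tot / (length(pos) * length(neg))
}
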