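# Independent oracles used across the suite.  These deliberately avoid the
# package's filtering/recursion code paths: the smoother oracle stacks all
# states into one big joint Gaussian and solves it densely; the IRF oracle
# uses companion-matrix powers.

# Posterior mean of a random-walk state path given observations
#   y_t = Z_t a_t + e_t,  e_t ~ N(0, Hcov_t),   a_1 ~ N(a0, diag(p0)),
#   a_{t+1} = a_t + w_t,  w_t ~ N(0, diag(w)).
# Zlist/Hlist/ylist are per-time lists; returns Te x k matrix.
dense_rw_smoother <- function(ylist, Zlist, Hlist, wdiag, a0, p0) {
  Te <- length(ylist)
  k <- length(a0)
  idx <- function(t) ((t - 1) * k + 1):(t * k)
  Q <- matrix(0, Te * k, Te * k)
  rhs <- numeric(Te * k)
  Q[idx(1), idx(1)] <- diag(1 / p0, k)
  rhs[idx(1)] <- (1 / p0) * a0
  if (Te > 1) {
    Winv <- diag(1 / wdiag, k)
    for (t in 1:(Te - 1)) {
      Q[idx(t), idx(t)] <- Q[idx(t), idx(t)] + Winv
      Q[idx(t + 1), idx(t + 1)] <- Q[idx(t + 1), idx(t + 1)] + Winv
      Q[idx(t), idx(t + 1)] <- Q[idx(t), idx(t + 1)] - Winv
      Q[idx(t + 1), idx(t)] <- Q[idx(t + 1), idx(t)] - Winv
    }
  }
  for (t in 1:Te) {
    Z <- Zlist[[t]]
    Hinv <- solve(Hlist[[t]])
    Q[idx(t), idx(t)] <- Q[idx(t), idx(t)] + t(Z) %*% Hinv %*% Z
    rhs[idx(t)] <- rhs[idx(t)] + as.numeric(t(Z) %*% Hinv %*% ylist[[t]])
  }
  matrix(solve(Q, rhs), Te, k, byrow = TRUE)
}

# dense observation covariance A^{-1} diag(e^h) A^{-T} at one time point
obs_cov_dense <- function(alpha_t, h_t) {
  m <- length(h_t)
  A <- alpha_to_A(alpha_t, m)
  Ainv <- solve(A)
  Ainv %*% diag(exp(h_t), m) %*% t(Ainv)
}

# companion-matrix closed form: psi_k = J C^k J' A^{-1} diag(scale)
companion_irf <- function(beta_t, alpha_t, scale, spec, H) {
  m <- spec$m; s <- spec$s
  bb <- beta_to_B(beta_t, spec)
  C <- matrix(0, m * s, m * s)
  C[1:m, ] <- do.call(cbind, bb$B)
  if (s > 1) C[(m + 1):(m * s), 1:(m * (s - 1))] <- diag(m * (s - 1))
  J <- cbind(diag(m), matrix(0, m, m * (s - 1)))
  P0 <- solve(alpha_to_A(alpha_t, m)) %*% diag(scale, m)
  out <- array(0, dim = c(H + 1, m, m))
  Ck <- diag(m * s)
  for (k in 0:H) {
    out[k + 1, , ] <- J %*% Ck %*% t(J) %*% P0
    Ck <- C %*% Ck
  }
  out
}

# random stable VAR(1) coefficient state for an m-variable spec
random_stable_beta <- function(spec, radius = 0.7) {
  m <- spec$m
  repeat {
    B <- matrix(runif(m * m, -1, 1), m, m)
    sr <- max(Mod(eigen(B, only.values = TRUE)$values))
    if (sr > 1e-3) {
      B <- B * (radius * runif(1, 0.3, 1) / sr)
      break
    }
  }
  # equation-stacked state vector (row i of B is equation i's lag block)
  as.numeric(t(B))
}

# small complete panel for sampler tests
toy_panel <- function(Tn = 40, m = 2, seed = 123) {
  set.seed(seed)
  matrix(rnorm(Tn * m), Tn, m)
}
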