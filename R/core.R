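#' TVP-VAR model specification
#'
#' Defines the dimensions of the time-varying parameter VAR: the structural
#' system is
#' \deqn{A_t y_t = M_{1,t} y_{t-1} + \dots + M_{s,t} y_{t-s} + \mu_t,}
#' rewritten in reduced form as \eqn{y_t = X_t \beta_t + A_t^{-1}\Sigma_t
#' \varepsilon_t} with \eqn{X_t = I_m \otimes (y_{t-1}', \dots, y_{t-s}')}
#' and \eqn{\varepsilon_t \sim N(0, I_m)}.  The contemporaneous matrix
#' \eqn{A_t} is unit-lower-triangular (recursive identification: shocks are
#' ordered), \eqn{\Sigma_t = \mathrm{diag}(e^{h_{jt}/2})} carries the
#' stochastic volatilities, and all three state blocks follow first-order
#' random walks.
#'
#' State dimensions: `k_beta = m^2 s` (plus `m` with an intercept),
#' `k_alpha = m (m - 1) / 2`, `k_h = m`.
#'
#' @param m number of variables (>= 1).
#' @param s lag order (>= 1); the pipeline default is 1.
#' @param var_names variable names in the recursive-identification order.
#' @param include_intercept prepend a constant to each equation's regressors.
#'   Off by default: the structural form carries no intercept.
#' @return object of class `tvpvar_spec`.
#' @examples
#' model_spec(3, 1, c("new", "pas", "pek"))
#' @export
model_spec <- function(m, s = 1L, var_names = paste0("y", seq_len(m)),
                       include_intercept = FALSE) {
  m <- as.integer(m); s <- as.integer(s)
  if (m < 1L || s < 1L) stop("need m >= 1 and s >= 1")
  if (length(var_names) != m) stop("var_names must have length m")
  p <- m * s + as.integer(include_intercept)
  structure(list(m = m, s = s, var_names = var_names,
                 include_intercept = isTRUE(include_intercept),
                 p = p,                    # regressors per equation
                 k_beta = m * p,
                 k_alpha = (m * (m - 1L)) %/% 2L,
                 k_h = m),
            class = "tvpvar_spec")
}

#' @export
print.tvpvar_spec <- function(x, ...) {
  cat(sprintf("<tvpvar_spec> m=%d, s=%d%s; k_beta=%d, k_alpha=%d, k_h=%d\n",
              x$m, x$s, if (x$include_intercept) " (+intercept)" else "",
              x$k_beta, x$k_alpha, x$k_h))
  cat("  ordering:", paste(x$var_names, collapse = " -> "), "\n")
  invisible(x)
}

#' Prior configuration for the TVP-VAR-SV sampler
#'
#' The initial states are Gaussian, \eqn{\beta_{s+1} \sim N(\mu_{\beta 0},
#' \Sigma_{\beta 0})} and likewise for \eqn{\alpha} and \eqn{h}; the defaults
#' are \eqn{\mu = 0}, \eqn{\Sigma_{\beta 0} = \Sigma_{\alpha 0} = 10 I},
#' \eqn{\Sigma_{h0} = 100 I}.  Each diagonal state-innovation precision
#' (the inverse squared innovation scale) carries an independent Gamma
#' (shape, rate) prior: (40, 0.02) for the coefficient block and (4, 0.02)
#' for the contemporaneous-relation and volatility blocks.
#'
#' @param sigma_beta0,sigma_alpha0,sigma_h0 diagonal values of the
#'   initial-state covariances.
#' @param gamma_beta_shape,gamma_beta_rate Gamma hyperprior on each
#'   beta-block innovation precision.
#' @param gamma_alpha_shape,gamma_alpha_rate same for the alpha block.
#' @param gamma_h_shape,gamma_h_rate same for the volatility block.
#' @return object of class `tvpvar_prior`.
#' @export
prior_config <- function(sigma_beta0 = 10, sigma_alpha0 = 10, sigma_h0 = 100,
                         gamma_beta_shape = 40, gamma_beta_rate = 0.02,
                         gamma_alpha_shape = 4, gamma_alpha_rate = 0.02,
                         gamma_h_shape = 4, gamma_h_rate = 0.02) {
  vals <- c(sigma_beta0, sigma_alpha0, sigma_h0,
            gamma_beta_shape, gamma_beta_rate, gamma_alpha_shape,
            gamma_alpha_rate, gamma_h_shape, gamma_h_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior hyperparameters must be positive and finite")
  structure(list(mu_beta0 = 0, mu_alpha0 = 0, mu_h0 = 0,
                 sigma_beta0 = sigma_beta0, sigma_alpha0 = sigma_alpha0,
                 sigma_h0 = sigma_h0,
                 gamma_beta = c(shape = gamma_beta_shape, rate = gamma_beta_rate),
                 gamma_alpha = c(shape = gamma_alpha_shape, rate = gamma_alpha_rate),
                 gamma_h = c(shape = gamma_h_shape, rate = gamma_h_rate)),
            class = "tvpvar_prior")
}

#' Kronecker design matrices
#'
#' For each effective time point t = s+1..T builds
#' \eqn{X_t = I_m \otimes x_t'} where \eqn{x_t = (y_{t-1}', \dots,
#' y_{t-s}')'} (prepended with 1 under an intercept), so that the
#' observation equation reads \eqn{y_t = X_t \beta_t + u_t}.
#'
#' @param y an `adjusted_panel`, `daily_panel` (complete), or T x m matrix.
#' @param spec a [model_spec()].
#' @return 3-d array of dimension `m x k_beta x (T - s)`; slice `[ , , t]`
#'   is the design for effective time t.
#' @export
build_design <- function(y, spec) {
  Y <- panel_values(y, spec)
  Tn <- nrow(Y)
  if (Tn <= spec$s) stop("need more observations than lags")
  XL <- lag_matrix(Y, spec)                 # (T - s) x p
  Te <- Tn - spec$s
  out <- array(0, dim = c(spec$m, spec$k_beta, Te))
  for (t in seq_len(Te)) out[, , t] <- diag(spec$m) %x% t(XL[t, ])
  out
}

# stacked-lag regressor rows x_t' for t = s+1..T
lag_matrix <- function(Y, spec) {
  Tn <- nrow(Y); s <- spec$s
  idx <- (s + 1):Tn
  cols <- lapply(seq_len(s), function(l) Y[idx - l, , drop = FALSE])
  XL <- do.call(cbind, cols)
  if (spec$include_intercept) XL <- cbind(1, XL)
  XL
}

panel_values <- function(y, spec = NULL) {
  Y <- if (is.matrix(y)) y else y$values
  if (anyNA(Y)) stop("panel contains missing values; impute first")
  if (!is.null(spec) && ncol(Y) != spec$m)
    stop(sprintf("panel has %d series but spec expects m = %d", ncol(Y), spec$m))
  Y
}

#' Contemporaneous-relation vector to matrix and back
#'
#' `alpha_to_A` fills the strictly-lower triangle of an m x m matrix
#' row-major from the stacked free elements of \eqn{A_t} and puts ones on
#' the diagonal; `A_to_alpha` extracts them again.
#'
#' @param alpha numeric vector of length m(m-1)/2; row-major order
#'   (a21, a31, a32, a41, ...).
#' @param m system dimension.
#' @return `alpha_to_A`: unit-lower-triangular m x m matrix.
#' @examples
#' alpha_to_A(c(0.5, -1, 2), 3)
#' @export
alpha_to_A <- function(alpha, m) {
  if (length(alpha) != m * (m - 1) / 2)
    stop("alpha must have length m(m-1)/2 = ", m * (m - 1) / 2)
  A <- diag(m)
  if (m > 1) {
    k <- 1L
    for (i in 2:m) for (j in 1:(i - 1)) {
      A[i, j] <- alpha[k]; k <- k + 1L
    }
  }
  A
}

#' @rdname alpha_to_A
#' @param A unit-lower-triangular matrix.
#' @export
A_to_alpha <- function(A) {
  m <- nrow(A)
  if (m == 1) return(numeric(0))
  out <- numeric(m * (m - 1) / 2)
  k <- 1L
  for (i in 2:m) for (j in 1:(i - 1)) {
    out[k] <- A[i, j]; k <- k + 1L
  }
  out
}

#' Reduced-form lag matrices
#'
#' Solves \eqn{B_i = A^{-1} M_i} for each structural lag matrix by forward
#' substitution against the unit-lower-triangular contemporaneous matrix.
#'
#' @param A unit-lower-triangular m x m matrix.
#' @param M_list list of m x m structural lag matrices.
#' @return list of reduced-form matrices, same length as `M_list`.
#' @export
reduced_form <- function(A, M_list) {
  if (any(abs(diag(A) - 1) > 1e-12))
    stop("A must have a unit diagonal")
  lapply(M_list, function(M) forwardsolve(A, M))
}

#' Reshape a coefficient state vector into lag matrices
#'
#' The state \eqn{\beta_t} stacks the equations' regressor coefficients:
#' entries `(i-1)p + 1 .. ip` belong to equation i, ordered (intercept,)
#' lag-1 block, ..., lag-s block.
#'
#' @param beta_t state vector of length `k_beta`.
#' @param spec a [model_spec()].
#' @return list with `B` (list of s reduced-form m x m lag matrices) and
#'   `intercept` (length-m vector, zeros when the spec has none).
#' @export
beta_to_B <- function(beta_t, spec) {
  m <- spec$m; s <- spec$s; p <- spec$p
  if (length(beta_t) != spec$k_beta) stop("beta_t has wrong length")
  Bmat <- matrix(beta_t, nrow = m, ncol = p, byrow = TRUE) # row i = eq i
  off <- as.integer(spec$include_intercept)
  intercept <- if (off) Bmat[, 1] else numeric(m)
  B <- lapply(seq_len(s), function(l)
    Bmat[, off + ((l - 1) * m + 1):(l * m), drop = FALSE])
  list(B = B, intercept = intercept)
}

#' Per-observation log-likelihood
#'
#' Log density of one observation under
#' \eqn{y_t \sim N(X_t \beta_t,\; A_t^{-1} \Sigma_t \Sigma_t' A_t^{-T})}
#' with \eqn{\Sigma_t = \mathrm{diag}(e^{h_t/2})}.  Uses the triangular
#' structure: the log determinant of the covariance is \eqn{\sum_j h_{jt}}
#' and the quadratic form is \eqn{\|\Sigma_t^{-1} A_t (y_t - X_t\beta_t)\|^2}.
#'
#' @param y_t observation vector (length m).
#' @param X_t design matrix m x k_beta (one slice of [build_design()]).
#' @param beta_t,alpha_t,h_t state vectors at time t.
#' @return scalar log density.
#' @export
loglik_obs <- function(y_t, X_t, beta_t, alpha_t, h_t) {
  if (any(!is.finite(c(beta_t, alpha_t, h_t))))
    stop("non-finite state values")
  m <- length(y_t)
  A <- alpha_to_A(alpha_t, m)
  resid <- as.numeric(y_t - X_t %*% beta_t)
  z <- A %*% resid                       # structural residual, var diag(e^h)
  -0.5 * (m * log(2 * pi) + sum(h_t) + sum(z^2 / exp(h_t)))
}
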