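#' MCMC run configuration
#'
#' Defaults follow the estimation setup used throughout the package's
#' headline analysis: 10,000 sampler cycles with the first 1,000 discarded
#' as burn-in and no thinning.  A reduced "fast" profile (2,000 / 200) is
#' available via [pipeline_config()].
#'
#' @param n_draws total Gibbs cycles.
#' @param burn_in cycles discarded from the front (must be < `n_draws`).
#' @param thin keep every `thin`-th retained cycle.
#' @param seed integer seed.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_draws = 10000L, burn_in = 1000L, thin = 1L,
                        seed = 1L) {
  n_draws <- as.integer(n_draws); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_draws) stop("burn_in must be smaller than n_draws")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_draws = n_draws, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed),
                 n_retained = (n_draws - burn_in) %/% thin),
            class = "mcmc_config")
}

# 10-component Gaussian mixture approximation to the log chi-squared(1)
# distribution (Omori, Chib, Shephard & Nakajima 2007): ln eps^2 with
# eps ~ N(0,1) is approximated by sum_i p_i N(m_i, v_i).
.sv_mixture <- list(
  p = c(0.00609, 0.04775, 0.13057, 0.20674, 0.22715,
        0.18842, 0.12047, 0.05591, 0.01575, 0.00115),
  m = c(1.92677, 1.34744, 0.73504, 0.02266, -0.85173,
        -1.97278, -3.46788, -5.55246, -8.68384, -14.65000),
  v = c(0.11265, 0.17788, 0.26768, 0.40611, 0.62699,
        0.98583, 1.57469, 2.54498, 4.16591, 7.33342))

#' Draw from the log chi-squared(1) mixture approximation
#'
#' Samples the 10-component Gaussian mixture used to linearize the
#' stochastic-volatility observation equation.  The exact distribution of
#' \eqn{\ln \varepsilon^2} for standard-normal \eqn{\varepsilon} has mean
#' \eqn{\psi(1/2) + \ln 2 \approx -1.2704}; the mixture reproduces it to
#' high accuracy.
#'
#' @param n number of draws.
#' @return numeric vector of draws.
#' @export
rlogchisq_mixture <- function(n) {
  comp <- sample.int(10L, n, replace = TRUE, prob = .sv_mixture$p)
  rnorm(n, .sv_mixture$m[comp], sqrt(.sv_mixture$v[comp]))
}

# internal: common Gibbs-state bookkeeping for one panel + spec
gibbs_inputs <- function(panel, spec) {
  Y <- panel_values(panel, spec)
  Tn <- nrow(Y)
  if (Tn <= spec$s + 10) stop("panel too short for MCMC (need T > s + 10)")
  list(Yobs = t(Y[(spec$s + 1):Tn, , drop = FALSE]),   # m x Te
       Xlag = t(lag_matrix(Y, spec)),                  # p x Te
       Te = Tn - spec$s)
}

alpha_cube <- function(alpha_path, m) {
  Te <- nrow(alpha_path)
  arr <- array(0, dim = c(m, m, Te))
  for (t in seq_len(Te)) arr[, , t] <- alpha_to_A(alpha_path[t, ], m)
  arr
}

#' Conditional draw of the coefficient state path
#'
#' Exact forward-filtering backward-sampling draw from
#' \eqn{p(\beta_{s+1:T} \mid y, \alpha, h, v_\beta)}: given the
#' contemporaneous matrices and volatilities the observation equation is a
#' linear-Gaussian state space with identity random-walk transition and
#' diagonal innovation covariance `diag(v_beta)`.
#'
#' @param panel complete panel (or T x m matrix).
#' @param spec a [model_spec()].
#' @param alpha_path (T-s) x k_alpha matrix of contemporaneous states.
#' @param h_path (T-s) x m matrix of log-volatilities.
#' @param v_beta length-k_beta innovation variances.
#' @param prior a [prior_config()].
#' @param want_mean also return the Rauch-Tung-Striebel smoother mean.
#' @param draw return a sampled path (set `FALSE` to get only the mean).
#' @return list with `draw` and/or `mean`, (T-s) x k_beta matrices.
#' @export
sample_beta <- function(panel, spec, alpha_path, h_path, v_beta,
                        prior = prior_config(), want_mean = FALSE,
                        draw = TRUE) {
  gi <- gibbs_inputs(panel, spec)
  out <- ffbs_beta_cpp(gi$Yobs, gi$Xlag, alpha_cube(as.matrix(alpha_path), spec$m),
                       t(exp(as.matrix(h_path))),
                       rep_len(v_beta, spec$k_beta),
                       rep(prior$mu_beta0, spec$k_beta),
                       rep(prior$sigma_beta0, spec$k_beta),
                       draw, want_mean)
  lapply(out, t)
}

#' Conditional draw of the contemporaneous-relation state path
#'
#' Uses the row-wise regression form: with \eqn{\hat y_t = y_t - X_t\beta_t},
#' the j-th row of \eqn{A_t \hat y_t = \Sigma_t \varepsilon_t} makes
#' \eqn{\hat y_{jt}} a regression on \eqn{-\hat y_{1..j-1,t}} with noise
#' variance \eqn{e^{h_{jt}}}, which is again a linear-Gaussian state space
#' in the stacked \eqn{\alpha_t}.
#'
#' @inheritParams sample_beta
#' @param beta_path (T-s) x k_beta coefficient states.
#' @param v_alpha length-k_alpha innovation variances.
#' @return list with `draw` and/or `mean`, (T-s) x k_alpha matrices
#'   (zero-column for m = 1).
#' @export
sample_alpha <- function(panel, spec, beta_path, h_path, v_alpha,
                         prior = prior_config(), want_mean = FALSE,
                         draw = TRUE) {
  gi <- gibbs_inputs(panel, spec)
  if (spec$k_alpha == 0L) {
    z <- matrix(0, gi$Te, 0L)
    out <- list()
    if (draw) out$draw <- z
    if (want_mean) out$mean <- z
    return(out)
  }
  rz <- resid_cpp(gi$Yobs, t(as.matrix(beta_path)), gi$Xlag,
                  matrix(0, spec$k_alpha, gi$Te))
  out <- ffbs_alpha_cpp(rz$yhat, t(exp(as.matrix(h_path))),
                        rep_len(v_alpha, spec$k_alpha),
                        rep(prior$mu_alpha0, spec$k_alpha),
                        rep(prior$sigma_alpha0, spec$k_alpha),
                        draw, want_mean)
  lapply(out, t)
}

#' Conditional draw of the log-volatility state paths
#'
#' Per series j the structural residual \eqn{e_{jt} = (A_t \hat y_t)_j} is
#' linearized through \eqn{y^*_{jt} = \ln(e_{jt}^2 + c)}; mixture-component
#' indicators for the 10-component log-chi-squared approximation are drawn
#' given the current path, and the resulting conditionally Gaussian model
#' is sampled by FFBS.  The offset `c = 1e-6` is applied after standardizing
#' each residual series to unit sample variance (the fitted path is shifted
#' back by the same constant), so the offset's distortion does not depend
#' on the data scale.
#'
#' @inheritParams sample_alpha
#' @param alpha_path (T-s) x k_alpha contemporaneous states.
#' @param v_h length-m innovation variances.
#' @param h_current (T-s) x m current path (conditioning for the indicator
#'   draw).
#' @param offset small positive constant c in the linearization (applied on
#'   the standardized scale).
#' @return list with `draw`, a (T-s) x m matrix.
#' @export
sample_h <- function(panel, spec, beta_path, alpha_path, v_h, h_current,
                     prior = prior_config(), offset = 1e-6) {
  gi <- gibbs_inputs(panel, spec)
  rz <- resid_cpp(gi$Yobs, t(as.matrix(beta_path)), gi$Xlag,
                  t(as.matrix(alpha_path)))
  e <- rz$e                               # m x Te structural residuals
  v_h <- rep_len(v_h, spec$m)
  hnew <- matrix(0, gi$Te, spec$m)
  for (j in seq_len(spec$m)) {
    scl <- sd(e[j, ])
    if (!is.finite(scl) || scl <= 0) scl <- 1e-8
    ystar <- log((e[j, ] / scl)^2 + offset)
    shift <- 2 * log(scl)
    htil <- h_current[, j] - shift
    comp <- draw_mixture_components(ystar, htil)
    res <- ffbs_uni_cpp(ystar - .sv_mixture$m[comp], .sv_mixture$v[comp],
                        v_h[j], prior$mu_h0 - shift, prior$sigma_h0,
                        TRUE, FALSE)
    hnew[, j] <- as.numeric(res$draw) + shift
  }
  list(draw = hnew)
}

# indicator draw: P(s_t = i) ~ p_i N(ystar_t; htil_t + m_i, v_i)
draw_mixture_components <- function(ystar, htil) {
  mx <- .sv_mixture
  lp <- vapply(1:10, function(i)
    log(mx$p[i]) + dnorm(ystar, htil + mx$m[i], sqrt(mx$v[i]), log = TRUE),
    numeric(length(ystar)))               # Te x 10
  lp <- lp - apply(lp, 1, max)
  w <- exp(lp)
  w <- w / rowSums(w)
  cw <- t(apply(w, 1, cumsum))
  u <- runif(length(ystar))
  rowSums(cw < u) + 1L
}

#' Conditional draw of the state-innovation variances
#'
#' Each diagonal innovation precision is conditionally Gamma: with prior
#' precision ~ Gamma(shape, rate) and state increments
#' \eqn{\Delta_t = x_{t+1} - x_t}, the update is
#' Gamma(shape + (T_eff - 1)/2, rate + 0.5 sum_t Delta_t^2); the variance
#' is the inverse of the drawn precision.
#'
#' @param paths a [state_paths()] object (>= 2 rows).
#' @param prior a [prior_config()].
#' @return list with positive vectors `v_beta`, `v_alpha`, `v_h`.
#' @export
sample_variances <- function(paths, prior = prior_config()) {
  stopifnot(inherits(paths, "state_paths"))
  if (nrow(paths$beta) < 2) stop("state paths need at least 2 rows")
  draw_block <- function(path, g) {
    k <- ncol(path)
    if (k == 0L) return(numeric(0))
    D <- diff(path)
    ss <- colSums(D^2)
    prec <- rgamma(k, shape = g[["shape"]] + (nrow(path) - 1) / 2,
                   rate = g[["rate"]] + ss / 2)
    1 / prec
  }
  list(v_beta = draw_block(paths$beta, prior$gamma_beta),
       v_alpha = draw_block(paths$alpha, prior$gamma_alpha),
       v_h = draw_block(paths$h, prior$gamma_h))
}

#' Run the TVP-VAR-SV block Gibbs sampler
#'
#' Cycles `sample_beta` -> `sample_alpha` -> `sample_h` ->
#' `sample_variances`, initialized at the prior state means (zeros) with
#' innovation variances at their gamma-prior means, discards the burn-in
#' and returns the retained draws.  The per-draw companion-matrix spectral
#' radius (of the time-averaged coefficient draw) is logged rather than
#' used to reject explosive draws.
#'
#' @param panel complete [adjusted_panel()], [daily_panel()] or T x m matrix.
#' @param spec a [model_spec()].
#' @param prior a [prior_config()].
#' @param config an [mcmc_config()].
#' @param progress print a progress line every 1000 cycles.
#' @return object of class `tvpvar_draws`: arrays `beta`
#'   (retained x (T-s) x k_beta), `alpha`, `h`; matrices `v_beta`,
#'   `v_alpha`, `v_h` (retained x k); `spectral_radius` (retained);
#'   plus `spec`, `prior`, `config` and the panel `dates` used.
#' @export
run_mcmc <- function(panel, spec, prior = prior_config(),
                     config = mcmc_config(), progress = FALSE) {
  stopifnot(inherits(spec, "tvpvar_spec"), inherits(config, "mcmc_config"))
  gi <- gibbs_inputs(panel, spec)
  Te <- gi$Te
  old <- set_local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)

  # initialization: states at prior means, variances at gamma-prior means
  beta <- matrix(0, Te, spec$k_beta)
  alpha <- matrix(0, Te, spec$k_alpha)
  h <- matrix(0, Te, spec$m)
  v_beta <- rep(prior$gamma_beta[["rate"]] / prior$gamma_beta[["shape"]],
                spec$k_beta)
  v_alpha <- rep(prior$gamma_alpha[["rate"]] / prior$gamma_alpha[["shape"]],
                 max(spec$k_alpha, 1L))[seq_len(spec$k_alpha)]
  v_h <- rep(prior$gamma_h[["rate"]] / prior$gamma_h[["shape"]], spec$m)

  nr <- config$n_retained
  store <- list(beta = array(NA_real_, c(nr, Te, spec$k_beta)),
                alpha = array(NA_real_, c(nr, Te, spec$k_alpha)),
                h = array(NA_real_, c(nr, Te, spec$m)),
                v_beta = matrix(NA_real_, nr, spec$k_beta),
                v_alpha = matrix(NA_real_, nr, spec$k_alpha),
                v_h = matrix(NA_real_, nr, spec$m),
                spectral_radius = numeric(nr))
  kept <- 0L
  for (it in seq_len(config$n_draws)) {
    step <- "beta"
    res <- tryCatch({
      beta <- sample_beta(panel, spec, alpha, h, v_beta, prior)$draw
      step <- "alpha"
      alpha <- sample_alpha(panel, spec, beta, h, v_alpha, prior)$draw
      step <- "h"
      h <- sample_h(panel, spec, beta, alpha, v_h, h, prior)$draw
      step <- "variances"
      vs <- sample_variances(state_paths(beta, alpha, h), prior)
      v_beta <- vs$v_beta; v_alpha <- vs$v_alpha; v_h <- vs$v_h
      NULL
    }, error = function(e)
      stop(sprintf("MCMC cycle %d, %s block: %s", it, step,
                   conditionMessage(e)), call. = FALSE))
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      store$beta[kept, , ] <- beta
      if (spec$k_alpha > 0) store$alpha[kept, , ] <- alpha
      store$h[kept, , ] <- h
      store$v_beta[kept, ] <- v_beta
      if (spec$k_alpha > 0) store$v_alpha[kept, ] <- v_alpha
      store$v_h[kept, ] <- v_h
      store$spectral_radius[kept] <-
        companion_spectral_radius(colMeans(beta), spec)
    }
    if (progress && it %% 1000L == 0L)
      message(sprintf("cycle %d / %d", it, config$n_draws))
  }
  dates <- if (is.matrix(panel)) NULL else panel$dates[-seq_len(spec$s)]
  structure(c(store, list(spec = spec, prior = prior, config = config,
                          dates = dates)),
            class = "tvpvar_draws")
}

#' @export
print.tvpvar_draws <- function(x, ...) {
  cat(sprintf("<tvpvar_draws> %d retained draws (of %d, burn-in %d), m=%d, s=%d, T_eff=%d\n",
              dim(x$beta)[1], x$config$n_draws, x$config$burn_in,
              x$spec$m, x$spec$s, dim(x$beta)[2]))
  invisible(x)
}

#' Companion-matrix spectral radius of a coefficient vector
#' @param beta_t length-k_beta state vector.
#' @param spec a [model_spec()].
#' @return largest eigenvalue modulus of the VAR companion matrix.
#' @export
companion_spectral_radius <- function(beta_t, spec) {
  bb <- beta_to_B(beta_t, spec)
  C <- companion_matrix(bb$B)
  max(Mod(eigen(C, only.values = TRUE)$values))
}

companion_matrix <- function(B_list) {
  m <- nrow(B_list[[1]]); s <- length(B_list)
  C <- matrix(0, m * s, m * s)
  C[1:m, ] <- do.call(cbind, B_list)
  if (s > 1) C[(m + 1):(m * s), 1:(m * (s - 1))] <- diag(m * (s - 1))
  C
}

#' Posterior-mean state paths
#' @param draws a `tvpvar_draws` object.
#' @return a [state_paths()] of posterior means.
#' @export
posterior_mean_states <- function(draws) {
  state_paths(apply(draws$beta, c(2, 3), mean),
              if (dim(draws$alpha)[3] > 0) apply(draws$alpha, c(2, 3), mean)
              else matrix(0, dim(draws$beta)[2], 0),
              apply(draws$h, c(2, 3), mean))
}
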