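test_that("beta FFBS smoother mean equals the dense joint-Gaussian solve", {
  set.seed(42)
  spec <- model_spec(2, 1)
  Tn <- 30
  Y <- toy_panel(Tn, 2, seed = 42)
  Te <- Tn - 1
  alpha_path <- matrix(rnorm(Te, 0, 0.3), Te, 1)
  h_path <- matrix(rnorm(Te * 2, 0, 0.3), Te, 2)
  v_beta <- rep(0.01, spec$k_beta)
  prior <- prior_config()

  sm <- sample_beta(Y, spec, alpha_path, h_path, v_beta, prior,
                    want_mean = TRUE, draw = FALSE)$mean
  X <- build_design(Y, spec)
  oracle <- dense_rw_smoother(
    ylist = lapply(1:Te, function(t) Y[t + 1, ]),
    Zlist = lapply(1:Te, function(t) X[, , t]),
    Hlist = lapply(1:Te, function(t) obs_cov_dense(alpha_path[t, ], h_path[t, ])),
    wdiag = v_beta, a0 = rep(0, spec$k_beta),
    p0 = rep(prior$sigma_beta0, spec$k_beta))
  expect_lt(max(abs(sm - oracle)), 1e-8)
})

test_that("alpha FFBS smoother mean equals the dense joint-Gaussian solve", {
  set.seed(43)
  spec <- model_spec(3, 1)
  Tn <- 30
  Y <- toy_panel(Tn, 3, seed = 43)
  Te <- Tn - 1
  beta_path <- matrix(rnorm(Te * spec$k_beta, 0, 0.2), Te, spec$k_beta)
  h_path <- matrix(rnorm(Te * 3, 0, 0.3), Te, 3)
  v_alpha <- rep(0.02, spec$k_alpha)
  prior <- prior_config()

  sm <- sample_alpha(Y, spec, beta_path, h_path, v_alpha, prior,
                     want_mean = TRUE, draw = FALSE)$mean

  X <- build_design(Y, spec)
  yhat <- t(vapply(1:Te, function(t)
    Y[t + 1, ] - as.numeric(X[, , t] %*% beta_path[t, ]), numeric(3)))
  # row-wise regression form: yhat_j on -yhat_{1..j-1}, noise exp(h_j)
  Zl <- lapply(1:Te, function(t) {
    Z <- matrix(0, 2, spec$k_alpha)
    Z[1, 1] <- -yhat[t, 1]
    Z[2, 2:3] <- -yhat[t, 1:2]
    Z
  })
  oracle <- dense_rw_smoother(
    ylist = lapply(1:Te, function(t) yhat[t, 2:3]),
    Zlist = Zl,
    Hlist = lapply(1:Te, function(t) diag(exp(h_path[t, 2:3]))),
    wdiag = v_alpha, a0 = rep(0, spec$k_alpha),
    p0 = rep(prior$sigma_alpha0, spec$k_alpha))
  expect_lt(max(abs(sm - oracle)), 1e-8)
})

test_that("FFBS draws are distributed around the smoother mean", {
  spec <- model_spec(2, 1)
  Y <- toy_panel(25, 2, seed = 77)
  Te <- 24
  alpha_path <- matrix(0.3, Te, 1)
  h_path <- matrix(0, Te, 2)
  v_beta <- rep(0.05, spec$k_beta)
  sm <- sample_beta(Y, spec, alpha_path, h_path, v_beta,
                    want_mean = TRUE, draw = FALSE)$mean
  set.seed(123)
  ndraw <- 3000
  acc <- matrix(0, Te, spec$k_beta)
  for (i in seq_len(ndraw))
    acc <- acc + sample_beta(Y, spec, alpha_path, h_path, v_beta)$draw
  emp <- acc / ndraw
  # posterior sds are bounded by the prior scale; use a generous MC band
  err <- abs(emp - sm)
  expect_lt(max(err), 3 * 1 / sqrt(ndraw) * 10)
  expect_lt(mean(err), 0.05)
})

test_that("a near-zero innovation variance freezes the sampled path", {
  spec <- model_spec(2, 1)
  Y <- toy_panel(60, 2, seed = 5)
  Te <- 59
  set.seed(1)
  path <- sample_beta(Y, spec, matrix(0, Te, 1), matrix(0, Te, 2),
                      v_beta = rep(1e-12, spec$k_beta))$draw
  expect_lt(max(abs(sweep(path, 2, path[1, ]))), 1e-3)
})

test_that("alpha block is a no-op for a univariate model", {
  spec <- model_spec(1, 1)
  Y <- toy_panel(40, 1, seed = 9)
  out <- sample_alpha(Y, spec, matrix(0.2, 39, 1), matrix(0, 39, 1),
                      numeric(0))
  expect_identical(dim(out$draw), c(39L, 0L))
})

test_that("constant contemporaneous relations are recovered from data", {
  spec <- model_spec(3, 1)
  al_true <- c(0.8, 0.3, -0.5)
  sim <- simulate_tvpvar(spec,
                         init_states = list(beta = rep(0, spec$k_beta),
                                            alpha = al_true, h = rep(0, 3)),
                         innovation_sds = list(beta = 0, alpha = 0, h = 0),
                         n_obs = 500, seed = 17)
  Te <- 499
  set.seed(18)
  acc <- matrix(0, Te, 3)
  truth <- sim$truth$state_paths
  for (i in 1:50)
    acc <- acc + sample_alpha(sim$panel$values, spec, truth$beta, truth$h,
                              v_alpha = rep(1e-10, 3))$draw
  est <- colMeans(acc / 50)
  expect_lt(max(abs(est - al_true)), 0.1)
})

test_that("variance updates follow the conjugate Gamma closed form", {
  prior <- prior_config()
  Te <- 50
  zero_paths <- state_paths(matrix(1, Te, 2), matrix(0, Te, 1),
                            matrix(2, Te, 1))
  set.seed(33)
  n <- 20000
  prec <- matrix(0, n, 2)
  for (i in seq_len(n))
    prec[i, ] <- 1 / sample_variances(zero_paths, prior)$v_beta
  a <- prior$gamma_beta[["shape"]] + (Te - 1) / 2
  b <- prior$gamma_beta[["rate"]]
  expect_lt(abs(mean(prec) - a / b), 3 * sqrt(a / b^2 / (2 * n)))
  expect_true(all(unlist(sample_variances(zero_paths, prior)) > 0))

  # quadrupled squared increments quarter the posterior precision (large-T)
  set.seed(34)
  ramp <- matrix(cumsum(rep(0.5, 400)), 400, 1)
  p1 <- mean(replicate(500, 1 / sample_variances(
    state_paths(ramp, matrix(0, 400, 0), ramp), prior)$v_beta))
  p2 <- mean(replicate(500, 1 / sample_variances(
    state_paths(2 * ramp, matrix(0, 400, 0), 2 * ramp), prior)$v_beta))
  expect_equal(p2 / p1, 0.25, tolerance = 0.05)
  expect_error(sample_variances(state_paths(matrix(1, 1, 1),
                                            matrix(0, 1, 0),
                                            matrix(0, 1, 1)), prior),
               "at least 2 rows")
})

test_that("the SV mixture reproduces the log chi-squared moments", {
  set.seed(55)
  x <- rlogchisq_mixture(200000)
  expect_lt(abs(mean(x) - (-1.2704)), 0.02)
  # Var(ln chi2_1) = pi^2/2 ~ 4.93
  expect_lt(abs(var(x) - pi^2 / 2), 0.15)
})

test_that("log-volatility paths are recovered around their true level", {
  spec <- model_spec(1, 1)
  sim <- simulate_tvpvar(spec,
                         init_states = list(beta = 0.4, alpha = numeric(0), h = 0),
                         innovation_sds = list(beta = 0, alpha = 0, h = 0),
                         n_obs = 1000, seed = 71)
  truth <- sim$truth$state_paths
  Te <- 999
  set.seed(72)
  h <- matrix(0, Te, 1)
  acc <- matrix(0, Te, 1)
  nit <- 300
  for (i in seq_len(nit + 100)) {
    h <- sample_h(sim$panel$values, spec, truth$beta, truth$alpha,
                  v_h = 1e-4, h_current = h)$draw
    if (i > 100) acc <- acc + h
  }
  post <- acc / nit
  # truth is h = 0; Var(ln chi2_1) ~ 4.93 sets the attainable accuracy
  expect_lt(abs(mean(post)), 0.25)
})

test_that("run_mcmc bookkeeping, determinism and positivity hold", {
  spec <- model_spec(2, 1)
  sim <- simulate_tvpvar(spec, innovation_sds = list(beta = 0.01, alpha = 0.01, h = 0.05),
                         n_obs = 60, seed = 3)
  cfg <- mcmc_config(n_draws = 120, burn_in = 40, thin = 2, seed = 10)
  expect_identical(cfg$n_retained, 40L)
  d1 <- run_mcmc(sim$panel, spec, config = cfg)
  d2 <- run_mcmc(sim$panel, spec, config = cfg)
  expect_identical(dim(d1$beta)[1], 40L)
  expect_identical(d1$beta, d2$beta)
  expect_identical(d1$v_h, d2$v_h)
  expect_true(all(d1$v_beta > 0) && all(d1$v_alpha > 0) && all(d1$v_h > 0))
  expect_true(all(is.finite(d1$spectral_radius)))
  expect_identical(length(d1$dates), 59L)
  expect_error(mcmc_config(100, 100), "burn_in")
  expect_error(run_mcmc(sim$panel$values[1:8, ], spec, config = cfg),
               "too short")
})

test_that("sampler errors carry the failing cycle and block", {
  spec <- model_spec(2, 1)
  bad <- matrix(c(0, Inf), 12, 2)
  expect_error(run_mcmc(bad, spec, config = mcmc_config(10, 2)),
               "MCMC cycle")
})
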