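test_that("simulate_tvpvar reproduces exactly under a fixed seed and obeys shapes", {
  spec <- model_spec(3, 1, c("new", "pas", "pek"))
  sds <- list(beta = 0.02, alpha = 0.02, h = 0.05)
  a <- simulate_tvpvar(spec, innovation_sds = sds, n_obs = 242, seed = 9)
  b <- simulate_tvpvar(spec, innovation_sds = sds, n_obs = 242, seed = 9)
  expect_identical(a$panel$values, b$panel$values)
  expect_identical(a$truth$state_paths$beta, b$truth$state_paths$beta)

  # panel of T rows, states of T - s rows
  expect_identical(nrow_panel(a$panel), 242L)
  expect_identical(nrow(a$truth$state_paths$beta), 241L)
  expect_identical(ncol(a$truth$state_paths$beta), spec$k_beta)
  expect_identical(ncol(a$truth$state_paths$alpha), spec$k_alpha)

  expect_error(simulate_tvpvar(spec, innovation_sds = sds, n_obs = 1),
               "exceed the lag order")
  expect_error(
    simulate_tvpvar(spec, innovation_sds = sds, n_obs = 50,
                    init_states = list(beta = 0, alpha = 0, h = 0)),
    "dimensions")
})

test_that("observations satisfy the observation equation exactly given the truth", {
  spec <- model_spec(2, 2, c("a", "b"))
  sim <- simulate_tvpvar(spec, innovation_sds = list(beta = 0.05, alpha = 0.05, h = 0.1),
                         n_obs = 60, seed = 4)
  Y <- sim$panel$values
  st <- sim$truth$state_paths
  X <- build_design(Y, spec)
  # reconstruct the structural shocks implied by the truth; they must be
  # standard-normal sized and, crucially, finite and exact under inversion
  for (t in c(1, 10, 58)) {
    A <- alpha_to_A(st$alpha[t, ], spec$m)
    resid <- Y[t + spec$s, ] - as.numeric(X[, , t] %*% st$beta[t, ])
    eps <- as.numeric(A %*% resid) / exp(st$h[t, ] / 2)
    # re-apply the generator's map and recover y exactly
    y_back <- as.numeric(X[, , t] %*% st$beta[t, ]) +
      solve(A, eps * exp(st$h[t, ] / 2))
    expect_equal(y_back, unname(Y[t + spec$s, ]), tolerance = 1e-12)
  }
})

test_that("degenerate innovation scales give a constant-parameter VAR with known variance", {
  # m=1, s=1, beta = 0.5, h = 0: AR(1) with unit shocks; stationary
  # variance 1/(1-0.25) = 4/3 (Yule-Walker closed form)
  spec <- model_spec(1, 1, "y")
  sim <- simulate_tvpvar(spec,
                         init_states = list(beta = 0.5, alpha = numeric(0), h = 0),
                         innovation_sds = list(beta = 0, alpha = 0, h = 0),
                         n_obs = 50000, seed = 21)
  expect_equal(max(apply(sim$truth$state_paths$beta, 2, sd)), 0)
  v <- var(sim$panel$values[-(1:100), 1])
  expect_lt(abs(v - 4 / 3), 0.05)
  # lag-1 autocovariance = phi * variance
  y <- sim$panel$values[-(1:100), 1]
  g1 <- mean((y[-1] - mean(y)) * (y[-length(y)] - mean(y)))
  expect_lt(abs(g1 - 0.5 * 4 / 3), 0.05)
})

test_that("study-like panel matches the study calendar and data types", {
  out <- make_study_like_panel(study_scenario_config(seed = 5))
  p <- out$panel
  expect_identical(nrow_panel(p), 242L)
  expect_identical(p$dates[1], as.Date("2020-01-01"))
  expect_identical(p$dates[242], as.Date("2020-08-29"))  # leap-year arithmetic
  expect_identical(diff(as.integer(p$dates)), rep(1L, 241))

  new <- p$values[, "new"]
  expect_true(all(new[!is.na(new)] >= 0))
  expect_true(all(new[!is.na(new)] == round(new[!is.na(new)])))
  pek <- p$values[, "pek"]
  expect_true(all(pek[!is.na(pek)] > 0))

  # baseline: every month for every variable; zero for the epidemic series
  bl <- out$baseline
  expect_identical(nrow(as.data.frame(bl)), 36L)
  expect_true(all(bl$mean[bl$variable == "new"] == 0))

  # determinism and substream independence of the missingness config
  out2 <- make_study_like_panel(study_scenario_config(seed = 5))
  expect_identical(out2$panel$values, p$values)
  expect_error(study_scenario_config(missing_rate = 0.2), "missing_rate")

  nomiss <- make_study_like_panel(study_scenario_config(seed = 5, missing_rate = 0))
  expect_false(any(nomiss$panel$missing_mask))
})

test_that("inject_missing masks at the requested rate and keeps originals", {
  p <- daily_panel(as.Date("2020-01-01") + 0:241,
                   matrix(rnorm(242 * 3), 242, 3,
                          dimnames = list(NULL, c("new", "pas", "pek"))))
  expect_identical(inject_missing(p, 0, seed = 1)$missing_mask, p$missing_mask)
  expect_true(all(inject_missing(p, 1, seed = 1)$missing_mask))

  q <- inject_missing(p, 0.05, seed = 7)
  n_mask <- sum(q$missing_mask)
  # Binomial(726, 0.05): mean 36.3, sd 5.87; stay within 3 sd
  expect_gt(n_mask, 36.3 - 3 * sqrt(726 * 0.05 * 0.95))
  expect_lt(n_mask, 36.3 + 3 * sqrt(726 * 0.05 * 0.95))
  expect_identical(attr(q, "original"), p$values)
  expect_error(inject_missing(p, 1.2), "rate")
})

test_that("state random-walk increments match the declared innovation scale", {
  spec <- model_spec(2, 1, c("a", "b"))
  sim <- simulate_tvpvar(spec, innovation_sds = list(beta = 0.3, alpha = 0.1, h = 0.2),
                         n_obs = 5000, seed = 31)
  inc <- diff(sim$truth$state_paths$beta)
  expect_equal(unname(apply(inc, 2, sd)), rep(0.3, spec$k_beta),
               tolerance = 0.05)
  inc_h <- diff(sim$truth$state_paths$h)
  expect_equal(unname(apply(inc_h, 2, sd)), rep(0.2, 2), tolerance = 0.05)
})
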