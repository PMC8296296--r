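test_that("irf_at matches scalar and zero-coefficient closed forms", {
  # B = 0: psi_0 = diag(scale), zero afterwards
  sp <- model_spec(2, 1)
  psi <- irf_at(rep(0, 4), 0, c(1, 1), sp, 5)
  expect_equal(psi[1, , ], diag(2))
  expect_equal(max(abs(psi[-1, , ])), 0)

  # m=1, s=1, beta = 0.5: psi_k = 0.5^k
  sp1 <- model_spec(1, 1)
  psi1 <- irf_at(0.5, numeric(0), 1, sp1, 10)
  expect_equal(as.numeric(psi1), 0.5^(0:10), tolerance = 1e-14)
  expect_error(irf_at(0.5, numeric(0), 1, sp1, -1), "H must be")
  expect_error(irf_at(NaN, numeric(0), 1, sp1, 2), "non-finite")
})

test_that("irf_at equals the companion-matrix power oracle on random instances", {
  set.seed(202)
  for (rep in 1:25) {
    m <- sample(2:3, 1); s <- sample(1:2, 1)
    sp <- model_spec(m, s)
    beta <- as.numeric(vapply(seq_len(s), function(l)
      random_stable_beta(model_spec(m, 1), radius = 0.5 / s), numeric(m * m)))
    # interleave lag blocks into equation-major state layout
    Bm <- matrix(0, m, m * s)
    for (l in seq_len(s))
      Bm[, ((l - 1) * m + 1):(l * m)] <- matrix(beta[((l - 1) * m * m + 1):(l * m * m)],
                                                m, m, byrow = TRUE)
    beta_t <- as.numeric(t(Bm))
    al <- rnorm(sp$k_alpha, 0, 0.5)
    scale <- exp(rnorm(m, 0, 0.3))
    psi <- irf_at(beta_t, al, scale, sp, 12)
    oracle <- companion_irf(beta_t, al, scale, sp, 12)
    expect_lt(max(abs(psi - oracle)), 1e-12)
  }
})

const_draws <- function(beta_t, al, h, Te = 30, n = 40, spec = model_spec(2, 1)) {
  structure(list(
    beta = aperm(array(beta_t, c(spec$k_beta, Te, n)), c(3, 2, 1)),
    alpha = aperm(array(al, c(max(spec$k_alpha, 1), Te, n)),
                  c(3, 2, 1))[, , seq_len(spec$k_alpha), drop = FALSE],
    h = aperm(array(h, c(spec$m, Te, n)), c(3, 2, 1)),
    v_beta = matrix(1e-4, n, spec$k_beta),
    v_alpha = matrix(1e-4, n, spec$k_alpha),
    v_h = matrix(1e-4, n, spec$m),
    spec = spec, config = mcmc_config(n + 1, 1),
    dates = as.Date("2020-01-02") + 0:(Te - 1)),
    class = "tvpvar_draws")
}

test_that("a constant-state surface is constant over dates and matches irf_at", {
  spec <- model_spec(2, 1)
  beta_t <- c(0.5, 0.1, -0.2, 0.4); al <- 0.6; h <- c(0.4, -0.6)
  d <- const_draws(beta_t, al, h)
  surf <- tv_irf(d, H = 8, band_draws = 10)
  expect_s3_class(surf, "irf_surface")
  # constant across dates
  expect_lt(max(abs(sweep(surf$mean, c(2, 3, 4), surf$mean[1, , , ]))), 1e-12)
  # equals the closed-form single IRF with the average-volatility scale
  psi <- irf_at(beta_t, al, exp(h / 2), spec, 8)
  expect_equal(surf$mean[5, , , ], psi, tolerance = 1e-12)
  # time-t convention coincides for a constant path
  surf2 <- tv_irf(d, H = 8, convention = "time_t_volatility", band_draws = 0)
  expect_equal(surf2$mean, surf$mean, tolerance = 1e-12)
  # degenerate bands collapse onto the mean
  expect_equal(surf$lower, surf$mean, tolerance = 1e-10)
})

test_that("recursive identification zeroes the upper triangle at horizon 0", {
  spec <- model_spec(3, 1)
  set.seed(7)
  sim <- simulate_tvpvar(spec, innovation_sds = list(beta = 0.02, alpha = 0.02, h = 0.05),
                         n_obs = 80, seed = 2)
  d <- run_mcmc(sim$panel, spec, config = mcmc_config(80, 30, seed = 1))
  surf <- tv_irf(d, H = 3, band_draws = 0)
  h0 <- surf$mean[, 1, , ]                 # date x response x shock
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(max(abs(h0[, i, j])), 0)
})

test_that("equal-interval and time-point slices extract the right curves", {
  spec <- model_spec(2, 1)
  d <- const_draws(c(0.6, 0.2, 0.1, 0.5), 0.3, c(0, 0), Te = 50)
  surf <- tv_irf(d, H = 14, band_draws = 0)
  ei <- equal_interval_slices(surf, shock = 1, response = 1,
                              horizons = c(1, 7, 14))
  expect_identical(nrow(ei), 150L)
  # positive, monotone-decaying system: |day-14| <= |day-7| <= |day-1|
  v1 <- ei$value[ei$horizon == 1]
  v7 <- ei$value[ei$horizon == 7]
  v14 <- ei$value[ei$horizon == 14]
  expect_true(all(abs(v14) <= abs(v7) & abs(v7) <= abs(v1)))
  expect_error(equal_interval_slices(surf, 1, 1, horizons = 20),
               "not computed")

  tp <- timepoint_slices(surf, 1, 2,
                         dates = as.Date(c("2020-01-05", "2020-02-01")))
  expect_identical(nrow(tp), 30L)
  # stable model: responses decay toward zero with the horizon
  last <- tp$value[tp$horizon == 14]
  first <- tp$value[tp$horizon == 1]
  expect_true(all(abs(last) < abs(first)))
  expect_error(timepoint_slices(surf, 1, 1, dates = as.Date("2019-12-01")),
               "valid range")
  expect_error(equal_interval_slices(surf, "nope", 1), "unknown variable")
})

test_that("the long-format export carries every cell once", {
  spec <- model_spec(2, 1)
  d <- const_draws(c(0.5, 0, 0, 0.5), 0.2, c(0, 0), Te = 10)
  surf <- tv_irf(d, H = 4, band_draws = 5)
  df <- as.data.frame(surf)
  expect_identical(nrow(df), 10L * 5L * 2L * 2L)
  sub <- df[df$date == surf$dates[3] & df$horizon == 2, ]
  for (r in seq_len(nrow(sub))) {
    i <- match(sub$response[r], spec$var_names)
    j <- match(sub$shock[r], spec$var_names)
    expect_equal(sub$value[r], surf$mean[3, 3, i, j])
  }
  expect_true(all(c("lower", "upper") %in% names(df)))
})
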