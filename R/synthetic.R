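#' Simulate from the TVP-VAR-SV data-generating process
#'
#' Draws latent state paths as first-order random walks,
#' \eqn{\beta_{t+1} = \beta_t + u_{\beta t}}, \eqn{\alpha_{t+1} = \alpha_t +
#' u_{\alpha t}}, \eqn{h_{t+1} = h_t + u_{h t}} with independent Gaussian
#' innovations of the given standard deviations, then generates observations
#' exactly from \eqn{y_t = X_t \beta_t + A_t^{-1} \Sigma_t \varepsilon_t},
#' \eqn{\varepsilon_t \sim N(0, I_m)}.  With all innovation scales zero the
#' generator degenerates to a constant-parameter homoskedastic VAR.
#'
#' The first `s` observations (the presample the design needs) are drawn
#' i.i.d. standard normal unless `init_y` is supplied.
#'
#' @param spec a [model_spec()].
#' @param init_states list with `beta`, `alpha`, `h`: state values at the
#'   first effective time t = s+1.  Defaults to zeros.
#' @param innovation_sds list with `beta`, `alpha`, `h`: non-negative
#'   state-innovation standard deviations (scalars recycle across the block).
#' @param n_obs total panel length T (must exceed the lag order).
#' @param seed integer seed; the draw is reproducible.
#' @param start_date first calendar date of the panel.
#' @param init_y optional s x m matrix of presample observations.
#' @return list with `panel` (a [daily_panel()]) and `truth`, an object of
#'   class `synthetic_truth` holding the `state_paths` (class `state_paths`:
#'   matrices `beta` (T-s x k_beta), `alpha`, `h`), the innovation sds, the
#'   seed and the spec.
#' @export
simulate_tvpvar <- function(spec, init_states = NULL, innovation_sds,
                            n_obs, seed = 1L,
                            start_date = as.Date("2020-01-01"),
                            init_y = NULL) {
  stopifnot(inherits(spec, "tvpvar_spec"))
  n_obs <- as.integer(n_obs)
  if (n_obs <= spec$s) stop("n_obs must exceed the lag order s")
  sds <- list(beta = rep_len(as.numeric(innovation_sds$beta), spec$k_beta),
              alpha = rep_len(as.numeric(if (spec$k_alpha > 0)
                innovation_sds$alpha else numeric(1)), max(spec$k_alpha, 1L)),
              h = rep_len(as.numeric(innovation_sds$h), spec$k_h))
  if (spec$k_alpha == 0L) sds$alpha <- numeric(0)
  if (any(unlist(sds) < 0)) stop("innovation sds must be non-negative")
  if (is.null(init_states))
    init_states <- list(beta = numeric(spec$k_beta),
                        alpha = numeric(spec$k_alpha),
                        h = numeric(spec$k_h))
  if (length(init_states$beta) != spec$k_beta ||
      length(init_states$alpha) != spec$k_alpha ||
      length(init_states$h) != spec$k_h)
    stop("init_states dimensions do not match the spec")

  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  Te <- n_obs - spec$s
  beta <- random_walk_path(init_states$beta, sds$beta, Te)
  alpha <- random_walk_path(init_states$alpha, sds$alpha, Te)
  h <- random_walk_path(init_states$h, sds$h, Te)

  Y <- matrix(0, n_obs, spec$m)
  Y[seq_len(spec$s), ] <- if (is.null(init_y))
    matrix(rnorm(spec$s * spec$m), spec$s, spec$m) else as.matrix(init_y)
  for (t in seq_len(Te)) {
    x <- regressor_at(Y, t + spec$s, spec)          # p-vector
    mean_t <- as.numeric(matrix(beta[t, ], spec$m, spec$p, byrow = TRUE) %*% x)
    A <- alpha_to_A(alpha[t, ], spec$m)
    eps <- rnorm(spec$m) * exp(h[t, ] / 2)
    Y[t + spec$s, ] <- mean_t + forwardsolve(A, eps)
  }
  dates <- start_date + 0:(n_obs - 1)
  panel <- daily_panel(dates, Y, names = spec$var_names)
  truth <- structure(list(
    state_paths = state_paths(beta, alpha, h),
    innovation_sds = sds, seed = as.integer(seed), spec = spec),
    class = "synthetic_truth")
  list(panel = panel, truth = truth)
}

regressor_at <- function(Y, t, spec) {
  # stacked lags in order (y_{t-1}', ..., y_{t-s}')
  x <- unlist(lapply(seq_len(spec$s), function(l) Y[t - l, ]))
  if (spec$include_intercept) x <- c(1, x)
  x
}

random_walk_path <- function(init, sds, Te) {
  k <- length(init)
  if (k == 0L) return(matrix(0, Te, 0L))
  steps <- matrix(rnorm((Te - 1) * k), Te - 1, k, byrow = TRUE)
  steps <- sweep(steps, 2, sds, `*`)
  path <- matrix(0, Te, k)
  path[1, ] <- init
  if (Te > 1) path[-1, ] <- rep(init, each = Te - 1) + apply(steps, 2, cumsum)
  path
}

#' Latent state paths
#' @param beta,alpha,h state matrices with one row per effective time point.
#' @return object of class `state_paths`.
#' @export
state_paths <- function(beta, alpha, h) {
  beta <- as.matrix(beta); alpha <- as.matrix(alpha); h <- as.matrix(h)
  if (nrow(alpha) == 0L && ncol(alpha) == 0L) alpha <- matrix(0, nrow(beta), 0L)
  if (!(nrow(beta) == nrow(alpha) && nrow(beta) == nrow(h)))
    stop("state blocks must have equal row counts")
  if (any(!is.finite(beta)) || any(!is.finite(alpha)) || any(!is.finite(h)))
    stop("state paths must be finite")
  structure(list(beta = beta, alpha = alpha, h = h), class = "state_paths")
}

#' Study-scenario configuration
#'
#' Parameters of the realistic daily panel generator: 242 days from
#' 2020-01-01, epidemic counts with two Gaussian-shaped outbreak waves
#' (first peaking in early February, second in mid-June), subway passenger
#' flow with weekday structure and a lockdown collapse/recovery profile,
#' positive PM2.5 with a winter-to-summer seasonal decline, and sporadic
#' missingness.
#'
#' @param n_days panel length (default 242, i.e. 2020-01-01..2020-08-29).
#' @param wave1_peak_day,wave2_peak_day day indices of the two epidemic
#'   peaks (defaults 36 = 2020-02-05 and 169 = 2020-06-17).
#' @param wave1_amplitude,wave2_amplitude peak expected daily case counts.
#' @param wave1_width,wave2_width Gaussian widths of the waves, in days.
#' @param weekday_amplitude size of the weekday-vs-weekend mobility swing
#'   (same units as `pas`, here thousand trips).
#' @param pm_seasonal_amplitude winter-over-summer PM2.5 level difference.
#' @param missing_rate fraction of cells masked at random, in [0, 0.1].
#' @param seed integer; one seed drives independent named substreams per
#'   series, so adding a series never perturbs the others.
#' @return object of class `study_scenario_config`.
#' @export
study_scenario_config <- function(n_days = 242L,
                                  wave1_peak_day = 36L, wave2_peak_day = 169L,
                                  wave1_amplitude = 25, wave2_amplitude = 20,
                                  wave1_width = 10, wave2_width = 7,
                                  weekday_amplitude = 250,
                                  pm_seasonal_amplitude = 30,
                                  missing_rate = 0.02, seed = 1L) {
  if (missing_rate < 0 || missing_rate > 0.1)
    stop("missing_rate must lie in [0, 0.1]")
  if (any(c(wave1_amplitude, wave2_amplitude) < 0))
    stop("wave amplitudes must be non-negative")
  structure(list(n_days = as.integer(n_days),
                 wave1_peak_day = wave1_peak_day,
                 wave2_peak_day = wave2_peak_day,
                 wave1_amplitude = wave1_amplitude,
                 wave2_amplitude = wave2_amplitude,
                 wave1_width = wave1_width, wave2_width = wave2_width,
                 weekday_amplitude = weekday_amplitude,
                 pm_seasonal_amplitude = pm_seasonal_amplitude,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "study_scenario_config")
}

#' Generate a realistic study-like daily panel
#'
#' Emulates the study's three daily series for 2020-01-01 onward:
#' `new` — non-negative integer epidemic counts, Poisson draws around two
#' Gaussian-shaped intensity waves; `pas` — subway passenger flow (thousand
#' trips) with weekday/weekend structure, a collapse at the late-January
#' lockdown, gradual recovery, and a second dip at the June outbreak;
#' `pek` — positive daily mean PM2.5 with a winter-to-summer seasonal
#' decline and right-skewed day-to-day noise.  Also returns the matching
#' previous-year monthly baseline (zero for `new`: the epidemic had no 2019
#' analogue) for seasonal adjustment.
#'
#' @param config a [study_scenario_config()].
#' @return list with `panel` (a [daily_panel()], with missing cells injected
#'   at `config$missing_rate`) and `baseline` (a [monthly_baseline()]).
#' @export
make_study_like_panel <- function(config = study_scenario_config()) {
  stopifnot(inherits(config, "study_scenario_config"))
  n <- config$n_days
  dates <- as.Date("2020-01-01") + 0:(n - 1)
  day <- seq_len(n)
  dow <- as.POSIXlt(dates)$wday          # 0 = Sunday
  month <- as.POSIXlt(dates)$mon + 1L

  # epidemic counts: two bump-shaped waves, Poisson rounding
  lambda <- config$wave1_amplitude *
    exp(-0.5 * ((day - config$wave1_peak_day) / config$wave1_width)^2) +
    config$wave2_amplitude *
    exp(-0.5 * ((day - config$wave2_peak_day) / config$wave2_width)^2)
  with_substream(config$seed, "new", {
    new <- rpois(n, lambda)
  })

  # mobility: weekday level minus lockdown collapse, recovery, June dip
  weekend <- dow %in% c(0, 6)
  base_pas <- 1100 - config$weekday_amplitude * weekend
  lockdown <- 750 / (1 + exp(-(day - 24) / 2)) / (1 + exp((day - 100) / 25))
  june_dip <- 220 * exp(-0.5 * ((day - config$wave2_peak_day) / 12)^2)
  with_substream(config$seed, "pas", {
    pas <- pmax(base_pas - lockdown - june_dip + rnorm(n, 0, 40), 10)
  })

  # PM2.5: seasonal decline winter -> summer, right-skewed noise
  season <- 45 + config$pm_seasonal_amplitude *
    cos(2 * pi * (day - 15) / 365)
  with_substream(config$seed, "pek", {
    pek <- pmax(season * exp(rnorm(n, 0, 0.35)) *
                  (1 + 0.25 * sin(2 * pi * day / 7 + 1)), 1)
  })

  panel <- daily_panel(dates, cbind(new = new, pas = pas, pek = pek))
  if (config$missing_rate > 0)
    panel <- inject_missing(panel, config$missing_rate,
                            seed = substream_seed(config$seed, "missing"))

  # previous-year (2019) monthly baselines; zero for the epidemic series
  mo <- 1:12
  pas_base <- 1050 + 30 * cos(2 * pi * (mo - 7) / 12)  # pre-epidemic level
  pek_base <- 45 + config$pm_seasonal_amplitude * cos(2 * pi * (mo - 0.5) / 12)
  baseline <- monthly_baseline(data.frame(
    variable = rep(c("new", "pas", "pek"), each = 12),
    month = rep(mo, 3),
    mean = c(rep(0, 12), pas_base, pek_base)))
  list(panel = panel, baseline = baseline)
}

#' Mask panel cells at random
#'
#' Marks each cell missing independently with probability `rate`; the
#' original values are returned in the `original` attribute so tests can
#' compare imputations against held-out truth.
#'
#' @param panel a [daily_panel()].
#' @param rate masking probability in [0, 1].
#' @param seed integer seed.
#' @return a [daily_panel()] with the union of old and new missing cells.
#' @export
inject_missing <- function(panel, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  mask <- matrix(runif(length(panel$values)) < rate,
                 nrow(panel$values), ncol(panel$values))
  vals <- panel$values
  vals[mask] <- NA_real_
  out <- daily_panel(panel$dates, vals, names = panel$names,
                     missing_mask = panel$missing_mask | mask)
  attr(out, "original") <- panel$values
  out
}

# --- seeding helpers ---------------------------------------------------------

# deterministic 31-bit substream seed from (seed, name)
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483629)
}

with_substream <- function(seed, name, expr) {
  old <- set_local_seed(substream_seed(seed, name))
  on.exit(restore_seed(old), add = TRUE)
  eval.parent(substitute(expr))
}

set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
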