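#' MCMC diagnostics for monitored scalar chains
#'
#' For a small set of representative scalars (by default one coefficient
#' state, one contemporaneous-relation state and one log-volatility state
#' at the middle date, plus each block's first innovation standard
#' deviation) computes the sample autocorrelation function, the trace path,
#' a posterior summary, the Geweke convergence statistic comparing the
#' first 10% against the last 50% of the chain, and the inefficiency
#' factor \eqn{1 + 2\sum_l w_l \hat\rho_l} (Bartlett-windowed).
#'
#' @param draws a `tvpvar_draws` object with >= 100 retained draws.
#' @param monitored optional named list of numeric chains to diagnose
#'   instead of the defaults.
#' @param acf_lag maximum ACF lag (default 500, clipped to chain length - 1).
#' @return object of class `tvpvar_diagnostics`: a named list per scalar
#'   with `trace`, `acf`, `mean`, `sd`, `quantiles`, `geweke_cd`,
#'   `inefficiency`.
#' @export
diagnose <- function(draws, monitored = NULL, acf_lag = 500L) {
  if (is.null(monitored)) monitored <- default_monitored(draws)
  n <- length(monitored[[1]])
  if (n < 100) stop("need at least 100 retained draws to diagnose")
  lag_max <- min(acf_lag, n - 1L)
  out <- lapply(monitored, function(x) {
    rho <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE,
                          demean = TRUE)$acf)
    list(trace = x,
         acf = rho,
         mean = mean(x), sd = sd(x),
         quantiles = quantile(x, c(0.025, 0.16, 0.5, 0.84, 0.975)),
         geweke_cd = geweke_cd(x),
         inefficiency = inefficiency_factor(x))
  })
  structure(out, class = "tvpvar_diagnostics")
}

#' @export
print.tvpvar_diagnostics <- function(x, ...) {
  cat("<tvpvar_diagnostics>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s mean %8.4f  sd %7.4f  Geweke CD %6.2f  IF %6.2f\n",
                nm, x[[nm]]$mean, x[[nm]]$sd, x[[nm]]$geweke_cd,
                x[[nm]]$inefficiency))
  invisible(x)
}

default_monitored <- function(draws) {
  Te <- dim(draws$beta)[2]
  mid <- max(1L, Te %/% 2L)
  mon <- list(beta_mid = draws$beta[, mid, 1],
              h_mid = draws$h[, mid, 1],
              sd_beta1 = sqrt(draws$v_beta[, 1]),
              sd_h1 = sqrt(draws$v_h[, 1]))
  if (dim(draws$alpha)[3] > 0) {
    mon$alpha_mid <- draws$alpha[, mid, 1]
    mon$sd_alpha1 <- sqrt(draws$v_alpha[, 1])
  }
  mon
}

#' Geweke convergence statistic
#'
#' Compares the means of the first `frac1` and last `frac2` portions of a
#' chain, standardized by their long-run variances (Bartlett lag window);
#' asymptotically standard normal for a converged chain.
#'
#' @param x numeric chain.
#' @param frac1,frac2 portions compared (defaults 0.1 and 0.5).
#' @return the CD z-statistic.
#' @export
geweke_cd <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  x1 <- x[seq_len(max(2, floor(frac1 * n)))]
  x2 <- x[(n - max(2, floor(frac2 * n)) + 1):n]
  (mean(x1) - mean(x2)) /
    sqrt(long_run_var(x1) / length(x1) + long_run_var(x2) / length(x2))
}

# Bartlett-window long-run variance with bandwidth ~ n^(1/3)
long_run_var <- function(x) {
  n <- length(x)
  b <- max(1L, floor(0.75 * n^(1 / 3)))
  xc <- x - mean(x)
  g0 <- sum(xc^2) / n
  out <- g0
  for (l in seq_len(min(b, n - 1))) {
    gl <- sum(xc[1:(n - l)] * xc[(l + 1):n]) / n
    out <- out + 2 * (1 - l / (b + 1)) * gl
  }
  max(out, 1e-12)
}

#' Inefficiency factor of a chain
#'
#' \eqn{1 + 2 \sum_{l=1}^{B} (1 - l/(B+1)) \hat\rho_l} with Bartlett window
#' size `B = min(bw, n - 1)`; equals 1 for white noise and deflates the
#' effective sample size otherwise.
#'
#' @param x numeric chain.
#' @param bw window size; the default `max(5, n^(1/3)/2)` keeps the
#'   estimator's own Monte-Carlo noise near +/- 0.1 for independent chains.
#' @return inefficiency factor (>= values near 1 for independent draws).
#' @export
inefficiency_factor <- function(x, bw = NULL) {
  n <- length(x)
  if (is.null(bw)) bw <- max(5L, floor(0.5 * n^(1 / 3)))
  bw <- min(bw, n - 1L)
  rho <- as.numeric(acf(x, lag.max = bw, plot = FALSE)$acf)[-1]
  1 + 2 * sum((1 - seq_len(bw) / (bw + 1)) * rho)
}

#' Export diagnostics as a tidy table
#' @param diag a `tvpvar_diagnostics` object.
#' @return data.frame with one row per monitored scalar.
#' @export
diagnostics_table <- function(diag) {
  do.call(rbind, lapply(names(diag), function(nm) {
    d <- diag[[nm]]
    data.frame(scalar = nm, mean = d$mean, sd = d$sd,
               q16 = unname(d$quantiles[["16%"]]),
               median = unname(d$quantiles[["50%"]]),
               q84 = unname(d$quantiles[["84%"]]),
               geweke_cd = d$geweke_cd, inefficiency = d$inefficiency,
               acf_50 = if (length(d$acf) > 50) d$acf[51] else NA_real_)
  }))
}
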