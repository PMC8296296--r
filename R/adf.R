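#' Schwert's maximum augmentation lag
#'
#' The data-length-based cap on the number of augmentation lags in an ADF
#' regression, \eqn{\lfloor 12 (T/100)^{1/4} \rfloor}.  At the study's
#' sample size T = 242 the rule gives 14.
#'
#' @param T series length (>= 25).
#' @return integer maximum lag.
#' @examples
#' schwert_max_lag(242)  # 14
#' @export
schwert_max_lag <- function(T) {
  T <- as.integer(T)
  if (T < 25) stop("series too short for the Schwert rule (need T >= 25)")
  as.integer(floor(12 * (T / 100)^0.25))
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Fits the ADF regression
#' \deqn{\Delta y_t = \rho\, y_{t-1} + \sum_{i=1}^{p} \gamma_i \Delta y_{t-i}
#'   + d_t + e_t}
#' with deterministic terms \eqn{d_t} equal to nothing (`"none"`), a
#' constant (`"constant"`), or a constant plus linear trend (`"trend"`),
#' and reports the t-ratio on \eqn{\rho}.  Under `lag_rule = "aic"` the
#' augmentation order is chosen by minimising the Akaike criterion over
#' 0..`max_lag` on a common sample (the statistic is then re-estimated at
#' the chosen lag on the full usable sample); `lag_rule = "fixed"` uses
#' `lags` directly.  P-values use the MacKinnon (1994) response-surface
#' polynomials and the 1/5/10% critical values the MacKinnon (2010)
#' surfaces, both for a single I(1) series.
#'
#' @param series numeric vector, no missing values.
#' @param deterministic `"none"`, `"constant"` or `"trend"`.
#' @param max_lag maximum augmentation lag; default [schwert_max_lag()] of
#'   the series length.
#' @param lag_rule `"aic"` (default) or `"fixed"`.
#' @param lags the augmentation order when `lag_rule = "fixed"`.
#' @return object of class `adf_result`: `statistic`, `pvalue`,
#'   `chosen_lag`, `deterministic`, `critical` (1/5/10% values), `reject`
#'   (logical flags at the three levels) and `n_used`.
#' @export
adf_test <- function(series, deterministic = c("constant", "none", "trend"),
                     max_lag = NULL, lag_rule = c("aic", "fixed"),
                     lags = 0L) {
  deterministic <- match.arg(deterministic)
  lag_rule <- match.arg(lag_rule)
  y <- as.numeric(series)
  if (anyNA(y)) stop("series has missing values")
  if (sd(y) == 0) stop("constant series has no unit-root behaviour to test")
  n <- length(y)
  if (is.null(max_lag)) max_lag <- schwert_max_lag(n)
  if (max_lag >= n / 2) stop("max_lag must be below T/2")
  if (n <= 2 * max_lag + 10) stop("series too short for max_lag = ", max_lag)

  if (lag_rule == "fixed") {
    chosen <- as.integer(lags)
    if (chosen < 0 || chosen > max_lag) stop("lags must lie in 0..max_lag")
  } else {
    # common estimation sample at max_lag for comparable AICs
    aics <- vapply(0:max_lag, function(p)
      adf_fit(y, p, deterministic, trim = max_lag)$aic, numeric(1))
    chosen <- (0:max_lag)[which.min(aics)]
  }
  fit <- adf_fit(y, chosen, deterministic, trim = chosen)
  crit <- mackinnon_crit(deterministic, fit$nobs)
  pval <- mackinnon_pval(fit$stat, deterministic)
  structure(list(statistic = fit$stat, pvalue = pval,
                 chosen_lag = chosen, deterministic = deterministic,
                 critical = crit,
                 reject = setNames(fit$stat < crit, names(crit)),
                 n_used = fit$nobs),
            class = "adf_result")
}

#' @export
print.adf_result <- function(x, ...) {
  cat(sprintf("ADF test (%s), lag %d, n = %d\n  tau = %.4f, p = %.4f\n",
              x$deterministic, x$chosen_lag, x$n_used, x$statistic, x$pvalue))
  cat(sprintf("  critical values: 1%% %.3f, 5%% %.3f, 10%% %.3f\n",
              x$critical[1], x$critical[2], x$critical[3]))
  invisible(x)
}

# OLS fit of the ADF regression with p augmentation lags; `trim` rows are
# dropped from the front so different p can share a common sample
adf_fit <- function(y, p, deterministic, trim = p) {
  n <- length(y)
  dy <- diff(y)
  idx <- (trim + 1):(n - 1)             # rows of dy used as response
  resp <- dy[idx]
  X <- cbind(lag_level = y[idx])
  if (p > 0)
    for (i in 1:p) X <- cbind(X, dy[idx - i])
  if (deterministic %in% c("constant", "trend")) X <- cbind(X, const = 1)
  if (deterministic == "trend") X <- cbind(X, trend = seq_along(idx))
  fit <- lm.fit(X, resp)
  res <- fit$residuals
  nobs <- length(resp)
  k <- ncol(X)
  rss <- sum(res^2)
  sigma2 <- rss / (nobs - k)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[1, 1])
  list(stat = fit$coefficients[["lag_level"]] / se,
       aic = nobs * log(rss / nobs) + 2 * k,
       nobs = nobs)
}

# MacKinnon (2010) critical-value response surfaces, one I(1) series.
# Rows: 1%, 5%, 10%; crit = b0 + b1/T + b2/T^2 + b3/T^3.
.mackinnon_2010 <- list(
  none = rbind(c(-2.56574, -2.2358, -3.627, 0),
               c(-1.94100, -0.2686, -3.365, 31.223),
               c(-1.61682, 0.2656, -2.714, 25.364)),
  constant = rbind(c(-3.43035, -6.5393, -16.786, -79.433),
                   c(-2.86154, -2.8903, -4.234, -40.040),
                   c(-2.56677, -1.5384, -2.809, 0)),
  trend = rbind(c(-3.95877, -9.0531, -28.428, -134.155),
                c(-3.41049, -4.3904, -9.036, -45.374),
                c(-3.12705, -2.5856, -3.925, -22.380)))

mackinnon_crit <- function(deterministic, nobs) {
  B <- .mackinnon_2010[[deterministic]]
  crit <- B[, 1] + B[, 2] / nobs + B[, 3] / nobs^2 + B[, 4] / nobs^3
  setNames(crit, c("1%", "5%", "10%"))
}

# MacKinnon (1994) asymptotic p-value polynomials, one I(1) series.
.mackinnon_1994 <- list(
  none = list(star = -1.04, min = -19.04, max = Inf,
              small = c(0.6344, 1.2378, 0.032496),
              large = c(0.4797, 0.93557, -0.06999, 0.033066)),
  constant = list(star = -1.61, min = -18.83, max = 2.74,
                  small = c(2.1659, 1.4412, 0.038269),
                  large = c(1.7339, 0.93202, -0.12745, -0.010368)),
  trend = list(star = -2.89, min = -16.18, max = 0.7,
               small = c(3.2512, 1.6047, 0.049588),
               large = c(2.5261, 0.61654, -0.37956, -0.060285)))

mackinnon_pval <- function(stat, deterministic) {
  cf <- .mackinnon_1994[[deterministic]]
  if (stat > cf$max) return(1)
  if (stat < cf$min) return(0)
  co <- if (stat <= cf$star) cf$small else cf$large
  pnorm(sum(co * stat^(seq_along(co) - 1)))
}

#' ADF table across deterministic specifications
#'
#' Runs [adf_test()] on every series of a panel under the three
#' deterministic-term specifications (no deterministic terms; a drift
#' constant; constant plus trend) and formats the statistics with the usual
#' significance stars.
#'
#' @param panel a complete [daily_panel()], [adjusted_panel()] or matrix.
#' @param max_lag,lag_rule,lags passed to [adf_test()].
#' @return data.frame: one row per (variable, specification) with
#'   `statistic`, `chosen_lag`, `pvalue` and `stars`.
#' @export
adf_table <- function(panel, max_lag = NULL, lag_rule = "aic", lags = 0L) {
  vals <- if (is.matrix(panel)) panel else panel$values
  nm <- colnames(vals)
  if (is.null(nm)) nm <- paste0("y", seq_len(ncol(vals)))
  specs <- c("none", "constant", "trend")
  rows <- list()
  for (j in seq_len(ncol(vals))) for (d in specs) {
    r <- adf_test(vals[, j], deterministic = d, max_lag = max_lag,
                  lag_rule = lag_rule, lags = lags)
    stars <- if (r$pvalue < 0.01) "***" else if (r$pvalue < 0.05) "**"
    else if (r$pvalue < 0.10) "*" else ""
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm[j], deterministic = d,
      statistic = unname(r$statistic), chosen_lag = r$chosen_lag,
      pvalue = r$pvalue, stars = stars)
  }
  do.call(rbind, rows)
}
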