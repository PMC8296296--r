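#' Multiple imputation of missing daily values
#'
#' Chained-equations multiple imputation.  Each variable with missing cells
#' is modelled by a Bayesian linear regression on calendar covariates (a
#' scaled day index, day-of-week indicators, month indicators) plus the
#' other variables' same-day values; the sampler cycles through the
#' variables for `n_sweeps` sweeps, each time drawing the error variance
#' from its inverse-gamma conditional, the coefficients from their Gaussian
#' conditional, and the missing cells from the posterior predictive (fitted
#' value plus Gaussian noise).  Observed cells are never altered.  The
#' returned consensus panel is the cell-wise mean of the completed copies;
#' it is what the downstream model consumes.
#'
#' @param panel a [daily_panel()]; every variable needs >= 50% observed cells.
#' @param n_imputations number of completed copies (default 5).
#' @param n_sweeps chained-equation sweeps per copy (default 10).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @return list with `imputations` (list of completed [daily_panel()]s) and
#'   `consensus` (a completed [daily_panel()]).
#' @export
impute_missing <- function(panel, n_imputations = 5L, n_sweeps = 10L,
                           seed = 1L) {
  stopifnot(inherits(panel, "daily_panel"))
  mask <- panel$missing_mask
  obs_frac <- 1 - colMeans(mask)
  if (any(obs_frac == 0))
    stop("variable(s) fully missing: ",
         paste(panel$names[obs_frac == 0], collapse = ", "))
  if (any(obs_frac < 0.5))
    stop("variable(s) with fewer than 50% observed cells: ",
         paste(panel$names[obs_frac < 0.5], collapse = ", "))

  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  C <- calendar_covariates(panel$dates)
  copies <- vector("list", n_imputations)
  for (i in seq_len(n_imputations)) {
    vals <- initial_fill(panel$values, mask, panel$dates)
    if (any(mask)) {
      for (sweep in seq_len(n_sweeps)) {
        for (j in seq_len(ncol(vals))) {
          if (!any(mask[, j])) next
          X <- cbind(C, vals[, -j, drop = FALSE])
          vals[mask[, j], j] <- draw_imputation(
            y = vals[, j], X = X, miss = mask[, j])
        }
      }
    }
    copies[[i]] <- daily_panel(panel$dates, vals, names = panel$names,
                               missing_mask = matrix(FALSE, nrow(vals), ncol(vals)))
  }
  consensus_vals <- Reduce(`+`, lapply(copies, `[[`, "values")) / n_imputations
  consensus <- daily_panel(panel$dates, consensus_vals, names = panel$names)
  list(imputations = copies, consensus = consensus)
}

# day index (scaled to [0,1]), day-of-week and month indicator columns
calendar_covariates <- function(dates) {
  lt <- as.POSIXlt(dates)
  n <- length(dates)
  X <- cbind(intercept = 1,
             day = seq_len(n) / n)
  dow <- lt$wday
  for (d in 1:6) X <- cbind(X, as.numeric(dow == d))
  months <- sort(unique(lt$mon))
  if (length(months) > 1)
    for (mo in months[-1]) X <- cbind(X, as.numeric(lt$mon == mo))
  X
}

# month-mean starting fill (overall mean if a whole month is empty)
initial_fill <- function(vals, mask, dates) {
  mon <- as.POSIXlt(dates)$mon
  for (j in seq_len(ncol(vals))) {
    if (!any(mask[, j])) next
    overall <- mean(vals[!mask[, j], j])
    for (t in which(mask[, j])) {
      same <- mon == mon[t] & !mask[, j]
      vals[t, j] <- if (any(same)) mean(vals[same, j]) else overall
    }
  }
  vals
}

# one posterior-predictive draw for the missing entries of y given X
draw_imputation <- function(y, X, miss, ridge = 1e-6) {
  Xo <- X[!miss, , drop = FALSE]
  yo <- y[!miss]
  p <- ncol(Xo); n <- nrow(Xo)
  XtX <- crossprod(Xo) + ridge * diag(p)
  Xty <- crossprod(Xo, yo)
  R <- chol(XtX)
  bhat <- backsolve(R, forwardsolve(t(R), Xty))
  rss <- sum((yo - Xo %*% bhat)^2)
  df <- max(n - p, 3)
  sigma2 <- rss / stats::rchisq(1, df)   # inverse-gamma(df/2, rss/2) draw
  bdraw <- bhat + sqrt(sigma2) * backsolve(R, rnorm(p))
  Xm <- X[miss, , drop = FALSE]
  as.numeric(Xm %*% bdraw + rnorm(sum(miss), 0, sqrt(sigma2)))
}

#' Seasonal adjustment by previous-year monthly means
#'
#' Subtracts from every daily value the baseline mean of the same variable
#' in the same calendar month of the preceding year:
#' `adjusted[t, j] = raw[t, j] - baseline[j, month(t)]`.
#'
#' @param panel a complete [daily_panel()] (impute first).
#' @param baseline a [monthly_baseline()] covering all months in the panel.
#' @return object of class `adjusted_panel` with fields `dates`, `values`,
#'   `names`.
#' @export
seasonal_adjust <- function(panel, baseline) {
  stopifnot(inherits(panel, "daily_panel"))
  if (any(panel$missing_mask))
    stop("panel has missing cells; run impute_missing() first")
  mon <- as.POSIXlt(panel$dates)$mon + 1L
  vals <- panel$values
  for (j in seq_along(panel$names)) {
    bl <- vapply(sort(unique(mon)), function(mo)
      baseline_value(baseline, panel$names[j], mo), numeric(1))
    names(bl) <- sort(unique(mon))
    vals[, j] <- vals[, j] - bl[as.character(mon)]
  }
  structure(list(dates = panel$dates, values = vals, names = panel$names),
            class = "adjusted_panel")
}

#' @export
print.adjusted_panel <- function(x, ...) {
  cat(sprintf("<adjusted_panel> %d days (%s .. %s), series: %s\n",
              length(x$dates), format(x$dates[1]),
              format(x$dates[length(x$dates)]),
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.adjusted_panel <- function(x, ...) {
  data.frame(date = x$dates, x$values, check.names = FALSE)
}

#' Descriptive statistics per series
#'
#' N, mean, min, max and sample standard deviation for each variable of a
#' complete panel, in the layout of a data-description table.
#'
#' @param panel a complete [daily_panel()] or [adjusted_panel()].
#' @return data.frame with columns `variable`, `n`, `mean`, `min`, `max`,
#'   `sd`.
#' @export
describe <- function(panel) {
  vals <- if (is.matrix(panel)) panel else panel$values
  if (length(vals) == 0 || nrow(vals) == 0) stop("empty panel")
  if (anyNA(vals)) stop("panel has missing cells; impute first")
  nm <- if (is.matrix(panel)) colnames(vals) else panel$names
  data.frame(variable = nm,
             n = nrow(vals),
             mean = apply(vals, 2, mean),
             min = apply(vals, 2, min),
             max = apply(vals, 2, max),
             sd = apply(vals, 2, sd),
             row.names = NULL)
}
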