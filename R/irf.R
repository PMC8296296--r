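#' Impulse responses at one point in time
#'
#' Holding the states fixed at their time-t values, builds the reduced-form
#' lag matrices from \eqn{\beta_t}, sets the impact response
#' \eqn{\psi_0 = A_t^{-1}\,\mathrm{diag}(\mathrm{shock\_scale})} and
#' iterates \eqn{\psi_k = \sum_{i=1}^{\min(k,s)} B_i \psi_{k-i}}.  Under the
#' recursive identification, variables ordered before the shocked one do
#' not move on impact.
#'
#' @param beta_t length-k_beta coefficient state.
#' @param alpha_t length-k_alpha contemporaneous state.
#' @param shock_scale length-m vector of shock standard deviations (use
#'   `rep(1, m)` for unit shocks).
#' @param spec a [model_spec()].
#' @param H largest horizon (>= 0).
#' @return array `(H+1) x m x m`; entry `[k+1, i, j]` is the horizon-k
#'   response of variable i to a shock in variable j.
#' @export
irf_at <- function(beta_t, alpha_t, shock_scale, spec, H) {
  if (H < 0) stop("H must be >= 0")
  if (any(!is.finite(c(beta_t, alpha_t, shock_scale))))
    stop("non-finite states")
  psi <- irf_at_cpp(as.numeric(beta_t), as.numeric(alpha_t),
                    rep_len(shock_scale, spec$m), spec$m, spec$s,
                    as.integer(spec$include_intercept), as.integer(H))
  aperm(psi, c(3, 1, 2))
}

#' Time-varying impulse-response surface
#'
#' Evaluates [irf_at()] for every retained posterior draw at every date and
#' averages over draws.  The shock scale follows the chosen convention:
#' `"average_volatility"` (default) uses each series' posterior
#' time-average of \eqn{e^{h_{jt}/2}} so one-unit-standard-deviation shocks
#' are comparable across dates; `"time_t_volatility"` uses the date-t
#' volatility.  16-84% posterior bands are computed from a thinned subset
#' of draws when `band_draws > 0`.
#'
#' @param draws a `tvpvar_draws` object.
#' @param H largest horizon (default 14; guarded by `max_H`).
#' @param convention shock-scale convention.
#' @param band_draws number of (evenly thinned) draws used for the bands;
#'   0 disables bands.
#' @param max_H memory guard on the horizon.
#' @return object of class `irf_surface`: `mean` array
#'   `(T-s) x (H+1) x m x m` (`[t, k+1, i, j]` = response of i to shock j),
#'   optional `lower`/`upper` arrays, `dates`, `horizons`, `convention`,
#'   `spec`.
#' @export
tv_irf <- function(draws, H = 14L,
                   convention = c("average_volatility", "time_t_volatility"),
                   band_draws = 200L, max_H = 60L) {
  convention <- match.arg(convention)
  stopifnot(inherits(draws, "tvpvar_draws"))
  H <- as.integer(H)
  if (H > max_H) stop("H exceeds the configured cap (", max_H, ")")
  spec <- draws$spec
  nr <- dim(draws$beta)[1]; Te <- dim(draws$beta)[2]
  if (nr == 0) stop("no retained draws")

  Bd <- aperm(draws$beta, c(3, 2, 1))          # k x Te x R
  Ad <- aperm(draws$alpha, c(3, 2, 1))
  scl <- shock_scales(draws, convention)       # m x Te x R
  off <- as.integer(spec$include_intercept)

  flat <- irf_mean_cpp(Bd, Ad, scl, spec$m, spec$s, off, H)
  mean_surf <- flat_to_surface(flat, Te, H, spec$m)

  lower <- upper <- NULL
  if (band_draws > 0) {
    keep <- unique(round(seq(1, nr, length.out = min(band_draws, nr))))
    dv <- irf_draws_cpp(Bd[, , keep, drop = FALSE],
                        Ad[, , keep, drop = FALSE],
                        scl[, , keep, drop = FALSE],
                        spec$m, spec$s, off, H)
    qs <- apply(dv, c(1, 2), quantile, probs = c(0.16, 0.84))
    lower <- flat_to_surface(qs[1, , ], Te, H, spec$m)
    upper <- flat_to_surface(qs[2, , ], Te, H, spec$m)
  }
  structure(list(mean = mean_surf, lower = lower, upper = upper,
                 dates = draws$dates, horizons = 0:H,
                 convention = convention, spec = spec),
            class = "irf_surface")
}

# m x Te x R cube of shock standard deviations per convention
shock_scales <- function(draws, convention) {
  nr <- dim(draws$h)[1]; Te <- dim(draws$h)[2]; m <- dim(draws$h)[3]
  scl <- array(0, dim = c(m, Te, nr))
  for (r in seq_len(nr)) {
    hr <- matrix(draws$h[r, , ], Te, m)
    sig <- exp(t(hr) / 2)                    # m x Te
    if (convention == "average_volatility")
      sig <- matrix(rowMeans(sig), m, Te)
    scl[, , r] <- sig
  }
  scl
}

# (m*m*(H+1)) x Te flat layout (i + m j + m^2 k, 0-based) -> Te x (H+1) x m x m
flat_to_surface <- function(flat, Te, H, m) {
  arr <- array(flat, dim = c(m, m, H + 1, Te))
  aperm(arr, c(4, 3, 1, 2))
}

#' @export
print.irf_surface <- function(x, ...) {
  cat(sprintf("<irf_surface> %d dates x horizons 0..%d, %d variables (%s), shocks scaled by %s\n",
              dim(x$mean)[1], max(x$horizons), x$spec$m,
              paste(x$spec$var_names, collapse = ", "), x$convention))
  invisible(x)
}

#' @export
as.data.frame.irf_surface <- function(x, ...) {
  dn <- x$spec$var_names
  grid <- expand.grid(date = seq_along(x$dates), horizon = x$horizons,
                      response = dn, shock = dn, stringsAsFactors = FALSE)
  # mean is date x horizon x response x shock; expand.grid varies date fastest
  val <- as.numeric(x$mean)
  out <- data.frame(date = x$dates[grid$date], horizon = grid$horizon,
                    shock = grid$shock, response = grid$response,
                    value = val)
  if (!is.null(x$lower)) {
    out$lower <- as.numeric(x$lower)
    out$upper <- as.numeric(x$upper)
  }
  out
}

resolve_var <- function(spec, v) {
  if (is.character(v)) {
    i <- match(v, spec$var_names)
    if (is.na(i)) stop("unknown variable '", v, "'")
    i
  } else as.integer(v)
}

#' Equal-interval impulse-response trajectories
#'
#' Extracts, for one (shock, response) pair, the response at fixed horizons
#' as a function of calendar date — the "equal-interval" reporting mode
#' with 1-day, 1-week and 2-week horizons as short/mid/long term.
#'
#' @param surface an [tv_irf()] result.
#' @param shock,response variable names or indices.
#' @param horizons horizons to trace (must be <= the surface's maximum).
#' @return data.frame with columns `date`, `horizon`, `value`.
#' @export
equal_interval_slices <- function(surface, shock, response,
                                  horizons = c(1, 7, 14)) {
  stopifnot(inherits(surface, "irf_surface"))
  if (any(!horizons %in% surface$horizons))
    stop("horizon(s) not computed: ",
         paste(setdiff(horizons, surface$horizons), collapse = ", "),
         " (surface holds 0..", max(surface$horizons), ")")
  j <- resolve_var(surface$spec, shock)
  i <- resolve_var(surface$spec, response)
  do.call(rbind, lapply(horizons, function(hh)
    data.frame(date = surface$dates, horizon = hh,
               value = surface$mean[, which(surface$horizons == hh), i, j])))
}

#' Fixed-date impulse-response curves
#'
#' Extracts, for one (shock, response) pair, the full horizon profile at
#' selected calendar dates — the "time-point" reporting mode (defaults:
#' 22 January, 30 March and 17 June 2020, representative of the first
#' outbreak, the inter-wave lull and the second outbreak).
#'
#' @param surface an [tv_irf()] result.
#' @param shock,response variable names or indices.
#' @param dates `Date` vector; must lie inside the surface's date range.
#' @return data.frame with columns `date`, `horizon`, `value`.
#' @export
timepoint_slices <- function(surface, shock, response,
                             dates = as.Date(c("2020-01-22", "2020-03-30",
                                               "2020-06-17"))) {
  stopifnot(inherits(surface, "irf_surface"))
  dates <- as.Date(dates)
  idx <- match(dates, surface$dates)
  if (anyNA(idx))
    stop("date(s) outside the surface: ",
         paste(format(dates[is.na(idx)]), collapse = ", "),
         " (valid range ", format(surface$dates[1]), " .. ",
         format(surface$dates[length(surface$dates)]), ")")
  j <- resolve_var(surface$spec, shock)
  i <- resolve_var(surface$spec, response)
  do.call(rbind, lapply(seq_along(dates), function(d)
    data.frame(date = dates[d], horizon = surface$horizons,
               value = surface$mean[idx[d], , i, j])))
}
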