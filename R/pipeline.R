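#' End-to-end pipeline configuration
#'
#' Bundles every stage's settings: input paths (or `NULL` to simulate a
#' study-like panel), model and prior, MCMC profile, and IRF reporting
#' choices.  The `"full"` profile runs 10,000 cycles with 1,000 burn-in;
#' the `"fast"` profile (2,000 / 200) is meant for smoke runs and CI.
#'
#' @param panel_path,baseline_path CSV inputs ([read_panel()] /
#'   [read_baseline()] formats); both `NULL` to generate synthetic inputs.
#' @param out_dir output directory (created if absent).
#' @param var_names variable ordering for the recursive identification.
#' @param lag VAR lag order.
#' @param profile `"fast"` or `"full"`, or `NULL` to use `n_draws`/`burn_in`.
#' @param n_draws,burn_in explicit MCMC settings (override the profile).
#' @param H largest IRF horizon.
#' @param irf_horizons equal-interval horizons to report.
#' @param irf_dates fixed reporting dates.
#' @param convention IRF shock-scale convention, see [tv_irf()].
#' @param n_imputations multiple-imputation copies.
#' @param seed master seed for every stage.
#' @param quiet suppress progress messages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(panel_path = NULL, baseline_path = NULL,
                            out_dir = "tvpvar-output",
                            var_names = c("new", "pas", "pek"),
                            lag = 1L, profile = c("fast", "full"),
                            n_draws = NULL, burn_in = NULL,
                            H = 14L, irf_horizons = c(1, 7, 14),
                            irf_dates = as.Date(c("2020-01-22", "2020-03-30",
                                                  "2020-06-17")),
                            convention = "average_volatility",
                            n_imputations = 5L, seed = 1L, quiet = TRUE) {
  if (is.null(n_draws)) {
    profile <- match.arg(profile)
    n_draws <- if (profile == "full") 10000L else 2000L
    burn_in <- if (profile == "full") 1000L else 200L
  } else profile <- "custom"
  structure(list(panel_path = panel_path, baseline_path = baseline_path,
                 out_dir = out_dir, var_names = var_names, lag = as.integer(lag),
                 profile = profile, n_draws = as.integer(n_draws),
                 burn_in = as.integer(burn_in), H = as.integer(H),
                 irf_horizons = irf_horizons, irf_dates = as.Date(irf_dates),
                 convention = convention,
                 n_imputations = as.integer(n_imputations),
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> impute -> seasonally adjust -> describe ->
#' ADF screen -> TVP-VAR-SV MCMC -> diagnostics -> time-varying IRFs, and
#' writes every artifact as CSV plus a JSON manifest into
#' `config$out_dir`.  Identical config and seed give a byte-identical
#' bundle.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory results: `panel`,
#'   `adjusted`, `descriptives`, `adf`, `draws`, `diagnostics`, `surface`,
#'   and the written `files`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(stage, ...) if (!config$quiet)
    message(sprintf("[%s +%.1fs] %s", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    sprintf(...)))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, df) {
    path <- file.path(config$out_dir, name)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
    path
  }

  # --- inputs ---------------------------------------------------------------
  inputs <- run_stage("input", {
    if (is.null(config$panel_path)) {
      say("input", "simulating study-like panel (seed %d)", config$seed)
      make_study_like_panel(study_scenario_config(seed = config$seed))
    } else {
      if (!file.exists(config$panel_path))
        stop("panel file not found: ", config$panel_path)
      if (is.null(config$baseline_path) || !file.exists(config$baseline_path))
        stop("baseline file not found: ",
             if (is.null(config$baseline_path)) "(none given)"
             else config$baseline_path)
      list(panel = read_panel(config$panel_path),
           baseline = read_baseline(config$baseline_path))
    }
  })

  # --- preprocess -----------------------------------------------------------
  adjusted <- run_stage("preprocess", {
    imp <- impute_missing(inputs$panel, n_imputations = config$n_imputations,
                          seed = config$seed)
    seasonal_adjust(imp$consensus, inputs$baseline)
  })
  descriptives <- run_stage("describe", describe(adjusted))
  emit("descriptives.csv", round_df(descriptives, 3))

  # --- stationarity ---------------------------------------------------------
  adf <- run_stage("adf", adf_table(adjusted))
  emit("adf_table.csv", round_df(adf, 3))
  say("adf", "ADF screen done")

  # --- model fit ------------------------------------------------------------
  spec <- model_spec(length(config$var_names), config$lag, config$var_names)
  draws <- run_stage("mcmc", {
    say("mcmc", "running %d cycles (burn-in %d)", config$n_draws,
        config$burn_in)
    run_mcmc(adjusted, spec, prior_config(),
             mcmc_config(config$n_draws, config$burn_in, seed = config$seed),
             progress = !config$quiet)
  })
  diagnostics <- NULL
  if (dim(draws$beta)[1] >= 100) {
    diagnostics <- run_stage("diagnose", diagnose(draws))
    emit("diagnostics.csv", round_df(diagnostics_table(diagnostics), 5))
  } else say("diagnose", "skipped (fewer than 100 retained draws)")

  # --- impulse responses ----------------------------------------------------
  surface <- run_stage("irf", tv_irf(draws, H = config$H,
                                     convention = config$convention))
  emit("irf_surface.csv", round_df(as.data.frame(surface), 6))
  keep_h <- config$irf_horizons[config$irf_horizons <= config$H]
  ei <- do.call(rbind, lapply(seq_len(spec$m), function(j)
    do.call(rbind, lapply(seq_len(spec$m), function(i) {
      df <- equal_interval_slices(surface, j, i, keep_h)
      cbind(shock = spec$var_names[j], response = spec$var_names[i], df)
    }))))
  emit("irf_equal_interval.csv", round_df(ei, 6))
  keep_dates <- config$irf_dates[config$irf_dates %in% surface$dates]
  if (length(keep_dates) > 0) {
    tp <- do.call(rbind, lapply(seq_len(spec$m), function(j)
      do.call(rbind, lapply(seq_len(spec$m), function(i) {
        df <- timepoint_slices(surface, j, i, keep_dates)
        cbind(shock = spec$var_names[j], response = spec$var_names[i], df)
      }))))
    emit("irf_timepoints.csv", round_df(tp, 6))
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    package = "tvpvarsv",
    version = as.character(utils::packageVersion("tvpvarsv")),
    seed = config$seed, profile = config$profile,
    n_draws = config$n_draws, burn_in = config$burn_in,
    retained = dim(draws$beta)[1],
    lag = config$lag, variables = config$var_names,
    H = config$H, convention = config$convention,
    n_days = nrow_panel(inputs$panel),
    files = basename(files))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  files <- c(files, manifest_path)
  say("done", "pipeline complete (%d files)", length(files))
  invisible(list(panel = inputs$panel, adjusted = adjusted,
                 descriptives = descriptives, adf = adf, draws = draws,
                 diagnostics = diagnostics, surface = surface,
                 files = files))
}

# stable CSV output: round numerics so files are byte-reproducible
round_df <- function(df, digits) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  df
}
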