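#' Ordinary least squares fit with slope inference
#'
#' Simple linear regression y ~ x with the exact small-sample t-based
#' p-value for the slope and its 95% confidence interval; the workhorse for
#' cross-species trait correlations (e.g. R_max against T_opt, cell width,
#' or aspect ratio).
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list of class `linear_fit`: `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `r_squared`, `p_value` (slope t-test), `ci95_slope`,
#'   `n`, `fit` (the underlying `lm`).
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need >= 3 finite (x, y) pairs")
  if (var(x) == 0) stop("x is constant; slope undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = 0.95)
  structure(list(
    slope = unname(coef(fit)["x"]),
    slope_se = sm$coefficients["x", "Std. Error"],
    intercept = unname(coef(fit)["(Intercept)"]),
    intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
    r_squared = sm$r.squared,
    p_value = sm$coefficients["x", "Pr(>|t|)"],
    ci95_slope = unname(ci[1, ]),
    n = length(x), fit = fit
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "slope = %.3f +/- %.3f [%.3f, %.3f], R^2 = %.3f, P = %.4g (n = %d)\n",
    x$slope, x$slope_se, x$ci95_slope[1], x$ci95_slope[2], x$r_squared,
    x$p_value, x$n))
  invisible(x)
}

#' Compare a fitted slope against unity
#'
#' Used to ask whether two thermal optima measured on the same strains
#' (e.g. T_opt of swimming speed vs T_opt of Fv/Fm) scale one-to-one: the
#' relationship is consistent with slope 1 when the 95% confidence interval
#' of the fitted slope contains 1.
#'
#' @param fit a [linear_fit()].
#' @return list with `consistent_with_one` (logical), `ci95_slope`,
#'   `slope`.
#' @export
slope_vs_one_test <- function(fit) {
  stopifnot(inherits(fit, "linear_fit"))
  ci <- fit$ci95_slope
  list(consistent_with_one = ci[1] < 1 && 1 < ci[2],
       ci95_slope = ci, slope = fit$slope)
}

#' Stability check of speed over time, per replicate
#'
#' For benchmarking recordings at constant temperature: fits an ordinary
#' least-squares slope of speed against time within each replicate, then
#' pools the replicate slopes (mean with a t-based 95% CI) and flags
#' whether the pooled CI includes 0, i.e. whether the control speed is
#' stable over the recording.
#'
#' @param data data.frame with columns `replicate`, `time_s`, `speed_um_s`.
#' @return list with `per_replicate` (data.frame of slopes), `mean_slope`,
#'   `ci95`, `stable` (CI includes 0).
#' @export
ramp_slope_check <- function(data) {
  stopifnot(all(c("replicate", "time_s", "speed_um_s") %in% names(data)))
  slopes <- vapply(split(data, data$replicate), function(d) {
    unname(coef(lm(speed_um_s ~ time_s, data = d))["time_s"])
  }, numeric(1))
  m <- mean(slopes)
  n <- length(slopes)
  if (n < 2) stop("need >= 2 replicates")
  se <- sd(slopes) / sqrt(n)
  ci <- m + c(-1, 1) * qt(0.975, n - 1) * se
  list(per_replicate = data.frame(replicate = names(slopes),
                                  slope = unname(slopes)),
       mean_slope = m, ci95 = ci, stable = ci[1] <= 0 && 0 <= ci[2])
}

#' Welch two-sample comparison of TPC parameters between conditions
#'
#' Thin wrapper used when comparing fitted parameters (T_opt, R_max, rise
#' slope) between, e.g., slow and fast temperature ramps. Welch's form is
#' the default since equal variances are not assumed.
#'
#' @param a,b numeric vectors of per-replicate parameter values.
#' @return `htest` from [stats::t.test()].
#' @export
compare_conditions <- function(a, b) {
  t.test(a, b, var.equal = FALSE)
}

#' Assign thermal classes from swimming T_opt
#'
#' Cryophilic: T_opt below 10 deg C; mesophilic: above 20 deg C; strains in
#' between are labelled intermediate.
#'
#' @param topt_C numeric vector of optimum temperatures.
#' @return character vector.
#' @export
thermal_class <- function(topt_C) {
  ifelse(topt_C < 10, "cryophilic",
         ifelse(topt_C > 20, "mesophilic", "intermediate"))
}

#' Run the full simulate-track-classify-fit pipeline
#'
#' End-to-end orchestration for one species: for each temperature and
#' replicate, simulates a population from a known thermal performance
#' curve, renders nothing (spot tables go straight to the tracker), links
#' and filters tracks, computes metrics and motile classification,
#' summarises replicates, and fits a TPC to the per-temperature motile
#' mean speeds. Deterministic given `seed`; all derived seeds stay below
#' 2^31. When `out_dir` is given, writes `summary.csv`, `fit.json`,
#' `curve.csv` and a `provenance.json` echoing the configuration.
#'
#' @param true_params generating TPC parameters (named list).
#' @param model generating/fitted model name.
#' @param temperatures incubation temperatures (deg C).
#' @param n_replicates replicates per temperature.
#' @param n_cells cells per replicate.
#' @param motile_fraction expected motile fraction at permissive
#'   temperatures.
#' @param noise_cv speed coefficient of variation.
#' @param seed master seed.
#' @param n_boot bootstrap replicates for the final fit.
#' @param link_cfg a [link_config()].
#' @param sim_cfg base [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `summaries` (per-replicate data.frame), `by_temp`
#'   (per-temperature mean/sd of motile speed), `fit` (a `tpc_fit`).
#' @export
run_pipeline <- function(true_params, model = "thomas2",
                         temperatures = c(0, 2.5, 5, 10, 15, 20, 25, 30),
                         n_replicates = 3, n_cells = 60,
                         motile_fraction = 0.7, noise_cv = 0.1, seed = 1,
                         n_boot = 200, link_cfg = link_config(),
                         sim_cfg = sim_config(), out_dir = NULL) {
  rows <- list()
  for (ti in seq_along(temperatures)) {
    for (r in seq_len(n_replicates)) {
      sub_seed <- (seed * 1000L + ti * 10L + r) %% .Machine$integer.max
      sim <- simulate_population(true_params, model, temperatures[ti],
                                 n_cells, motile_fraction, noise_cv,
                                 seed = sub_seed, config = sim_cfg)
      if (nrow(sim$spots) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          species = "synthetic", temperature_C = temperatures[ti],
          replicate = r, n_tracks = 0, n_motile = 0, motile_fraction = NA,
          motile_mean_speed_um_s = NA, motile_speed_sd = NA,
          motile_mean_dispersal_um_s = NA, motile_dispersal_sd = NA)
        next
      }
      tracks <- link_tracks(sim$spots, link_cfg)
      tracks <- filter_tracks(tracks, link_cfg$min_track_frames,
                              quiet = TRUE)
      if (nrow(tracks) == 0) next
      met <- classify_motile(tracks_metrics(tracks, fps = sim_cfg$fps),
                             recording_duration_s = sim_cfg$duration_s)
      rows[[length(rows) + 1]] <- population_summary(
        met, species = "synthetic", temperature_C = temperatures[ti],
        replicate = r)
    }
  }
  summaries <- do.call(rbind, rows)
  # per-temperature rate table for fitting: mean over replicate motile means;
  # temperatures where nothing swims contribute rate 0
  by_temp <- do.call(rbind, lapply(split(summaries, summaries$temperature_C),
    function(d) {
      v <- d$motile_mean_speed_um_s
      v[is.na(v)] <- 0
      data.frame(temperature_C = d$temperature_C[1], rate = mean(v),
                 sd = max(sd(v), 1e-2), n = length(v))
    }))
  rownames(by_temp) <- NULL
  fit <- fit_tpc(by_temp, model = model, n_boot = n_boot, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summaries, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    write_tpc_fit(fit, file.path(out_dir, "fit.json"),
                  file.path(out_dir, "curve.csv"))
    jsonlite::write_json(list(
      seed = seed, model = model, temperatures = temperatures,
      n_replicates = n_replicates, n_cells = n_cells,
      motile_fraction = motile_fraction, noise_cv = noise_cv,
      n_boot = n_boot,
      package_version = as.character(utils::packageVersion("snowmotility"))
    ), file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  }
  list(summaries = summaries, by_temp = by_temp, fit = fit)
}
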