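#' Thermal performance curve model functions
#'
#' Rate-versus-temperature models for unimodal thermal responses of
#' biological rates (here: swimming speed in um/s, or the photosynthetic
#' yield Fv/Fm).
#'
#' `pawar_rate()` is the modified Sharpe-Schoolfield form parameterised by
#' the optimum temperature:
#' \deqn{rate(T) = \frac{r_{tref}\,
#'   e^{-\frac{e}{k}\left(\frac{1}{T + 273.15} - \frac{1}{t_{ref} + 273.15}\right)}}
#'   {1 + \frac{e}{e_h - e}\,
#'   e^{\frac{e_h}{k}\left(\frac{1}{T_{opt} + 273.15} - \frac{1}{T + 273.15}\right)}}}
#' with `e` the activation energy (eV), `eh > e` the high-temperature
#' inactivation energy (eV), `topt` the optimum (deg C), `tref` the
#' standardisation temperature (deg C, default 1, a temperature at which
#' rates are not yet inactivated) and `k` Boltzmann's constant,
#' 8.62e-5 eV/K. Temperatures enter in kelvin via `T + 273.15`.
#'
#' `thomas2_rate()` is the difference-of-exponentials form
#' \deqn{rate(T) = a e^{bT} - (c + d e^{eT})}
#' where `a` is the rate at 0 deg C (when `c = d = 0`), `b` the exponential
#' rise coefficient (1/degC), `c` a temperature-independent inactivation
#' term, and `d`, `e` the scale and temperature sensitivity of the
#' exponential inactivation. The raw value can be negative beyond the
#' thermal limits; set `floor0 = TRUE` to clamp for reporting (fitting uses
#' the raw value).
#'
#' `weibull_rate()` is the 4-parameter Weibull-shaped curve
#' (parameters `a` = peak rate, `topt`, breadth `b`, shape `c`), included
#' for AIC comparison.
#'
#' @param temp temperature (deg C), vectorised.
#' @param r_tref,e,eh,topt,tref Pawar parameters (see above).
#' @param a,b,c,d Thomas2 / Weibull parameters (see above).
#' @param e_coef Thomas2 inactivation temperature sensitivity (1/degC).
#' @param floor0 clamp negative Thomas2 rates to 0.
#' @return rate in the units of `r_tref` / `a`.
#' @examples
#' pawar_rate(5, r_tref = 30, e = 0.6, eh = 4, topt = 8)
#' thomas2_rate(0, a = 40, b = 0.08, c = 0, d = 0, e_coef = 0.3) # = a
#' @name tpc_models
NULL

K_BOLTZ <- 8.62e-5 # eV per kelvin

#' @rdname tpc_models
#' @export
pawar_rate <- function(temp, r_tref, e, eh, topt, tref = 1) {
  tk <- temp + 273.15
  num <- r_tref * exp(-e / K_BOLTZ * (1 / tk - 1 / (tref + 273.15)))
  den <- 1 + (e / (eh - e)) *
    exp(eh / K_BOLTZ * (1 / (topt + 273.15) - 1 / tk))
  num / den
}

#' @rdname tpc_models
#' @export
thomas2_rate <- function(temp, a, b, c, d, e_coef, floor0 = FALSE) {
  r <- a * exp(b * temp) - (c + d * exp(e_coef * temp))
  if (floor0) pmax(r, 0) else r
}

#' @rdname tpc_models
#' @export
weibull_rate <- function(temp, a, topt, b, c) {
  f <- ((c - 1) / c)^(1 / c)
  z <- (temp - topt) / b + f
  ifelse(z > 0,
         a * ((c - 1) / c)^((1 - c) / c) * z^(c - 1) *
           exp(-z^c + (c - 1) / c),
         0)
}

tpc_n_params <- c(pawar = 4L, thomas2 = 5L, weibull = 4L)

#' Evaluate a named TPC model
#'
#' @param model `"pawar"`, `"thomas2"` or `"weibull"`.
#' @param temp temperature (deg C).
#' @param params named list/vector of the model's parameters
#'   (`pawar`: r_tref, e, eh, topt, optionally tref; `thomas2`: a, b, c, d,
#'   e_coef; `weibull`: a, topt, b, c).
#' @return rate.
#' @export
tpc_rate <- function(model, temp, params) {
  p <- as.list(params)
  switch(match.arg(model, c("pawar", "thomas2", "weibull")),
    pawar = pawar_rate(temp, p$r_tref, p$e, p$eh, p$topt,
                       p$tref %||% 1),
    thomas2 = thomas2_rate(temp, p$a, p$b, p$c, p$d, p$e_coef),
    weibull = weibull_rate(temp, p$a, p$topt, p$b, p$c))
}

#' Locate the thermal optimum of a fitted curve
#'
#' Numeric argmax of the model curve on a dense grid over the observed
#' temperature range extended by 2 deg C on each side. For the Pawar model
#' the `topt` parameter is reported directly and cross-checked against the
#' numeric argmax (warning if they disagree by more than 0.5 deg C, which
#' indicates the fitted optimum fell outside the meaningful range).
#'
#' @param model model name.
#' @param params fitted parameters.
#' @param temp_range numeric length-2, observed temperature range (deg C).
#' @param grid_step grid resolution (deg C).
#' @param extend range extension on each side (deg C).
#' @return list with `topt_C` and `rmax`.
#' @export
derive_topt_rmax <- function(model, params, temp_range, grid_step = 0.01,
                             extend = 2) {
  grid <- seq(temp_range[1] - extend, temp_range[2] + extend, by = grid_step)
  vals <- tpc_rate(model, grid, params)
  i <- which.max(vals)
  topt_num <- grid[i]
  if (model == "pawar") {
    topt <- as.list(params)$topt
    if (is.finite(vals[i]) && abs(topt - topt_num) > 0.5) {
      warning(sprintf(
        "pawar topt parameter (%.2f) and numeric argmax (%.2f) disagree",
        topt, topt_num))
    }
    list(topt_C = topt, rmax = tpc_rate(model, topt, params))
  } else {
    list(topt_C = topt_num, rmax = vals[i])
  }
}

# ---- fitting -----------------------------------------------------------

# Deterministic multi-start grids. Fitting happens on an unconstrained
# transformed scale: positive parameters are log-transformed and the
# eh > e constraint is enforced by eh = e + exp(phi).
tpc_start_grid <- function(model, data) {
  tmin <- min(data$temperature_C)
  rmax_obs <- max(data$rate)
  r_cold <- data$rate[which.min(data$temperature_C)]
  temps <- sort(unique(data$temperature_C))
  switch(model,
    pawar = expand.grid(
      r_tref = max(r_cold, 0.1 * rmax_obs, 1e-3),
      e = c(0.3, 0.6, 1.0),
      eh = c(2, 4, 8),
      topt = temps),
    thomas2 = {
      # data-driven rise: log-linear fit of the rising limb up to the peak
      t_peak <- data$temperature_C[which.max(data$rate)]
      rising <- data[data$temperature_C <= t_peak & data$rate > 0, ]
      if (nrow(rising) >= 2 && var(rising$temperature_C) > 0) {
        cf <- coef(lm(log(rate) ~ temperature_C, data = rising))
        a0 <- exp(cf[[1]])
        b0 <- max(cf[[2]], 1e-3)
      } else {
        a0 <- max(r_cold, 1e-3)
        b0 <- 0.05
      }
      # pin the inactivation so the curve crosses zero where the data do
      beyond <- data$temperature_C[data$temperature_C > t_peak &
                                     data$rate <= 0.05 * rmax_obs]
      t_zero <- if (length(beyond)) min(beyond) else max(data$temperature_C) + 2
      g <- expand.grid(a = a0, b = c(b0, 0.5 * b0, 1.5 * b0),
                       c = 0, d = NA_real_,
                       e_coef = c(0.2, 0.4, 0.7, 1.0))
      g$d <- pmax((g$a * exp(g$b * t_zero) - g$c) / exp(g$e_coef * t_zero),
                  1e-8)
      rbind(g, expand.grid(a = max(r_cold, 1e-3), b = c(0.02, 0.1),
                           c = 0, d = c(0.1, 1), e_coef = c(0.1, 0.3)))
    },
    weibull = expand.grid(
      a = rmax_obs,
      topt = temps,
      b = c(5, 10, 20),
      c = c(1.5, 2.5, 4)))
}

# transform a start row (named list) to the unconstrained scale
tpc_to_unconstrained <- function(model, p) {
  switch(model,
    pawar = list(lr = log(p$r_tref), le = log(p$e),
                 phi = log(max(p$eh - p$e, 1e-3)), topt = p$topt),
    thomas2 = list(la = log(p$a), b = p$b, c = p$c,
                   ld = log(max(p$d, 1e-6)),
                   lec = log(max(p$e_coef, 1e-6))),
    weibull = list(la = log(p$a), topt = p$topt, lb = log(p$b),
                   lc = log(max(p$c - 1, 1e-3))))
}

tpc_from_unconstrained <- function(model, q) {
  switch(model,
    pawar = list(r_tref = exp(q$lr), e = exp(q$le),
                 eh = exp(q$le) + exp(q$phi), topt = q$topt, tref = 1),
    thomas2 = list(a = exp(q$la), b = q$b, c = q$c, d = exp(q$ld),
                   e_coef = exp(q$lec)),
    weibull = list(a = exp(q$la), topt = q$topt, b = exp(q$lb),
                   c = 1 + exp(q$lc)))
}

tpc_formula <- function(model) {
  switch(model,
    pawar = rate ~ pawar_rate(temperature_C, exp(lr), exp(le),
                              exp(le) + exp(phi), topt),
    thomas2 = rate ~ thomas2_rate(temperature_C, exp(la), b, c, exp(ld),
                                  exp(lec)),
    weibull = rate ~ weibull_rate(temperature_C, exp(la), topt, exp(lb),
                                  1 + exp(lc)))
}

# One weighted Levenberg-Marquardt fit from a given unconstrained start.
# Returns NULL on failure.
tpc_fit_once <- function(model, data, w, start) {
  # do.call so `data`/`weights` enter the call as values: nls resolves the
  # weights symbol in the formula environment, not in this frame
  fit <- tryCatch(
    suppressWarnings(do.call(minpack.lm::nlsLM, list(
      tpc_formula(model), data = data, start = start, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  q <- as.list(coef(fit))
  params <- tpc_from_unconstrained(model, q)
  pred <- tpc_rate(model, data$temperature_C, params)
  if (any(!is.finite(pred))) return(NULL)
  wrss <- sum(w * (data$rate - pred)^2)
  list(params = params, q = q, wrss = wrss, fitted = pred)
}

# Numeric Jacobian of the model surface wrt the unconstrained parameters,
# and leverage diagonal of the weighted linearised hat matrix. Residual
# resampling uses leverage-corrected residuals r / sqrt(1 - h) (the
# standard small-sample correction for residual bootstraps): nonlinear TPC
# fits on few points absorb a large share of the noise into the fit, and
# uncorrected residuals understate it badly.
tpc_hat_diag <- function(model, data, q, w) {
  qv <- unlist(q)
  f0 <- tpc_rate(model, data$temperature_C,
                 tpc_from_unconstrained(model, as.list(qv)))
  J <- matrix(0, nrow(data), length(qv))
  for (j in seq_along(qv)) {
    qq <- qv
    h <- 1e-6
    qq[j] <- qv[j] + h
    fj <- tpc_rate(model, data$temperature_C,
                   tpc_from_unconstrained(model, as.list(qq)))
    J[, j] <- (fj - f0) / h
  }
  Jw <- J * sqrt(w)
  if (any(!is.finite(Jw))) return(rep(0, nrow(data)))
  qr1 <- qr(Jw)
  if (qr1$rank == 0) return(rep(0, nrow(data)))
  Q <- qr.Q(qr1)[, seq_len(qr1$rank), drop = FALSE]
  pmin(rowSums(Q^2), 0.99)
}

#' Fit a thermal performance curve by weighted nonlinear regression
#'
#' Fits the chosen model to per-temperature rate summaries by weighted
#' least squares (weights 1/sd by default, matching rates measured with
#' heteroscedastic replicate error), using Levenberg-Marquardt iterations
#' from a deterministic multi-start grid; the best start by weighted SSE
#' wins. Confidence intervals for the optimum temperature `T_opt` and the
#' peak rate `R_max` come from a residual-resampling bootstrap: weighted
#' residuals (residual x sqrt(weight), leverage-corrected by
#' 1/sqrt(1 - h_ii) from the linearised hat matrix, since nonlinear fits on
#' few points absorb part of the noise) are resampled with replacement,
#' added back onto the fitted values, and the model is refit on each of
#' `n_boot` resampled datasets; 95% percentile intervals are reported.
#'
#' When per-replicate measurements are available, fit them directly (one
#' row per replicate) rather than collapsing to per-temperature means: a
#' residual pool of n_temperatures points is largely absorbed by a 4-5
#' parameter curve, leaving the bootstrap too little noise to propagate.
#'
#' @param data data.frame with columns `temperature_C`, `rate` and,
#'   when weighting, `sd` (> 0); an `n` column is carried but unused.
#' @param model `"pawar"`, `"thomas2"` or `"weibull"`.
#' @param weights `"inv_sd"` (1/sd, default), `"inv_var"` (1/sd^2) or
#'   `"none"`.
#' @param n_boot bootstrap replicates (default 1000); 0 gives point
#'   estimates only with `NA` intervals.
#' @param seed integer seed for the bootstrap.
#' @param resample `"global"` resamples weighted residuals across all
#'   temperatures (default); `"within_temperature"` resamples within each
#'   temperature's own residual pool (only meaningful with replicated
#'   temperatures).
#' @param n_starts number of grid starts refined by Levenberg-Marquardt
#'   (ranked by weighted SSE at the start values).
#' @return object of class `tpc_fit`: list with `model`, `params`,
#'   `topt_C`, `rmax`, `ci_topt`, `ci_rmax`, `aic`, `wrss`, `n_boot`,
#'   `n_boot_converged`, `converged`, `seed`, `data`, `weights_kind`,
#'   `boot` (data.frame of bootstrap topt/rmax).
#' @examples
#' d <- data.frame(temperature_C = c(0, 2.5, 5, 10, 15, 20, 25, 30))
#' d$rate <- thomas2_rate(d$temperature_C, 40, 0.08, 5, 1, 0.3, floor0 = TRUE)
#' d$sd <- pmax(0.05 * d$rate, 0.5)
#' fit <- fit_tpc(d, "thomas2", n_boot = 0)
#' fit$topt_C
#' @export
fit_tpc <- function(data, model = c("pawar", "thomas2", "weibull"),
                    weights = c("inv_sd", "inv_var", "none"), n_boot = 1000,
                    seed = NULL, resample = c("global", "within_temperature"),
                    n_starts = 5) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  resample <- match.arg(resample)
  data <- as.data.frame(data)
  stopifnot(all(c("temperature_C", "rate") %in% names(data)))
  n_temps <- length(unique(data$temperature_C))
  if (n_temps < tpc_n_params[[model]]) {
    stop(sprintf("%s needs >= %d distinct temperatures, got %d", model,
                 tpc_n_params[[model]], n_temps))
  }
  if (all(data$rate == 0)) stop("all rates are zero; nothing to fit")
  if (weights != "none" &&
      (!"sd" %in% names(data) || any(!is.finite(data$sd)) ||
       any(data$sd <= 0))) {
    stop(weights, " weighting needs a positive 'sd' column")
  }
  w <- switch(weights,
    inv_sd = 1 / data$sd,
    inv_var = 1 / data$sd^2,
    none = rep(1, nrow(data)))

  # rank the deterministic start grid by weighted SSE, refine the best few
  grid <- tpc_start_grid(model, data)
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    p <- as.list(grid[i, , drop = FALSE])
    pred <- tpc_rate(model, data$temperature_C, p)
    if (any(!is.finite(pred))) return(Inf)
    sum(w * (data$rate - pred)^2)
  }, numeric(1))
  ord <- order(sse)[seq_len(min(n_starts, nrow(grid)))]
  best <- NULL
  for (i in ord) {
    st <- tpc_to_unconstrained(model, as.list(grid[i, , drop = FALSE]))
    cand <- tpc_fit_once(model, data, w, st)
    if (!is.null(cand) && (is.null(best) || cand$wrss < best$wrss)) {
      best <- cand
    }
  }
  if (is.null(best)) stop("all starts failed to converge for model ", model)

  trange <- range(data$temperature_C)
  pk <- derive_topt_rmax(model, best$params, trange)
  n <- nrow(data)
  k <- tpc_n_params[[model]] + 1
  aic <- n * log(best$wrss / n) + 2 * k

  boot <- data.frame(topt_C = numeric(0), rmax = numeric(0))
  n_conv <- 0L
  if (n_boot > 0) {
    resid_raw <- data$rate - best$fitted
    hii <- tpc_hat_diag(model, data, best$q, w)
    wres <- resid_raw * sqrt(w) / sqrt(1 - hii)
    temp_groups <- match(data$temperature_C, unique(data$temperature_C))
    boot_list <- with_seed(seed, {
      lapply(seq_len(n_boot), function(b) {
        if (resample == "global") {
          idx <- sample.int(n, n, replace = TRUE)
        } else {
          idx <- seq_len(n)
          for (g in unique(temp_groups)) {
            gi <- which(temp_groups == g)
            idx[gi] <- if (length(gi) == 1) gi else sample(gi, length(gi),
                                                          replace = TRUE)
          }
        }
        d2 <- data
        d2$rate <- best$fitted + wres[idx] / sqrt(w)
        refit <- tpc_fit_once(model, d2, w, best$q)
        if (is.null(refit)) return(NULL)
        pk_b <- derive_topt_rmax(model, refit$params, trange)
        c(pk_b$topt_C, pk_b$rmax)
      })
    })
    ok <- !vapply(boot_list, is.null, logical(1))
    n_conv <- sum(ok)
    if (n_conv > 0) {
      m <- do.call(rbind, boot_list[ok])
      boot <- data.frame(topt_C = m[, 1], rmax = m[, 2])
    }
  }
  ci_topt <- ci_rmax <- c(NA_real_, NA_real_)
  if (nrow(boot) > 0) {
    ci_topt <- unname(quantile(boot$topt_C, c(0.025, 0.975)))
    ci_rmax <- unname(quantile(boot$rmax, c(0.025, 0.975)))
  }
  converged <- if (n_boot > 0) n_conv >= n_boot / 2 else TRUE

  structure(list(
    model = model, params = best$params, topt_C = pk$topt_C, rmax = pk$rmax,
    ci_topt = ci_topt, ci_rmax = ci_rmax, aic = aic, wrss = best$wrss,
    n_boot = n_boot, n_boot_converged = n_conv, converged = converged,
    seed = seed, data = data, weights_kind = weights, boot = boot
  ), class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("Thermal performance curve fit (%s)\n", x$model))
  cat(sprintf("  T_opt = %.2f C [%.2f, %.2f]\n", x$topt_C,
              x$ci_topt[1], x$ci_topt[2]))
  cat(sprintf("  R_max = %.2f [%.2f, %.2f]\n", x$rmax,
              x$ci_rmax[1], x$ci_rmax[2]))
  cat(sprintf("  AIC = %.2f, weighted RSS = %.4g, bootstrap %d/%d converged\n",
              x$aic, x$wrss, x$n_boot_converged, x$n_boot))
  invisible(x)
}

#' Predict a fitted curve on a temperature grid
#'
#' @param object a `tpc_fit`.
#' @param temps temperature grid (deg C); defaults to the observed range at
#'   0.1 deg C steps.
#' @param ... unused.
#' @return data.frame with `temperature_C` and `rate`.
#' @export
predict.tpc_fit <- function(object, temps = NULL, ...) {
  temps <- temps %||% seq(min(object$data$temperature_C),
                          max(object$data$temperature_C), by = 0.1)
  data.frame(temperature_C = temps,
             rate = tpc_rate(object$model, temps, object$params))
}

#' Select among fitted TPC models by AIC
#'
#' AIC is computed from the weighted residual sum of squares with
#' `k = n_params + 1` (the +1 for the error variance); the lowest AIC wins,
#' with ties broken in favour of fewer parameters. All fits must be to the
#' same data with the same weighting for the comparison to be meaningful.
#'
#' @param fits list of `tpc_fit` objects.
#' @return the selected `tpc_fit`, with attribute `aic_table`.
#' @export
model_select_aic <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "tpc_fit")))
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    n_params = vapply(fits, function(f) tpc_n_params[[f$model]], integer(1)),
    aic = vapply(fits, `[[`, numeric(1), "aic"))
  best <- fits[[order(tab$aic, tab$n_params)[1]]]
  attr(best, "aic_table") <- tab[order(tab$aic, tab$n_params), ]
  best
}

#' Write a TPC fit as JSON plus a predicted-curve CSV
#'
#' @param fit a `tpc_fit`.
#' @param json_path,curve_path output paths (`NULL` skips either).
#' @export
write_tpc_fit <- function(fit, json_path = NULL, curve_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      model = fit$model, params = fit$params, topt_C = fit$topt_C,
      rmax = fit$rmax, ci_topt = fit$ci_topt, ci_rmax = fit$ci_rmax,
      aic = fit$aic, n_boot = fit$n_boot,
      n_boot_converged = fit$n_boot_converged, converged = fit$converged,
      seed = fit$seed
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(curve_path)) {
    write.csv(predict(fit), curve_path, row.names = FALSE)
  }
  invisible(fit)
}
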