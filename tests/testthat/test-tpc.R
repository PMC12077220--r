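# Frozen generating parameters used across the TPC tests: a cryophilic-like
# curve for each model family (optimum below ~11 C, collapse by 20-30 C).
TP_PAWAR <- list(r_tref = 30, e = 0.6, eh = 4, topt = 8, tref = 1)
TP_THOMAS2 <- list(a = 40, b = 0.08, c = 5, d = 1, e_coef = 0.3)
TP_WEIBULL <- list(a = 50, topt = 12, b = 15, c = 3)
DESIGN_TEMPS <- c(0, 2.5, 5, 10, 15, 20, 25, 30)

test_that("pawar rate matches an independent transcription of the formula", {
  # independent re-implementation, written directly from the equation
  oracle <- function(temp, r_tref, e, eh, topt, tref = 1) {
    k <- 8.62e-5
    arrh <- r_tref * exp(-(e / k) * (1 / (temp + 273.15) -
                                     1 / (tref + 273.15)))
    inact <- 1 + (e / (eh - e)) *
      exp((eh / k) * (1 / (topt + 273.15) - 1 / (temp + 273.15)))
    arrh / inact
  }
  for (temp in c(-2, 0, 1, 5, 8, 12, 20, 30)) {
    expect_equal(pawar_rate(temp, 30, 0.6, 4, 8),
                 oracle(temp, 30, 0.6, 4, 8), tolerance = 1e-10)
  }
  # temp = tref: numerator reduces to r_tref
  expect_equal(pawar_rate(1, 30, 0.6, 4, 8),
               30 / (1 + (0.6 / 3.4) * exp(4 / 8.62e-5 *
                 (1 / (8 + 273.15) - 1 / (1 + 273.15)))), tolerance = 1e-10)
  # eh very large below the optimum: pure Arrhenius limit
  expect_equal(pawar_rate(5, 30, 0.6, 1e4, 8),
               30 * exp(-(0.6 / 8.62e-5) * (1 / (5 + 273.15) -
                                            1 / (1 + 273.15))),
               tolerance = 1e-8)
})

test_that("thomas2 rate reduces to its limiting forms", {
  # no inactivation: pure exponential rise, value a at 0 C
  expect_equal(thomas2_rate(0, 40, 0.08, 0, 0, 0.3), 40)
  temps <- seq(0, 30, by = 2.5)
  r <- thomas2_rate(temps, 40, 0.08, 0, 0, 0.3)
  expect_true(all(diff(r) > 0)) # monotone, no interior optimum
  # raw value can be negative; floor0 clamps for reporting only
  expect_lt(thomas2_rate(30, 40, 0.08, 5, 1, 0.3), 0)
  expect_equal(thomas2_rate(30, 40, 0.08, 5, 1, 0.3, floor0 = TRUE), 0)
})

test_that("numeric argmax agrees with the calculus stationary point", {
  p <- TP_THOMAS2
  # stationary point of a*b*exp(b*t) = d*e*exp(e*t):
  # t* = log((a*b)/(d*e)) / (e - b)
  t_star <- log((p$a * p$b) / (p$d * p$e_coef)) / (p$e_coef - p$b)
  got <- derive_topt_rmax("thomas2", p, c(0, 30))
  expect_equal(got$topt_C, t_star, tolerance = 0.01)
  expect_equal(got$rmax, thomas2_rate(t_star, p$a, p$b, p$c, p$d, p$e_coef),
               tolerance = 1e-3)
})

test_that("noiseless self-consistent data recover the optimum exactly", {
  for (model in c("pawar", "thomas2", "weibull")) {
    p <- switch(model, pawar = TP_PAWAR, thomas2 = TP_THOMAS2,
                weibull = TP_WEIBULL)
    mu <- tpc_rate(model, DESIGN_TEMPS, p)
    d <- data.frame(temperature_C = DESIGN_TEMPS, rate = mu,
                    sd = pmax(0.05 * abs(mu), 0.3))
    f <- fit_tpc(d, model, n_boot = 0)
    truth <- derive_topt_rmax(model, p, range(DESIGN_TEMPS))
    expect_lt(abs(f$topt_C - truth$topt_C), 0.1)
    expect_equal(f$rmax, truth$rmax, tolerance = 0.01)
  }
})

test_that("n_boot = 0 gives point estimates with empty intervals", {
  d <- gen_tpc_data("pawar", TP_PAWAR, DESIGN_TEMPS, seed = 1)
  f <- fit_tpc(d, "pawar", n_boot = 0)
  expect_true(all(is.na(f$ci_topt)))
  expect_true(all(is.na(f$ci_rmax)))
  expect_equal(nrow(f$boot), 0)
  expect_true(f$converged)
})

test_that("bootstrap is reproducible bit-for-bit under a fixed seed", {
  d <- gen_tpc_data("pawar", TP_PAWAR, DESIGN_TEMPS, seed = 2)
  f1 <- fit_tpc(d, "pawar", n_boot = 50, seed = 99)
  f2 <- fit_tpc(d, "pawar", n_boot = 50, seed = 99)
  expect_identical(f1$boot, f2$boot)
  expect_identical(f1$ci_topt, f2$ci_topt)
})

test_that("bootstrap intervals are ordered and bracket the estimate", {
  d <- gen_tpc_data("thomas2", TP_THOMAS2, DESIGN_TEMPS, seed = 3)
  f <- fit_tpc(d, "thomas2", n_boot = 100, seed = 5)
  expect_lt(f$ci_topt[1], f$ci_topt[2])
  expect_lt(f$ci_rmax[1], f$ci_rmax[2])
  expect_gt(f$n_boot_converged, 50)
  expect_true(f$converged)
})

test_that("fit validation rejects undersized or degenerate datasets", {
  d <- data.frame(temperature_C = c(0, 5, 10), rate = c(1, 2, 1),
                  sd = c(1, 1, 1))
  expect_error(fit_tpc(d, "pawar"), "distinct temperatures")
  d0 <- data.frame(temperature_C = DESIGN_TEMPS, rate = 0,
                   sd = rep(1, 8))
  expect_error(fit_tpc(d0, "pawar"), "zero")
  dna <- data.frame(temperature_C = DESIGN_TEMPS, rate = 1:8, sd = 0)
  expect_error(fit_tpc(dna, "pawar"), "sd")
})

test_that("weighting options change the objective as documented", {
  d <- gen_tpc_data("pawar", TP_PAWAR, DESIGN_TEMPS, seed = 4)
  f_sd <- fit_tpc(d, "pawar", weights = "inv_sd", n_boot = 0)
  f_none <- fit_tpc(d, "pawar", weights = "none", n_boot = 0)
  # both converge; weighted RSS values live on different scales
  expect_true(is.finite(f_sd$wrss) && is.finite(f_none$wrss))
})

test_that("AIC selection prefers the generating model and breaks ties", {
  d <- gen_tpc_data("thomas2", TP_THOMAS2, DESIGN_TEMPS, cv = 0.05,
                    seed = 6)
  fits <- lapply(c("pawar", "thomas2", "weibull"), function(m)
    fit_tpc(d, m, n_boot = 0))
  best <- model_select_aic(fits)
  expect_equal(best$model, "thomas2")
  tab <- attr(best, "aic_table")
  expect_equal(tab$model[1], "thomas2")
  expect_true(all(diff(tab$aic) >= 0))
})

test_that("fitted curves can be predicted and serialised", {
  d <- gen_tpc_data("pawar", TP_PAWAR, DESIGN_TEMPS, seed = 7)
  f <- fit_tpc(d, "pawar", n_boot = 10, seed = 1)
  pr <- predict(f)
  expect_equal(names(pr), c("temperature_C", "rate"))
  expect_true(all(is.finite(pr$rate)))
  jp <- tempfile(fileext = ".json")
  cp <- tempfile(fileext = ".csv")
  write_tpc_fit(f, jp, cp)
  js <- jsonlite::read_json(jp)
  expect_equal(js$model, "pawar")
  expect_equal(js$topt_C, f$topt_C, tolerance = 1e-9)
  expect_equal(nrow(read.csv(cp)), nrow(pr))
})
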