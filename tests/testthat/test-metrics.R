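test_that("straight track metrics match the collinear closed form", {
  tr <- straight_track(speed = 10, duration_s = 10)
  m <- track_metrics(tr)
  expect_equal(m$total_distance_um, 100, tolerance = 1e-9)
  expect_equal(m$max_distance_um, 100, tolerance = 1e-9)
  expect_equal(m$mean_speed_um_s, 10, tolerance = 1e-9)
  expect_equal(m$confinement_ratio, 1, tolerance = 1e-9)
  expect_equal(m$dispersal_um_s, 10, tolerance = 1e-9)
})

test_that("closed circle has confinement ratio 1/pi", {
  # circumference C, max displacement from start = diameter = C/pi
  m <- track_metrics(circle_track(circumference = 100, n = 20000))
  expect_equal(m$total_distance_um, 100, tolerance = 1e-4)
  expect_equal(m$max_distance_um, 100 / pi, tolerance = 1e-4)
  expect_equal(m$confinement_ratio, 1 / pi, tolerance = 1e-4)
})

test_that("metrics equal an independent brute-force recomputation", {
  set.seed(50)
  for (i in 1:50) {
    tr <- rw_track(n = sample(10:80, 1))
    m <- track_metrics(tr)
    bf <- brute_metrics(tr)
    expect_equal(m$total_distance_um, bf$total, tolerance = 1e-9)
    expect_equal(m$max_distance_um, bf$maxd, tolerance = 1e-9)
    expect_equal(m$mean_speed_um_s, bf$speed, tolerance = 1e-9)
    expect_equal(m$confinement_ratio, bf$conf, tolerance = 1e-9)
    expect_equal(m$dispersal_um_s, bf$disp, tolerance = 1e-9)
  }
})

test_that("metrics are invariant under rigid motion", {
  set.seed(51)
  tr <- rw_track(n = 60)
  m0 <- track_metrics(tr)
  th <- 0.83
  tr2 <- tr
  tr2$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um + 500
  tr2$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um - 120
  m1 <- track_metrics(tr2)
  for (col in c("total_distance_um", "max_distance_um", "mean_speed_um_s",
                "confinement_ratio", "dispersal_um_s")) {
    expect_equal(m1[[col]], m0[[col]], tolerance = 1e-9)
  }
})

test_that("confinement ratio never exceeds one", {
  set.seed(52)
  for (i in 1:30) {
    m <- track_metrics(rw_track(n = sample(5:50, 1)))
    expect_lte(m$confinement_ratio, 1 + 1e-12)
    expect_gte(m$confinement_ratio, 0)
  }
})

test_that("any-pair max-distance convention is at least the from-first one", {
  set.seed(53)
  tr <- rw_track(n = 40)
  m_ff <- track_metrics(tr, max_convention = "from_first")
  m_ap <- track_metrics(tr, max_convention = "any_pair")
  expect_gte(m_ap$max_distance_um, m_ff$max_distance_um - 1e-12)
})

test_that("degenerate tracks are rejected", {
  expect_error(track_metrics(data.frame(frame = 0, t_s = 0, x_um = 0,
                                        y_um = 0)), "at least 2")
  expect_error(track_metrics(data.frame(frame = c(0, 0), t_s = c(0, 0),
                                        x_um = c(0, 1), y_um = 0)),
               "zero elapsed time")
})

test_that("motile classification is boundary-inclusive and rescales", {
  met <- data.frame(total_distance_um = c(100, 99.9, 150, 0))
  out <- classify_motile(met)
  expect_equal(out$motile, c(TRUE, FALSE, TRUE, FALSE))
  # 5 s recording: same 10 um/s speed equivalence -> 50 um threshold
  out5 <- classify_motile(data.frame(total_distance_um = c(49, 51)),
                          recording_duration_s = 5)
  expect_equal(out5$motile, c(FALSE, TRUE))
})

test_that("deciliated control populations classify as fully non-motile", {
  cfg <- sim_config(n_motile = 0, n_drifting = 15, n_stationary = 15,
                    drift_velocity_um_s = c(3, 0), brownian_sd_um = 0.1,
                    seed = 54)
  sim <- simulate_deciliated_control(cfg)
  met <- classify_motile(tracks_metrics(
    transform(sim$spots, track_id = cell_id)))
  # drift of 3 um/s covers ~30 um in 10 s, far below the 100 um threshold
  expect_equal(sum(met$motile), 0)
  summ <- population_summary(met, "control", 5, 1)
  expect_equal(summ$motile_fraction, 0)
  expect_true(is.na(summ$motile_mean_speed_um_s))
})

test_that("threshold calibration methods behave as documented", {
  set.seed(55)
  control <- data.frame(total_distance_um = rlnorm(100, log(20), 0.4))
  expect_equal(calibrate_threshold(control, "fixed", quiet = TRUE), 100)
  q <- calibrate_threshold(control, "quantile", quiet = TRUE)
  expect_equal(q, unname(quantile(control$total_distance_um, 0.99)))
  expect_error(calibrate_threshold(control[1:10, , drop = FALSE], "valley",
                                   quiet = TRUE), "quantile")
  # bimodal mixture: valley lands between the passive and active modes
  mixed <- data.frame(total_distance_um = c(rlnorm(150, log(20), 0.3),
                                            rlnorm(150, log(400), 0.3)))
  v <- calibrate_threshold(mixed, "valley", quiet = TRUE)
  expect_gt(v, 40)
  expect_lt(v, 250)
})

test_that("population summary separates motile-only statistics", {
  met <- data.frame(
    mean_speed_um_s = c(40, 60, 1, 2),
    dispersal_um_s = c(30, 50, 0.5, 0.4),
    total_distance_um = c(400, 600, 10, 20))
  met <- classify_motile(met)
  s <- population_summary(met, "sp", 5, 1)
  expect_equal(s$n_tracks, 4)
  expect_equal(s$motile_fraction, 0.5)
  expect_equal(s$motile_mean_speed_um_s, 50)
  expect_equal(s$motile_mean_dispersal_um_s, 40)
  expect_error(population_summary(met[, -ncol(met)]), "classify_motile")
})

test_that("dispersal unit conversion matches the exact factor", {
  expect_equal(dispersal_to_m_per_day(15), 1.296, tolerance = 1e-12)
  expect_equal(dispersal_to_m_per_day(15, truncate = TRUE), 1.29)
  expect_equal(dispersal_to_m_per_day(0), 0)
  # inverse of the conversion factor: 1 m/day
  expect_equal(dispersal_to_m_per_day(1 / 0.0864), 1, tolerance = 1e-9)
})

test_that("motile fraction recovery through the full metric chain", {
  p <- list(r_tref = 30, e = 0.6, eh = 4, topt = 8, tref = 1)
  for (f in c(0.3, 0.7)) {
    sim <- simulate_population(p, "pawar", temperature = 8, n_cells = 120,
                               motile_fraction = f, noise_cv = 0.1,
                               seed = round(1000 * f),
                               config = sim_config(arena_width_um = 4000,
                                                   arena_height_um = 4000,
                                                   brownian_sd_um = 0.1))
    met <- classify_motile(tracks_metrics(
      transform(sim$spots, track_id = cell_id)))
    f_hat <- mean(met$motile)
    expect_lt(abs(f_hat - f), 3 * sqrt(f * (1 - f) / 120))
  }
})
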