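test_that("DoG detector localises isolated blobs to sub-pixel accuracy", {
  sp <- data.frame(frame = 0L, x_um = c(30.3, 70.7), y_um = c(40.5, 42.2))
  fr <- render_frames(sp, psf_sigma_px = 2.5, width_px = 100,
                      height_px = 80, noise_sd = 1, seed = 1)
  det <- detect_spots_dog(fr, diameter_px = 10, quality_threshold = 1)
  expect_equal(nrow(det), 2)
  det <- det[order(det$x_um), ]
  expect_lt(abs(det$x_um[1] - 30.3), 0.5)
  expect_lt(abs(det$y_um[1] - 40.5), 0.5)
  expect_lt(abs(det$x_um[2] - 70.7), 0.5)
  expect_lt(abs(det$y_um[2] - 42.2), 0.5)
  expect_true(all(det$quality > 1))
})

test_that("DoG detector returns no spots on blank frames", {
  blank <- list(matrix(100, 60, 60), matrix(100, 60, 60))
  det <- detect_spots_dog(blank, diameter_px = 10, quality_threshold = 0.5)
  expect_equal(nrow(det), 0)
  expect_error(detect_spots_dog(list(), 10), "empty")
  expect_error(detect_spots_dog(blank, -1), "positive")
})

test_that("two blobs separated by 3x diameter give exactly two spots", {
  sp <- data.frame(frame = 0L, x_um = c(40, 70), y_um = c(40, 40))
  fr <- render_frames(sp, psf_sigma_px = 2.5, width_px = 110,
                      height_px = 80, noise_sd = 0.5, seed = 2)
  det <- detect_spots_dog(fr, diameter_px = 10, quality_threshold = 1)
  expect_equal(nrow(det), 2)
})

test_that("a short dropout gap within limits is closed into one track", {
  # one cell moving +4 um/frame; 5-frame detection gap, 20 um jump
  fr_all <- 0:100
  keep <- !(fr_all %in% 41:45)
  sp <- data.frame(frame = fr_all[keep], t_s = fr_all[keep] / 30,
                   x_um = 4 * fr_all[keep], y_um = 0)
  tr <- link_tracks(sp, link_config(pixel_size_um = 1))
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), sum(keep))
})

test_that("a gap longer than the frame limit splits the track", {
  fr_all <- 0:100
  keep <- !(fr_all %in% 31:70) # 40 missing frames > 30-frame gap limit
  sp <- data.frame(frame = fr_all[keep], t_s = fr_all[keep] / 30,
                   x_um = 0.5 * fr_all[keep], y_um = 0)
  tr <- link_tracks(sp, link_config())
  expect_equal(length(unique(tr$track_id)), 2)
})

test_that("parallel tracks beyond twice the link radius never switch", {
  fr <- 0:150
  sp <- rbind(
    data.frame(cell = 1, frame = fr, x_um = 2 * fr, y_um = 0),
    data.frame(cell = 2, frame = fr, x_um = 2 * fr, y_um = 70))
  sp$t_s <- sp$frame / 30
  tr <- link_tracks(sp, link_config(link_max_dist_px = 30))
  tab <- table(tr$track_id, tr$cell)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_true(all(rowSums(tab > 0) == 1)) # no identity switches
})

test_that("simulated mixed population is recovered exactly when separable", {
  cfg <- sim_config(n_motile = 10, n_drifting = 4, n_stationary = 4,
                    speed_mean_um_s = 45, speed_sd_um_s = 8,
                    turn_rate_sd_rad_s = 1.2, loop_bias_rad_s = 0.8,
                    brownian_sd_um = 0.3, drift_velocity_um_s = c(2, 1),
                    detection_dropout_p = 0.03,
                    arena_width_um = 3000, arena_height_um = 3000, seed = 21)
  sim <- simulate_tracks(cfg)
  tr <- link_tracks(sim$spots, link_config())
  tab <- table(tr$track_id, tr$cell_id)
  expect_equal(length(unique(tr$track_id)), nrow(sim$truth))
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  expect_equal(nrow(tr), nrow(sim$spots)) # every spot used exactly once
})

test_that("track frame sequences are strictly increasing", {
  cfg <- sim_config(n_motile = 6, detection_dropout_p = 0.1,
                    speed_mean_um_s = 40, turn_rate_sd_rad_s = 1,
                    arena_width_um = 2000, arena_height_um = 2000, seed = 22)
  sim <- simulate_tracks(cfg)
  tr <- link_tracks(sim$spots, link_config())
  for (d in split(tr, tr$track_id)) {
    expect_true(all(diff(d$frame) >= 1))
    expect_true(all(diff(d$frame) <= 30)) # never bridges beyond the limit
  }
})

test_that("duration filter keeps 75-frame tracks and drops 74-frame ones", {
  mk <- function(id, nspan) data.frame(track_id = id,
                                       frame = seq_len(nspan) - 1,
                                       x_um = 0, y_um = 0)
  tracks <- rbind(mk(1, 74), mk(2, 75), mk(3, 76))
  out <- filter_tracks(tracks, 75, quiet = TRUE)
  expect_setequal(unique(out$track_id), c(2, 3))
  expect_equal(attr(out, "n_removed"), 1L)
  empty <- filter_tracks(tracks[0, ], 75)
  expect_equal(nrow(empty), 0)
})

test_that("duration filter agrees with a brute-force scan on random tracks", {
  set.seed(30)
  tracks <- do.call(rbind, lapply(1:100, function(id) {
    n <- sample(2:120, 1)
    f0 <- sample(0:50, 1)
    data.frame(track_id = id, frame = f0:(f0 + n - 1), x_um = 0, y_um = 0)
  }))
  out <- filter_tracks(tracks, 75, quiet = TRUE)
  keep_bf <- c()
  for (id in 1:100) {
    f <- tracks$frame[tracks$track_id == id]
    if (max(f) - min(f) + 1 >= 75) keep_bf <- c(keep_bf, id)
  }
  expect_setequal(unique(out$track_id), keep_bf)
})

test_that("TrackMate exports parse with decoration rows and unit override", {
  path <- system.file("extdata", "synthetic_trackmate_spots.csv",
                      package = "snowmotility")
  tr <- read_trackmate_export(path)
  expect_equal(nrow(tr), 8)
  expect_equal(sort(unique(tr$track_id)), c(0, 1))
  expect_equal(tr$x_um[tr$track_id == 0][1], 10)
  tr2 <- read_trackmate_export(path, unit_to_um = 2)
  expect_equal(tr2$x_um, tr$x_um * 2)
})

test_that("missing mandatory columns are reported by name", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(FRAME = 0, POSITION_X = 1, POSITION_Y = 2,
                       POSITION_T = 0), tmp, row.names = FALSE)
  expect_error(read_trackmate_export(tmp), "TRACK_ID")
})

test_that("spot tables round-trip through the CSV dialect", {
  cfg <- sim_config(n_motile = 3, speed_mean_um_s = 30, seed = 31,
                    arena_width_um = 1000, arena_height_um = 1000)
  sim <- simulate_tracks(cfg)
  tr <- link_tracks(sim$spots, link_config())
  tmp <- tempfile(fileext = ".csv")
  write_spots_csv(tr, tmp)
  back <- read_trackmate_export(tmp)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(sort(back$x_um), sort(tr$x_um), tolerance = 1e-9)
})

test_that("image stacks round-trip through 16-bit TIFF", {
  sp <- data.frame(frame = c(0L, 1L), x_um = c(10, 12), y_um = c(15, 15))
  fr <- render_frames(sp, psf_sigma_px = 2, width_px = 30, height_px = 30,
                      noise_sd = 0, seed = 1)
  tmp <- tempfile(fileext = ".tif")
  write_frames_tiff(fr, tmp)
  back <- read_frames_tiff(tmp)
  expect_length(back, 2)
  # same argmax after intensity rescaling
  expect_equal(which.max(back[[1]]), which.max(fr[[1]]))
})

test_that("column-threshold spot filters subset correctly", {
  sp <- data.frame(frame = 0:4, x_um = 0, y_um = 0, quality = 1:5)
  expect_equal(nrow(filter_spots(sp, "quality", min = 3)), 3)
  expect_equal(nrow(filter_spots(sp, "quality", min = 2, max = 4)), 3)
  expect_error(filter_spots(sp, "snr"), "no such column")
})
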