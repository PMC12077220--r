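#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study datasets.
#
# Emulates the study conditions: 10 s recordings at 30 frames/s in a shallow
# chamber; a mixed population of active swimmers (looping paths), passive
# drifters and stationary cells; and a deciliated control population used
# later to calibrate the motile/non-motile distance threshold. Spot tables
# are written in the TrackMate spots-CSV dialect.

suppressPackageStartupMessages(library(snowmotility))
dir.create("results", showWarnings = FALSE)
SEED <- 20260901

# mixed population: 60 swimmers around 45 um/s with loop bias, plus passive
# cells; 0.1 um/frame localisation jitter; 3% detection dropout
cfg <- sim_config(
  arena_width_um = 3500, arena_height_um = 3500,
  n_motile = 60, n_drifting = 20, n_stationary = 20,
  speed_mean_um_s = 45, speed_sd_um_s = 12,
  turn_rate_sd_rad_s = 1.2, loop_bias_rad_s = 0.8,
  drift_velocity_um_s = c(2, 1), brownian_sd_um = 0.1,
  detection_dropout_p = 0.03, seed = SEED)
sim <- simulate_tracks(cfg)
write_spots_csv(sim$spots, "results/spots_mixed.csv")
write.csv(sim$truth, "results/truth_mixed.csv", row.names = FALSE)

# deciliated control: drifting + stationary only
ctrl_cfg <- sim_config(
  arena_width_um = 3500, arena_height_um = 3500,
  n_motile = 0, n_drifting = 50, n_stationary = 50,
  drift_velocity_um_s = c(3, 0), brownian_sd_um = 0.1,
  seed = SEED + 1)
ctrl <- simulate_deciliated_control(ctrl_cfg)
write_spots_csv(ctrl$spots, "results/spots_deciliated.csv")

# a short rendered clip to exercise detection in step 2
clip <- sim$spots[sim$spots$frame < 5 & sim$spots$x_um < 500 &
                    sim$spots$y_um < 500, ]
frames <- render_frames(clip, pixel_size_um = 1, width_px = 520,
                        height_px = 520, psf_sigma_px = 2.5,
                        noise_sd = 2, n_frames = 5, seed = SEED + 2)
write_frames_tiff(frames, "results/clip.tif")

cat(sprintf("mixed population: %d cells, %d spots (dropout removed %.1f%%)\n",
            nrow(sim$truth), nrow(sim$spots),
            100 * (1 - nrow(sim$spots) / (nrow(sim$truth) * 301))))
cat(sprintf("deciliated control: %d cells, %d spots\n",
            nrow(ctrl$truth), nrow(ctrl$spots)))
cat(sprintf("rendered clip: %d frames, %d spots\n", length(frames),
            nrow(clip)))
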