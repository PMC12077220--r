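#!/usr/bin/env Rscript
# Step 2 — detect and link.
#
# Runs the DoG detector over the rendered clip (sanity check against the
# simulated positions), then links the full mixed-population spot table
# with the LAP tracker (30 px frame-to-frame, 50 px / 30 frame gap
# closing) and removes tracks shorter than 75 frames.

suppressPackageStartupMessages(library(snowmotility))

frames <- read_frames_tiff("results/clip.tif")
det <- detect_spots_dog(frames, diameter_px = 10, quality_threshold = 0.02)
cat(sprintf("detector: %d spots over %d frames\n", nrow(det), length(frames)))

spots <- read_trackmate_export("results/spots_mixed.csv")
spots$frame <- as.integer(spots$frame)
spots$track_id <- NULL
cfg <- link_config(link_max_dist_px = 30, gap_max_dist_px = 50,
                   gap_max_frames = 30, min_track_frames = 75,
                   pixel_size_um = 1)
tracks <- link_tracks(spots, cfg)
n_before <- length(unique(tracks$track_id))
tracks <- filter_tracks(tracks, cfg$min_track_frames)
cat(sprintf("linked %d tracks; %d survive the 75-frame filter\n",
            n_before, length(unique(tracks$track_id))))
write_spots_csv(tracks, "results/tracks_mixed.csv")

ctrl <- read_trackmate_export("results/spots_deciliated.csv")
ctrl$track_id <- NULL
ctrl_tracks <- filter_tracks(link_tracks(ctrl, cfg), cfg$min_track_frames)
write_spots_csv(ctrl_tracks, "results/tracks_deciliated.csv")
cat(sprintf("deciliated control: %d tracks\n",
            length(unique(ctrl_tracks$track_id))))
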