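# snowmotility

Analysis chain for temperature-dependent motility of ciliated microalgae
(snow algae and similar microswimmers), for researchers quantifying how
swimming behaviour responds to temperature and light. The package covers
the full path from raw detections to population-level thermal traits:

* **Simulation** of microswimmer recordings (10 s, 30 frames/s): mixed
  populations of active swimmers with looping paths, passive drifters and
  stationary cells; deciliated control populations; per-temperature
  populations drawn from a known thermal performance curve; phototaxis
  dish image pairs with a tunable light bias.
* **Tracking**: difference-of-Gaussians spot detection with sub-pixel
  refinement, and a two-stage LAP (linear assignment problem) tracker —
  frame-to-frame linking (30 px) plus track-segment gap closing
  (50 px / 30 frames) — with a 75-frame duration filter, solved exactly by
  a compiled shortest-augmenting-path solver. TrackMate-style spot CSV
  exports are read and written directly.
* **Motility metrics**: per-track total and maximum distance, path speed,
  confinement ratio (max/total distance), and dispersal
  (speed × confinement, convertible to m/day); motile/non-motile
  classification at 100 µm total distance per 10 s (≡ 10 µm/s), with
  threshold calibration from deciliated controls.
* **Thermal performance curves**: weighted nonlinear fits of the
  Pawar/Sharpe–Schoolfield, Thomas2 and Weibull models,

      rate(T) = r_tref · exp(−e/k · (1/(T+273.15) − 1/(t_ref+273.15)))
                / (1 + e/(e_h − e) · exp(e_h/k · (1/(T_opt+273.15) − 1/(T+273.15))))
      rate(T) = a·exp(b·T) − (c + d·exp(e·T))

  with T_opt and R_max plus 95% CIs from a leverage-corrected
  residual-resampling bootstrap, and AIC model selection.
* **Phototaxis**: dish index = front-half share of background-subtracted
  cell signal (0.5 = no light-directed migration), one-sample t-tests
  against 0.5 with Holm adjustment across a species battery.
* **Reporting**: OLS trait correlations with exact slope inference,
  slope-vs-1 comparison of swimming vs photosynthetic optima, stability
  checks of control recordings, and an end-to-end
  simulate→track→classify→fit pipeline.

## Worked example

Simulate a replicate population at 8 °C from a cryophilic thermal
performance curve, classify motility, and summarise:

```r
library(snowmotility)

p <- list(r_tref = 30, e = 0.6, eh = 4, topt = 8, tref = 1)
sim <- simulate_population(p, "pawar", temperature = 8, n_cells = 100,
                           motile_fraction = 0.6, noise_cv = 0.1, seed = 8,
                           config = sim_config(arena_width_um = 3000,
                                               arena_height_um = 3000,
                                               brownian_sd_um = 0.1))
tracks <- filter_tracks(link_tracks(sim$spots, link_config()), 75)
met <- classify_motile(tracks_metrics(tracks, fps = 30))
population_summary(met, species = "demo", temperature_C = 8, replicate = 1)
```

```
  species temperature_C replicate n_tracks n_motile motile_fraction
1    demo             8         1      100       65            0.65
  motile_mean_speed_um_s motile_speed_sd motile_mean_dispersal_um_s
1               47.53268        4.769105                   42.59473
  motile_dispersal_sd
1            9.757755
```

65 of 100 tracked cells exceed the 100 µm threshold (the generator drew
65 motile cells at this seed); their mean path speed of ~47.5 µm/s
matches the curve's rate at 8 °C (~48 µm/s), and the mean dispersal of
~42.6 µm/s corresponds to `dispersal_to_m_per_day(42.6, truncate = TRUE)`
= 3.68 m/day of effective net displacement.

The numbered scripts in `analysis/` run the whole study chain
(`01_simulate.R` … `06_report.R`), each printing what it found and
writing its tables under `results/`; run them in order from the
repository root.

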