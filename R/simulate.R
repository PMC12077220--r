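#' Simulation settings for a synthetic microswimmer recording
#'
#' Bundles the geometry, acquisition and population parameters used by
#' [simulate_tracks()]. Defaults emulate a 10 s recording at 30 frames/s of a
#' mixed population in a shallow (20 um deep) counting chamber, where motion
#' is effectively confined to the focal plane and is simulated in 2D.
#'
#' Three behavioural categories are supported:
#' \describe{
#'   \item{motile}{constant-speed heading process: per-cell speed drawn from
#'     `N(speed_mean_um_s, speed_sd_um_s)` (clamped at 0), heading subject to
#'     rotational diffusion of strength `turn_rate_sd_rad_s` plus a constant
#'     angular drift `loop_bias_rad_s` that produces the looping/helical
#'     paths typical of biciliate swimmers.}
#'   \item{drifting}{passive advection at `drift_velocity_um_s` plus
#'     per-frame Brownian jitter `brownian_sd_um`.}
#'   \item{stationary}{Brownian jitter only.}
#' }
#'
#' @param arena_width_um,arena_height_um arena size (um). Walls are
#'   reflective.
#' @param duration_s recording duration (s). `fps * duration_s` must be an
#'   integer; positions are emitted at frames `0..fps*duration_s` so a
#'   straight swimmer covers exactly `speed * duration_s` of path.
#' @param fps frame rate (frames per second).
#' @param pixel_size_um physical size of one pixel (um/px), used only when
#'   rendering frames or converting link radii.
#' @param n_motile,n_drifting,n_stationary population counts.
#' @param speed_mean_um_s,speed_sd_um_s motile speed distribution (um/s).
#' @param turn_rate_sd_rad_s rotational diffusion, sd of heading change per
#'   sqrt(second) (rad).
#' @param loop_bias_rad_s constant angular drift (rad/s); non-zero values
#'   yield loops.
#' @param drift_velocity_um_s length-2 numeric, advection of drifters (um/s).
#' @param brownian_sd_um per-frame positional jitter sd (um) for drifting and
#'   stationary cells.
#' @param detection_dropout_p probability in [0, 1) that any individual spot
#'   is missed by detection (i.i.d. per spot).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(arena_width_um = 500, arena_height_um = 500,
                       duration_s = 10, fps = 30, pixel_size_um = 1,
                       n_motile = 0, n_drifting = 0, n_stationary = 0,
                       speed_mean_um_s = 50, speed_sd_um_s = 0,
                       turn_rate_sd_rad_s = 0, loop_bias_rad_s = 0,
                       drift_velocity_um_s = c(0, 0), brownian_sd_um = 0,
                       detection_dropout_p = 0, seed = NULL) {
  nf <- fps * duration_s
  if (abs(nf - round(nf)) > 1e-9) {
    stop("fps * duration_s must be an integer number of frames")
  }
  if (n_motile < 0 || n_drifting < 0 || n_stationary < 0) {
    stop("population counts must be >= 0")
  }
  if (speed_mean_um_s < 0 || speed_sd_um_s < 0) {
    stop("speeds must be non-negative")
  }
  if (detection_dropout_p < 0 || detection_dropout_p >= 1) {
    stop("detection_dropout_p must lie in [0, 1)")
  }
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (length(drift_velocity_um_s) != 2) {
    stop("drift_velocity_um_s must be a length-2 vector")
  }
  structure(list(
    arena_width_um = arena_width_um, arena_height_um = arena_height_um,
    duration_s = duration_s, fps = fps, pixel_size_um = pixel_size_um,
    n_motile = n_motile, n_drifting = n_drifting,
    n_stationary = n_stationary,
    speed_mean_um_s = speed_mean_um_s, speed_sd_um_s = speed_sd_um_s,
    turn_rate_sd_rad_s = turn_rate_sd_rad_s,
    loop_bias_rad_s = loop_bias_rad_s,
    drift_velocity_um_s = drift_velocity_um_s,
    brownian_sd_um = brownian_sd_um,
    detection_dropout_p = detection_dropout_p, seed = seed
  ), class = "sim_config")
}

# reflect coordinates into [0, w] (fold about the walls)
reflect_into <- function(x, w) {
  x <- x %% (2 * w)
  ifelse(x > w, 2 * w - x, x)
}

# Simulate one cell's positions over frames 0..nf. Returns an (nf+1) x 2
# matrix in um. `speed` is the (fixed) path speed for motile cells.
sim_cell_path <- function(category, nf, fps, cfg, speed = 0) {
  w <- cfg$arena_width_um
  h <- cfg$arena_height_um
  pos <- matrix(0, nrow = nf + 1, ncol = 2)
  pos[1, ] <- c(runif(1, 0, w), runif(1, 0, h))
  if (category == "motile") {
    theta <- runif(1, 0, 2 * pi)
    dth_drift <- cfg$loop_bias_rad_s / fps
    dth_sd <- cfg$turn_rate_sd_rad_s / sqrt(fps)
    step <- speed / fps
    turns <- if (dth_sd > 0) rnorm(nf, dth_drift, dth_sd) else rep(dth_drift, nf)
    for (k in seq_len(nf)) {
      theta <- theta + turns[k]
      p <- pos[k, ] + step * c(cos(theta), sin(theta))
      # reflect at walls, flipping the corresponding heading component
      if (p[1] < 0 || p[1] > w) {
        p[1] <- reflect_into(p[1], w)
        theta <- pi - theta
      }
      if (p[2] < 0 || p[2] > h) {
        p[2] <- reflect_into(p[2], h)
        theta <- -theta
      }
      pos[k + 1, ] <- p
    }
  } else {
    drift <- if (category == "drifting") cfg$drift_velocity_um_s / fps else c(0, 0)
    jit <- if (cfg$brownian_sd_um > 0) {
      matrix(rnorm(2 * nf, 0, cfg$brownian_sd_um), ncol = 2)
    } else {
      matrix(0, nrow = nf, ncol = 2)
    }
    steps <- sweep(jit, 2, drift, `+`)
    pos[-1, ] <- sweep(apply(steps, 2, cumsum), 2, pos[1, ], `+`)
    pos[, 1] <- reflect_into(pos[, 1], w)
    pos[, 2] <- reflect_into(pos[, 2], h)
  }
  pos
}

#' Simulate a mixed microswimmer population
#'
#' Generates time-stamped 2D detections ("spots") for a mixed population of
#' active swimmers, passive drifters and stationary cells, together with the
#' per-cell ground truth. The output is the interchange unit consumed by the
#' tracker and the metrics stage, and doubles as a detection table when the
#' `cell_id` column is ignored.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \item{spots}{data.frame with columns `cell_id`, `frame` (0-based),
#'     `t_s`, `x_um`, `y_um`, `quality`, sorted by frame then cell.}
#'   \item{truth}{data.frame with `cell_id`, `category`
#'     (motile/drifting/stationary) and `true_mean_speed_um_s`.}
#' @examples
#' cfg <- sim_config(n_motile = 3, speed_mean_um_s = 40, seed = 1)
#' sim <- simulate_tracks(cfg)
#' head(sim$spots)
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nf <- round(config$fps * config$duration_s)
    cats <- rep(c("motile", "drifting", "stationary"),
                c(config$n_motile, config$n_drifting, config$n_stationary))
    n_cells <- length(cats)
    speeds <- numeric(n_cells)
    if (config$n_motile > 0) {
      speeds[cats == "motile"] <- pmax(
        0, rnorm(config$n_motile, config$speed_mean_um_s, config$speed_sd_um_s))
    }
    spot_list <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      pos <- sim_cell_path(cats[i], nf, config$fps, config, speeds[i])
      keep <- rep(TRUE, nf + 1)
      if (config$detection_dropout_p > 0) {
        keep <- runif(nf + 1) >= config$detection_dropout_p
      }
      frames <- (0:nf)[keep]
      spot_list[[i]] <- data.frame(
        cell_id = i, frame = frames, t_s = frames / config$fps,
        x_um = pos[keep, 1], y_um = pos[keep, 2],
        quality = runif(sum(keep), 5, 15)
      )
    }
    spots <- do.call(rbind, spot_list)
    if (is.null(spots)) {
      spots <- data.frame(cell_id = integer(), frame = integer(),
                          t_s = numeric(), x_um = numeric(),
                          y_um = numeric(), quality = numeric())
    } else {
      spots <- spots[order(spots$frame, spots$cell_id), , drop = FALSE]
      rownames(spots) <- NULL
    }
    truth <- data.frame(cell_id = seq_len(n_cells), category = cats,
                        true_mean_speed_um_s = speeds)
    list(spots = spots, truth = truth)
  })
}

#' Simulate a deciliated control population
#'
#' Emits only drifting and stationary cells, emulating populations whose
#' cilia were removed by pH shock. Used to calibrate the motile/non-motile
#' total-distance threshold: without propulsion, total distance stays far
#' below that of active swimmers.
#'
#' @param config a [sim_config()]; `n_motile` is forced to 0.
#' @return as [simulate_tracks()].
#' @export
simulate_deciliated_control <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$n_motile <- 0
  simulate_tracks(config)
}

#' Simulate one replicate population at a given temperature
#'
#' Draws motile-cell speeds around the thermal-performance-curve rate at
#' `temperature` with coefficient of variation `noise_cv`, simulates the
#' remainder as a mix of stationary and drifting cells, and returns the spot
#' table plus ground truth. At temperatures where the curve is undefined or
#' non-positive, all cells are emitted as non-motile (speed 0), mirroring
#' motility inactivation beyond the thermal limits.
#'
#' @param tpc_params named list of model parameters (see [tpc_rate()]).
#' @param model TPC model name: "pawar", "thomas2" or "weibull".
#' @param temperature incubation temperature (degrees C).
#' @param n_cells total cells in the replicate.
#' @param motile_fraction expected proportion of motile cells in [0, 1]; the
#'   realised count is Binomial(n_cells, motile_fraction).
#' @param noise_cv coefficient of variation of motile speeds around the TPC
#'   rate.
#' @param seed integer seed.
#' @param config optional base [sim_config()] supplying arena/acquisition
#'   settings.
#' @return list with `spots`, `truth`, plus `temperature` and `tpc_rate`
#'   (the generating rate, um/s).
#' @export
simulate_population <- function(tpc_params, model, temperature, n_cells,
                                motile_fraction, noise_cv = 0.1, seed = NULL,
                                config = sim_config()) {
  if (motile_fraction < 0 || motile_fraction > 1) {
    stop("motile_fraction must lie in [0, 1]")
  }
  rate <- tpc_rate(model, temperature, tpc_params)
  with_seed(seed, {
    if (!is.finite(rate) || rate <= 0) {
      n_mot <- 0L
      rate <- 0
    } else {
      n_mot <- rbinom(1, n_cells, motile_fraction)
    }
    n_rest <- n_cells - n_mot
    n_drift <- floor(n_rest / 2)
    n_stat <- n_rest - n_drift
    cfg <- config
    cfg$n_motile <- n_mot
    cfg$n_drifting <- n_drift
    cfg$n_stationary <- n_stat
    cfg$speed_mean_um_s <- rate
    cfg$speed_sd_um_s <- noise_cv * rate
    cfg$seed <- NULL # already inside with_seed()
    sim <- simulate_tracks(cfg)
    c(sim, list(temperature = temperature, tpc_rate = rate))
  })
}

# Additive Gaussian blob rendering shared by render_frames() and the
# phototaxis dish simulator. Positions in pixel units, origin top-left,
# x right / y down; img[row, col] = img[y + 1, x + 1].
add_blobs <- function(img, x_px, y_px, amplitude, sigma_px) {
  h <- nrow(img)
  w <- ncol(img)
  r <- ceiling(4 * sigma_px)
  for (k in seq_along(x_px)) {
    cx <- x_px[k]
    cy <- y_px[k]
    xs <- max(0, floor(cx) - r):min(w - 1, ceiling(cx) + r)
    ys <- max(0, floor(cy) - r):min(h - 1, ceiling(cy) + r)
    if (!length(xs) || !length(ys)) next
    gx <- exp(-((xs - cx)^2) / (2 * sigma_px^2))
    gy <- exp(-((ys - cy)^2) / (2 * sigma_px^2))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amplitude[k] * outer(gy, gx)
  }
  img
}

#' Render spot tables into a synthetic image stack
#'
#' Renders each spot as a Gaussian intensity blob on a noisy background,
#' bright-on-dark (videos are assumed intensity-inverted upstream so cells
#' appear as bright spots). Exercises the difference-of-Gaussians detector
#' end to end.
#'
#' @param spots spot table (`frame`, `x_um`, `y_um` columns).
#' @param pixel_size_um um per pixel; spot positions are divided by this.
#' @param width_px,height_px frame size; defaults cover the spot extent.
#' @param psf_sigma_px Gaussian blob scale (px).
#' @param peak_intensity blob peak amplitude (intensity units).
#' @param background_level constant background offset.
#' @param noise_sd sd of i.i.d. Gaussian read noise per pixel.
#' @param n_frames number of frames; defaults to `max(frame) + 1`.
#' @param seed integer seed for the noise.
#' @return list of numeric matrices (one per frame), `img[y + 1, x + 1]`.
#' @export
render_frames <- function(spots, pixel_size_um = 1, width_px = NULL,
                          height_px = NULL, psf_sigma_px = 2,
                          peak_intensity = 400, background_level = 100,
                          noise_sd = 5, n_frames = NULL, seed = NULL) {
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be positive")
  x_px <- spots$x_um / pixel_size_um
  y_px <- spots$y_um / pixel_size_um
  width_px <- width_px %||% ceiling(max(x_px, 0) + 6 * psf_sigma_px + 1)
  height_px <- height_px %||% ceiling(max(y_px, 0) + 6 * psf_sigma_px + 1)
  n_frames <- n_frames %||% (max(spots$frame) + 1)
  with_seed(seed, {
    lapply(seq_len(n_frames) - 1L, function(f) {
      img <- matrix(background_level, nrow = height_px, ncol = width_px)
      if (noise_sd > 0) {
        img <- img + matrix(rnorm(height_px * width_px, 0, noise_sd),
                            nrow = height_px)
      }
      sel <- spots$frame == f
      if (any(sel)) {
        img <- add_blobs(img, x_px[sel], y_px[sel],
                         rep(peak_intensity, sum(sel)), psf_sigma_px)
      }
      img
    })
  })
}

#' Simulate a phototaxis Petri-dish image pair
#'
#' Builds a background image (dish vignette, no cells) and an assay image in
#' which cell blobs are placed with a controllable bias toward the light
#' facing half of the dish (light along +x). `bias` is the expected fraction
#' of cell signal in the front half: 0.5 reproduces the no-phototaxis null,
#' 1.0 puts every cell in the front half.
#'
#' The same background realisation is shared by both images, so background
#' subtraction is exact and the downstream index isolates cell placement.
#'
#' @param n_cells number of cell blobs.
#' @param bias expected front-half fraction in [0, 1].
#' @param dish_diameter_px dish diameter (px); images are square with a small
#'   margin.
#' @param cell_intensity blob peak amplitude.
#' @param psf_sigma_px blob scale (px).
#' @param seed integer seed.
#' @return list with `background`, `assay` (matrices), `mask` (logical matrix
#'   of in-dish pixels), `light_axis` (unit 2-vector, +x) and `truth`
#'   (data.frame of blob positions and front-half membership).
#' @export
simulate_phototaxis_dish <- function(n_cells, bias, dish_diameter_px = 200,
                                     cell_intensity = 50, psf_sigma_px = 1.5,
                                     seed = NULL) {
  if (bias < 0 || bias > 1) stop("bias must lie in [0, 1]")
  R <- dish_diameter_px / 2
  margin <- 8
  side <- ceiling(dish_diameter_px + 2 * margin)
  side <- side + side %% 2 # even side: centre falls between pixels
  cx <- (side - 1) / 2
  cy <- (side - 1) / 2
  xg <- matrix(rep(0:(side - 1), each = side), nrow = side)
  yg <- matrix(rep(0:(side - 1), times = side), nrow = side)
  rr <- sqrt((xg - cx)^2 + (yg - cy)^2)
  mask <- rr <= R
  # dish vignette: brighter centre falling off towards the rim
  background <- matrix(20, side, side)
  background[mask] <- 60 + 40 * (1 - (rr[mask] / R)^2)
  with_seed(seed, {
    front <- runif(n_cells) < bias
    # uniform placement within the assigned half-disk (rejection sampling),
    # keeping blobs a few sigma inside the rim
    r_eff <- R - 3 * psf_sigma_px
    xs <- ys <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      repeat {
        px <- runif(1, -r_eff, r_eff)
        py <- runif(1, -r_eff, r_eff)
        if (px^2 + py^2 > r_eff^2) next
        if (front[i] == (px >= 0)) break
      }
      xs[i] <- cx + px
      ys[i] <- cy + py
    }
    assay <- add_blobs(background, xs, ys,
                       rep(cell_intensity, n_cells), psf_sigma_px)
    list(background = background, assay = assay, mask = mask,
         light_axis = c(1, 0),
         truth = data.frame(x_px = xs, y_px = ys, front = front))
  })
}
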