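#' Per-track motility metrics
#'
#' Computes, for one track, the standard motility descriptors:
#' \describe{
#'   \item{total_distance_um}{sum of consecutive-spot Euclidean distances
#'     (path length). Across a closed detection gap the straight segment
#'     between the retained spots contributes.}
#'   \item{max_distance_um}{maximum Euclidean displacement from the track's
#'     first spot to any later spot (the track-feature convention of common
#'     tracking software; the maximum over all spot pairs is available via
#'     `max_convention = "any_pair"` for sensitivity analysis).}
#'   \item{mean_speed_um_s}{path speed: total distance divided by elapsed
#'     time (last minus first timestamp).}
#'   \item{confinement_ratio}{max distance / total distance, in [0, 1]; 1
#'     for a straight path, near 0 for a confined loop; defined as 0 when
#'     the total distance is 0.}
#'   \item{dispersal_um_s}{mean speed times confinement ratio — an
#'     effective net-displacement rate.}
#' }
#'
#' @param track data.frame of one track's spots with `frame`, `x_um`,
#'   `y_um` and either `t_s` or both implied by `fps`.
#' @param fps frame rate, used to derive timestamps when `t_s` is absent.
#' @param max_convention `"from_first"` (default) or `"any_pair"`.
#' @return one-row data.frame with `track_id` (if present), `n_spots`,
#'   `duration_s`, `total_distance_um`, `max_distance_um`,
#'   `mean_speed_um_s`, `confinement_ratio`, `dispersal_um_s`.
#' @examples
#' tr <- data.frame(frame = 0:300, t_s = (0:300) / 30,
#'                  x_um = (0:300) / 3, y_um = 0)
#' track_metrics(tr) # 100 um path at 10 um/s, confinement 1
#' @export
track_metrics <- function(track, fps = 30,
                          max_convention = c("from_first", "any_pair")) {
  max_convention <- match.arg(max_convention)
  if (nrow(track) < 2) stop("track must contain at least 2 spots")
  o <- order(track$frame)
  track <- track[o, , drop = FALSE]
  t_s <- if ("t_s" %in% names(track)) track$t_s else track$frame / fps
  elapsed <- t_s[length(t_s)] - t_s[1]
  if (elapsed <= 0) stop("track has zero elapsed time")
  x <- track$x_um
  y <- track$y_um
  total <- sum(sqrt(diff(x)^2 + diff(y)^2))
  maxd <- if (max_convention == "from_first") {
    max(sqrt((x - x[1])^2 + (y - y[1])^2))
  } else {
    max(stats::dist(cbind(x, y)))
  }
  speed <- total / elapsed
  conf <- if (total > 0) maxd / total else 0
  data.frame(
    track_id = if ("track_id" %in% names(track)) track$track_id[1] else NA,
    n_spots = nrow(track), duration_s = elapsed,
    total_distance_um = total, max_distance_um = maxd,
    mean_speed_um_s = speed, confinement_ratio = conf,
    dispersal_um_s = speed * conf
  )
}

#' Motility metrics for every track in a table
#'
#' @param tracks data.frame of spots with a `track_id` column.
#' @inheritParams track_metrics
#' @return data.frame, one row per track.
#' @export
tracks_metrics <- function(tracks, fps = 30,
                           max_convention = c("from_first", "any_pair")) {
  max_convention <- match.arg(max_convention)
  parts <- split(tracks, tracks$track_id)
  out <- do.call(rbind, lapply(parts, track_metrics, fps = fps,
                               max_convention = max_convention))
  rownames(out) <- NULL
  out
}

#' Classify tracks as motile or non-motile
#'
#' A cell is motile when its total distance travelled reaches the distance
#' threshold. The default 100 um threshold is calibrated for 10 s
#' recordings, where it corresponds to an average path speed of 10 um/s; for
#' other recording durations the threshold is rescaled to keep that speed
#' equivalence (`10 um/s x duration`). The boundary is inclusive: exactly
#' 100 um counts as motile.
#'
#' @param metrics data.frame from [tracks_metrics()] (needs
#'   `total_distance_um`).
#' @param distance_threshold_um threshold for a 10 s recording (default
#'   100 um, i.e. 10 um/s).
#' @param recording_duration_s duration the threshold refers to.
#' @return the metrics data.frame with a logical `motile` column.
#' @export
classify_motile <- function(metrics, distance_threshold_um = 100,
                            recording_duration_s = 10) {
  thr <- distance_threshold_um * recording_duration_s / 10
  metrics$motile <- metrics$total_distance_um >= thr
  metrics
}

#' Calibrate the motile/non-motile distance threshold from controls
#'
#' Given metrics of a deciliated (non-motile) control population, returns a
#' total-distance threshold separating passive from active movement.
#'
#' Methods: `"fixed"` returns 100 um; `"quantile"` the `q`-th quantile of
#' control total distances (default 0.99, i.e. a threshold that fewer than
#' 1% of passive cells exceed); `"valley"` the minimum-density point between
#' the two largest modes of a kernel density estimate of log10 total
#' distance (requires mixed control data with at least 30 tracks).
#'
#' @param control_metrics metrics data.frame of control tracks.
#' @param method one of `"fixed"`, `"quantile"`, `"valley"`.
#' @param q quantile for the quantile method.
#' @param quiet suppress the log message.
#' @return threshold in um.
#' @export
calibrate_threshold <- function(control_metrics,
                                method = c("fixed", "quantile", "valley"),
                                q = 0.99, quiet = FALSE) {
  method <- match.arg(method)
  d <- control_metrics$total_distance_um
  thr <- switch(method,
    fixed = 100,
    quantile = unname(quantile(d, q)),
    valley = {
      if (length(d) < 30) {
        stop("valley calibration needs >= 30 control tracks; ",
             "use method = \"quantile\" instead")
      }
      ld <- log10(d[d > 0])
      dens <- density(ld)
      yy <- dens$y
      # local maxima of the KDE
      pk <- which(diff(sign(diff(yy))) == -2) + 1
      if (length(pk) < 2) {
        stop("no bimodal structure in control distances; ",
             "use method = \"quantile\" instead")
      }
      pk <- pk[order(yy[pk], decreasing = TRUE)][1:2]
      lo <- min(pk)
      hi <- max(pk)
      valley <- lo + which.min(yy[lo:hi]) - 1
      10^dens$x[valley]
    })
  if (!quiet) {
    message(sprintf("calibrate_threshold: method = %s, threshold = %.2f um",
                    method, thr))
  }
  thr
}

#' Summarise one replicate population
#'
#' Collapses per-track metrics of one replicate at one temperature into the
#' row consumed by the thermal-performance stage: the motile fraction and
#' the mean/sd of speed and dispersal over the motile subpopulation only
#' (each track weighted once).
#'
#' @param metrics metrics data.frame with a `motile` column (see
#'   [classify_motile()]).
#' @param species,temperature_C,replicate labels carried into the output.
#' @return one-row data.frame with `species`, `temperature_C`, `replicate`,
#'   `n_tracks`, `n_motile`, `motile_fraction`, `motile_mean_speed_um_s`,
#'   `motile_speed_sd`, `motile_mean_dispersal_um_s`, `motile_dispersal_sd`.
#' @export
population_summary <- function(metrics, species = NA, temperature_C = NA,
                               replicate = NA) {
  if (!"motile" %in% names(metrics)) {
    stop("metrics must carry a 'motile' column; run classify_motile() first")
  }
  n <- nrow(metrics)
  mot <- metrics[metrics$motile, , drop = FALSE]
  data.frame(
    species = species, temperature_C = temperature_C, replicate = replicate,
    n_tracks = n, n_motile = nrow(mot),
    motile_fraction = if (n > 0) nrow(mot) / n else NA_real_,
    motile_mean_speed_um_s = if (nrow(mot)) mean(mot$mean_speed_um_s) else NA_real_,
    motile_speed_sd = if (nrow(mot) > 1) sd(mot$mean_speed_um_s) else NA_real_,
    motile_mean_dispersal_um_s = if (nrow(mot)) mean(mot$dispersal_um_s) else NA_real_,
    motile_dispersal_sd = if (nrow(mot) > 1) sd(mot$dispersal_um_s) else NA_real_
  )
}

#' Convert a dispersal rate to metres per day
#'
#' `rate` in um/s times 86,400 s/day times 1e-6 m/um. Reported values are
#' conventionally truncated (not rounded) to two decimals, so 15 um/s
#' (= 1.296 m/day exactly) reports as 1.29.
#'
#' @param rate_um_s dispersal rate (um/s).
#' @param truncate truncate to two decimals for reporting.
#' @return m/day.
#' @examples
#' dispersal_to_m_per_day(15) # 1.296
#' dispersal_to_m_per_day(15, truncate = TRUE) # 1.29
#' @export
dispersal_to_m_per_day <- function(rate_um_s, truncate = FALSE) {
  v <- rate_um_s * 86400 * 1e-6
  if (truncate) trunc(v * 100) / 100 else v
}
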