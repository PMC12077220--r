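#' Linking settings for the LAP tracker
#'
#' Defaults follow the standard video-tracking configuration for 30 fps
#' microswimmer recordings: 30 px maximum frame-to-frame link distance,
#' 50 px / 30 frames (1 s) for track-segment gap closing, and removal of
#' tracks spanning fewer than 75 frames.
#'
#' @param link_max_dist_px maximum frame-to-frame link distance (px).
#' @param gap_max_dist_px maximum spatial distance for gap closing (px).
#' @param gap_max_frames maximum frame difference bridged by gap closing
#'   (a gap of `g` missing frames has frame difference `g + 1`).
#' @param min_track_frames minimum track span in frames (first to last,
#'   inclusive) retained by [filter_tracks()].
#' @param pixel_size_um um per pixel, used to convert the pixel radii to the
#'   spot table's um coordinates.
#' @return list of class `link_config`.
#' @export
link_config <- function(link_max_dist_px = 30, gap_max_dist_px = 50,
                        gap_max_frames = 30, min_track_frames = 75,
                        pixel_size_um = 1) {
  stopifnot(link_max_dist_px > 0, gap_max_dist_px > 0, gap_max_frames > 0,
            min_track_frames >= 2, pixel_size_um > 0)
  structure(list(link_max_dist_px = link_max_dist_px,
                 gap_max_dist_px = gap_max_dist_px,
                 gap_max_frames = gap_max_frames,
                 min_track_frames = min_track_frames,
                 pixel_size_um = pixel_size_um),
            class = "link_config")
}

BIG_COST <- 1e9

# Jaqaman-style padded square LAP: rows = [sources, dummy-per-target],
# cols = [targets, dummy-per-source]. `cost` is the n1 x n2 feasible-link
# block (BIG_COST where infeasible), `alt` the non-linking alternative cost.
# Returns an integer vector a of length n1: a[i] = j if source i links
# target j, NA otherwise.
lap_link_full <- function(cost, alt) {
  n1 <- nrow(cost)
  n2 <- ncol(cost)
  n <- n1 + n2
  M <- matrix(BIG_COST, n, n)
  M[seq_len(n1), seq_len(n2)] <- cost
  M[seq_len(n1), n2 + seq_len(n1)] <- `diag<-`(matrix(BIG_COST, n1, n1), alt)
  M[n1 + seq_len(n2), seq_len(n2)] <- `diag<-`(matrix(BIG_COST, n2, n2), alt)
  M[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0 # dummy-dummy block
  a <- .lap_solve(M)[seq_len(n1)]
  out <- rep(NA_integer_, n1)
  linked <- a <= n2
  if (any(linked)) {
    linked[linked] <- cost[cbind(which(linked), a[linked])] < BIG_COST
  }
  out[linked] <- a[linked]
  out
}

# The non-linking alternative is per-node, so the objective separates over
# connected components of the feasibility graph: solve each component's
# padded LAP independently (exact, and near-linear when most cells are far
# apart). Singleton pairs short-circuit: any feasible link costs at most
# `alt` < 2 * alt, so it is always taken.
lap_link <- function(cost, alt) {
  n1 <- nrow(cost)
  n2 <- ncol(cost)
  out <- rep(NA_integer_, n1)
  if (n1 == 0 || n2 == 0) return(out)
  feas <- cost < BIG_COST
  src_nb <- apply(feas, 1, which, simplify = FALSE)
  tgt_nb <- apply(feas, 2, which, simplify = FALSE)
  seen_s <- rep(FALSE, n1)
  seen_t <- rep(FALSE, n2)
  for (s0 in seq_len(n1)) {
    if (seen_s[s0]) next
    # BFS over the bipartite feasibility graph
    cs <- s0
    ct <- integer(0)
    seen_s[s0] <- TRUE
    queue_s <- s0
    queue_t <- integer(0)
    while (length(queue_s) || length(queue_t)) {
      if (length(queue_s)) {
        s <- queue_s[1]
        queue_s <- queue_s[-1]
        for (t in src_nb[[s]]) {
          if (!seen_t[t]) {
            seen_t[t] <- TRUE
            ct <- c(ct, t)
            queue_t <- c(queue_t, t)
          }
        }
      } else {
        t <- queue_t[1]
        queue_t <- queue_t[-1]
        for (s in tgt_nb[[t]]) {
          if (!seen_s[s]) {
            seen_s[s] <- TRUE
            cs <- c(cs, s)
            queue_s <- c(queue_s, s)
          }
        }
      }
    }
    if (length(ct) == 0) next # isolated source: no link
    if (length(cs) == 1 && length(ct) == 1) {
      out[cs] <- ct
    } else {
      sub <- lap_link_full(cost[cs, ct, drop = FALSE], alt)
      out[cs] <- ct[sub]
    }
  }
  out
}

#' Link spots into tracks with a two-stage LAP tracker
#'
#' Stage 1 links spots between consecutive frames by a one-to-one assignment
#' minimising summed squared distances, subject to a maximum link radius;
#' unlinked spots start new track segments. Stage 2 closes detection gaps by
#' assigning segment ends to later segment starts within a spatial radius
#' and a maximum frame difference, again by minimum-cost assignment. Both
#' stages use an exact assignment solver with a non-linking alternative cost
#' equal to the squared maximum radius, so every feasible link is preferred
#' over leaving both parties unlinked. No splitting or merging is performed;
#' the assignment is deterministic for a fixed spot ordering.
#'
#' @param spots spot table with columns `frame`, `x_um`, `y_um` (plus any
#'   others, carried through).
#' @param cfg a [link_config()]; pixel radii are converted to um via
#'   `cfg$pixel_size_um`.
#' @return data.frame of the input spots with a `track_id` column, ordered
#'   by `track_id` then `frame`.
#' @export
link_tracks <- function(spots, cfg = link_config()) {
  stopifnot(inherits(cfg, "link_config"))
  if (nrow(spots) == 0) {
    spots$track_id <- integer(0)
    return(spots)
  }
  o <- order(spots$frame)
  spots <- spots[o, , drop = FALSE]
  link_r <- cfg$link_max_dist_px * cfg$pixel_size_um
  gap_r <- cfg$gap_max_dist_px * cfg$pixel_size_um

  frames <- sort(unique(spots$frame))
  idx_by_frame <- split(seq_len(nrow(spots)), spots$frame)
  # segments as growing integer vectors of spot row indices
  segs <- as.list(idx_by_frame[[1]])
  open_seg <- seq_along(segs) # segments whose last spot is in current frame
  for (fi in seq_len(length(frames) - 1)) {
    if (frames[fi + 1] != frames[fi] + 1) {
      open_seg <- integer(0) # non-consecutive: stage 2 handles the gap
    }
    nxt <- idx_by_frame[[as.character(frames[fi + 1])]]
    if (length(open_seg) && length(nxt)) {
      ends <- vapply(segs[open_seg], function(s) s[length(s)], integer(1))
      dx <- outer(spots$x_um[ends], spots$x_um[nxt], `-`)
      dy <- outer(spots$y_um[ends], spots$y_um[nxt], `-`)
      d2 <- dx * dx + dy * dy
      costm <- matrix(BIG_COST, length(ends), length(nxt))
      feas <- d2 <= link_r^2
      costm[feas] <- d2[feas]
      a <- lap_link(costm, link_r^2)
    } else {
      a <- rep(NA_integer_, length(open_seg))
    }
    new_open <- integer(0)
    taken <- rep(FALSE, length(nxt))
    for (k in seq_along(open_seg)) {
      if (!is.na(a[k])) {
        s <- open_seg[k]
        segs[[s]] <- c(segs[[s]], nxt[a[k]])
        taken[a[k]] <- TRUE
        new_open <- c(new_open, s)
      }
    }
    for (j in which(!taken)) {
      segs[[length(segs) + 1]] <- nxt[j]
      new_open <- c(new_open, length(segs))
    }
    open_seg <- new_open
  }

  # stage 2: gap closing between segment ends and later segment starts
  n_seg <- length(segs)
  if (n_seg > 1) {
    end_i <- vapply(segs, function(s) s[length(s)], integer(1))
    start_i <- vapply(segs, function(s) s[1], integer(1))
    ef <- spots$frame[end_i]
    sf <- spots$frame[start_i]
    dframe <- outer(sf, ef, `-`) # dframe[j, i] = start_j - end_i
    dx <- outer(spots$x_um[start_i], spots$x_um[end_i], `-`)
    dy <- outer(spots$y_um[start_i], spots$y_um[end_i], `-`)
    d2 <- dx * dx + dy * dy
    feas <- t(dframe >= 2 & dframe <= cfg$gap_max_frames & d2 <= gap_r^2)
    if (any(feas)) {
      costm <- matrix(BIG_COST, n_seg, n_seg)
      costm[feas] <- t(d2)[feas]
      a <- lap_link(costm, gap_r^2)
      # merge chains: follow successor pointers from chain heads
      succ <- a
      has_pred <- rep(FALSE, n_seg)
      has_pred[succ[!is.na(succ)]] <- TRUE
      merged <- vector("list", 0)
      for (s in seq_len(n_seg)) {
        if (has_pred[s]) next
        chain <- segs[[s]]
        j <- succ[s]
        while (!is.na(j)) {
          chain <- c(chain, segs[[j]])
          j <- succ[j]
        }
        merged[[length(merged) + 1]] <- chain
      }
      segs <- merged
    }
  }

  ord <- order(vapply(segs, function(s) spots$frame[s[1]], numeric(1)),
               vapply(segs, function(s) s[1], integer(1)))
  segs <- segs[ord]
  out <- spots[unlist(segs), , drop = FALSE]
  out$track_id <- rep(seq_along(segs), lengths(segs))
  rownames(out) <- NULL
  out[, c("track_id", setdiff(names(out), "track_id"))]
}

#' Remove short tracks
#'
#' Drops tracks whose frame span (last minus first frame, inclusive) is
#' below `min_track_frames`. The number of removed tracks is reported via
#' `message()` and attached as attribute `n_removed`.
#'
#' @param tracks data.frame with `track_id` and `frame` columns.
#' @param min_track_frames minimum span in frames (default 75).
#' @param quiet suppress the message.
#' @return filtered data.frame.
#' @export
filter_tracks <- function(tracks, min_track_frames = 75, quiet = FALSE) {
  if (nrow(tracks) == 0) {
    attr(tracks, "n_removed") <- 0L
    return(tracks)
  }
  span <- tapply(tracks$frame, tracks$track_id,
                 function(f) max(f) - min(f) + 1)
  keep_ids <- as.numeric(names(span)[span >= min_track_frames])
  n_removed <- length(span) - length(keep_ids)
  if (!quiet && n_removed > 0) {
    message(sprintf("filter_tracks: removed %d track(s) shorter than %d frames",
                    n_removed, min_track_frames))
  }
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- as.integer(n_removed)
  out
}

#' Detect spots by difference-of-Gaussians filtering
#'
#' Band-pass filters each frame with a difference of two Gaussians tuned to
#' the expected object diameter, then reports local maxima above a quality
#' threshold with sub-pixel centroid refinement (per-axis parabolic fit on
#' the 3x3 neighbourhood). Quality is the raw DoG response at the maximum,
#' so thresholds are dataset-specific and do not transfer between detectors
#' with different normalisations.
#'
#' @param frames list of numeric matrices (bright spots on dark background),
#'   `img[y + 1, x + 1]`, or a 3D array with the frame index last.
#' @param diameter_px expected object diameter (px); the inner Gaussian
#'   scale is `diameter_px / (2 * sqrt(2))`, the outer `sqrt(2)` larger.
#' @param quality_threshold minimum DoG response retained.
#' @param pixel_size_um um per pixel for the output coordinates.
#' @param fps frame rate, for spot timestamps.
#' @return spot table (`frame`, `t_s`, `x_um`, `y_um`, `quality`).
#' @export
detect_spots_dog <- function(frames, diameter_px, quality_threshold = 0,
                             pixel_size_um = 1, fps = 30) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  if (length(frames) == 0) stop("empty image stack")
  if (diameter_px <= 0) stop("diameter_px must be positive")
  s1 <- diameter_px / (2 * sqrt(2))
  s2 <- s1 * sqrt(2)
  res <- lapply(seq_along(frames), function(fi) {
    img <- frames[[fi]]
    dog <- EBImage::gblur(img, sigma = s1) - EBImage::gblur(img, sigma = s2)
    h <- nrow(dog)
    w <- ncol(dog)
    if (h < 3 || w < 3) return(NULL)
    core <- dog[2:(h - 1), 2:(w - 1)]
    is_max <- core > quality_threshold
    for (dyy in -1:1) for (dxx in -1:1) {
      if (dyy == 0 && dxx == 0) next
      nb <- dog[2:(h - 1) + dyy, 2:(w - 1) + dxx]
      is_max <- is_max & (core > nb)
    }
    hits <- which(is_max, arr.ind = TRUE)
    if (nrow(hits) == 0) return(NULL)
    ry <- hits[, 1] + 1 # row/col in full image
    cx <- hits[, 2] + 1
    # per-axis parabolic sub-pixel refinement
    f0 <- dog[cbind(ry, cx)]
    fxm <- dog[cbind(ry, cx - 1)]
    fxp <- dog[cbind(ry, cx + 1)]
    fym <- dog[cbind(ry - 1, cx)]
    fyp <- dog[cbind(ry + 1, cx)]
    denx <- fxm - 2 * f0 + fxp
    deny <- fym - 2 * f0 + fyp
    dx <- ifelse(abs(denx) > 1e-12, 0.5 * (fxm - fxp) / denx, 0)
    dy <- ifelse(abs(deny) > 1e-12, 0.5 * (fym - fyp) / deny, 0)
    dx <- pmin(pmax(dx, -0.5), 0.5)
    dy <- pmin(pmax(dy, -0.5), 0.5)
    data.frame(frame = fi - 1L,
               x_px = (cx - 1) + dx, y_px = (ry - 1) + dy, quality = f0)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      quality = numeric())
  }
  data.frame(frame = res$frame, t_s = res$frame / fps,
             x_um = res$x_px * pixel_size_um,
             y_um = res$y_px * pixel_size_um, quality = res$quality)
}

#' Generic column-threshold spot filter
#'
#' Optional post-detection filters (e.g. on intensity standard deviation or
#' signal-to-noise columns carried in the spot table). Off by default: such
#' filters are tuned per video batch, so no fixed value is meaningful.
#'
#' @param spots spot table.
#' @param column column name.
#' @param min,max inclusive bounds; `NULL` leaves the side open.
#' @return filtered spot table.
#' @export
filter_spots <- function(spots, column, min = NULL, max = NULL) {
  if (!column %in% names(spots)) stop("no such column: ", column)
  keep <- rep(TRUE, nrow(spots))
  if (!is.null(min)) keep <- keep & spots[[column]] >= min
  if (!is.null(max)) keep <- keep & spots[[column]] <= max
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

trackmate_required <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y",
                        "POSITION_T")

#' Read a TrackMate-style spots CSV export
#'
#' Parses the spot-export dialect: a header row naming at least `TRACK_ID`,
#' `FRAME`, `POSITION_X`, `POSITION_Y`, `POSITION_T` (plus optional
#' `QUALITY`), tolerating up to three non-numeric decoration rows (repeated
#' names, units, shortcut labels) below the header. Spots are grouped by
#' `TRACK_ID`; positions are interpreted in the file's spatial unit unless
#' `unit_to_um` rescales them.
#'
#' @param path CSV path.
#' @param unit_to_um multiplier converting the file's spatial unit to um
#'   (default 1: positions already in um).
#' @return data.frame with `track_id`, `frame`, `t_s`, `x_um`, `y_um`,
#'   `quality`, ordered by track then frame. Rows without a track id
#'   (raw detections) get `track_id = NA`.
#' @export
read_trackmate_export <- function(path, unit_to_um = 1) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trackmate_required, names(raw))
  if (length(missing_cols)) {
    stop("TrackMate export is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  # drop decoration rows: FRAME must parse as a number
  frame_num <- suppressWarnings(as.numeric(raw$FRAME))
  raw <- raw[!is.na(frame_num), , drop = FALSE]
  if (nrow(raw) == 0) stop("no data rows in TrackMate export")
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    track_id = num(raw$TRACK_ID),
    frame = as.integer(num(raw$FRAME)),
    t_s = num(raw$POSITION_T),
    x_um = num(raw$POSITION_X) * unit_to_um,
    y_um = num(raw$POSITION_Y) * unit_to_um,
    quality = if ("QUALITY" %in% names(raw)) num(raw$QUALITY) else NA_real_
  )
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a spot/track table as a TrackMate-style CSV
#'
#' @param spots data.frame with `frame`, `t_s`, `x_um`, `y_um` and optional
#'   `track_id`, `quality` columns.
#' @param path output path.
#' @export
write_spots_csv <- function(spots, path) {
  out <- data.frame(
    TRACK_ID = if ("track_id" %in% names(spots)) spots$track_id else "",
    FRAME = spots$frame,
    POSITION_T = spots$t_s,
    POSITION_X = spots$x_um,
    POSITION_Y = spots$y_um,
    QUALITY = if ("quality" %in% names(spots)) spots$quality else NA_real_
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities are linearly scaled by `1 / max_intensity` into [0, 1] and
#' stored at 16 bits per sample.
#'
#' @param frames list of numeric matrices.
#' @param path output path.
#' @param max_intensity intensity mapped to white.
#' @export
write_frames_tiff <- function(frames, path, max_intensity = NULL) {
  max_intensity <- max_intensity %||% max(vapply(frames, max, numeric(1)))
  scaled <- lapply(frames, function(f) pmin(pmax(f / max_intensity, 0), 1))
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a list of matrices
#'
#' @param path TIFF path.
#' @return list of numeric matrices with intensities in the unit interval.
#' @export
read_frames_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(m) if (length(dim(m)) == 3) m[, , 1] else m)
}
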