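## Directional-run extraction. A trajectory is scanned with the cosine of
## the angle between consecutive instantaneous velocity vectors as a
## directional-correlation measure; maximal stretches where every interior
## cosine exceeds the threshold (default 0.6, an ~100 degree forward cone)
## become candidate runs, which are then filtered per analysis variant:
##   single_channel: tracks of >= 20 frames, runs lasting more than six
##     frames, split wherever more than three consecutive per-frame
##     displacements are one pixel or less;
##   colocalized: runs longer than 0.3 s with net displacement above 0.5 um.

#' Instantaneous velocities of a track
#'
#' Forward differences between consecutive detections divided by the true
#' time difference (so a gap-closed link yields the average velocity across
#' the gap). The directional-correlation cosine compares each velocity with
#' the previous one and is undefined (NA) whenever either has zero length.
#'
#' @param track data frame with `frame`, `x_um`, `y_um` for one track,
#'   ordered by frame.
#' @param dt frame interval, seconds.
#' @return data frame with one row per consecutive position pair: `frame`
#'   (start of the pair), `dt_s` (true time difference), `vx`, `vy`,
#'   `speed` (um/s), `step_um` (displacement) and `cos_prev`.
#' @export
compute_velocities <- function(track, dt = 0.1) {
  n <- nrow(track)
  if (n < 2L)
    return(data.frame(frame = integer(0), dt_s = numeric(0), vx = numeric(0),
                      vy = numeric(0), speed = numeric(0),
                      step_um = numeric(0), cos_prev = numeric(0)))
  df <- diff(track$frame)
  dts <- df * dt
  dx <- diff(track$x_um); dy <- diff(track$y_um)
  vx <- dx / dts; vy <- dy / dts
  speed <- sqrt(vx^2 + vy^2)
  m <- n - 1L
  cos_prev <- rep(NA_real_, m)
  if (m >= 2L) {
    num <- vx[-m] * vx[-1] + vy[-m] * vy[-1]
    den <- speed[-m] * speed[-1]
    cp <- ifelse(den > 0, num / den, NA_real_)
    cos_prev[-1] <- pmin(1, pmax(-1, cp))
  }
  data.frame(frame = track$frame[-n], dt_s = dts, vx = vx, vy = vy,
             speed = speed, step_um = speed * dts, cos_prev = cos_prev)
}

#' Segment tracks into directional runs
#'
#' Extracts maximal directional segments (every cosine between consecutive
#' velocity vectors strictly above `cos_threshold`; an undefined cosine from
#' a zero-length velocity terminates a segment) and applies the variant
#' filters described above. For colocalized tracks the coordinates driving
#' segmentation are configurable via `segment_channel`: the cargo channel
#' (`gx`/`gy`, default), the motor channel (`rx`/`ry`) or the averaged
#' position.
#'
#' @param tracks data frame with `track_id`, `frame`, `x_um`, `y_um` (and
#'   per-channel columns for colocalized data).
#' @param variant `"colocalized"` or `"single_channel"`.
#' @param dt frame interval, seconds.
#' @param cos_threshold directional-correlation threshold (strictly above).
#' @param min_run_frames single-channel minimum run length in positions
#'   ("more than six frames" = at least 7).
#' @param min_track_frames single-channel minimum track length.
#' @param pause_max_px pause step threshold in pixels.
#' @param pause_min_steps minimum consecutive pause steps that split a run
#'   ("more than three" = at least 4).
#' @param pixel_size micrometres per pixel for the pause threshold.
#' @param min_duration_s colocalized minimum run duration (strictly above).
#' @param min_displacement_um colocalized minimum net displacement
#'   (strictly above).
#' @param segment_channel coordinates driving segmentation for colocalized
#'   tracks.
#' @return data frame of runs: `run_id`, `track_id`, `start_frame`,
#'   `end_frame`, `n_points`, `duration_s`, `length_um`, `net_um`,
#'   `speed_um_s`, `vx`, `vy` (mean velocity vector), `com_x`, `com_y`,
#'   `start_x`, `start_y`, and the row span `row_start`, `row_end` into the
#'   (track-ordered) input.
#' @export
segment_runs <- function(tracks,
                         variant = c("colocalized", "single_channel"),
                         dt = 0.1, cos_threshold = 0.6,
                         min_run_frames = 7L, min_track_frames = 20L,
                         pause_max_px = 1, pause_min_steps = 4L,
                         pixel_size = 0.065,
                         min_duration_s = 0.3, min_displacement_um = 0.5,
                         segment_channel = c("cargo", "motor", "averaged")) {
  variant <- match.arg(variant)
  segment_channel <- match.arg(segment_channel)
  if (is.null(tracks$track_id)) tracks$track_id <- 1L
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  cols <- switch(segment_channel,
                 cargo = if (all(c("gx", "gy") %in% names(tracks)))
                   c("gx", "gy") else c("x_um", "y_um"),
                 motor = if (all(c("rx", "ry") %in% names(tracks)))
                   c("rx", "ry") else c("x_um", "y_um"),
                 averaged = c("x_um", "y_um"))
  split_rows <- split(seq_len(nrow(tracks)), tracks$track_id)
  runs <- list(); rid <- 0L
  for (rows in split_rows) {
    tr <- tracks[rows, ]
    if (variant == "single_channel" && nrow(tr) < min_track_frames) next
    seg_tr <- data.frame(frame = tr$frame,
                         x_um = tr[[cols[1]]], y_um = tr[[cols[2]]])
    segs <- maximal_directional_segments(seg_tr, dt, cos_threshold)
    if (variant == "single_channel" && length(segs)) {
      segs <- unlist(lapply(segs, function(s)
        split_at_pauses(s, seg_tr, pause_max_px * pixel_size,
                        pause_min_steps)), recursive = FALSE)
    }
    for (s in segs) {
      a <- s[1]; b <- s[2]
      npt <- b - a + 1L
      dur <- (seg_tr$frame[b] - seg_tr$frame[a]) * dt
      if (variant == "single_channel") {
        if (npt < min_run_frames) next
      } else {
        net0 <- sqrt((seg_tr$x_um[b] - seg_tr$x_um[a])^2 +
                     (seg_tr$y_um[b] - seg_tr$y_um[a])^2)
        if (dur <= min_duration_s || net0 <= min_displacement_um) next
      }
      rid <- rid + 1L
      runs[[rid]] <- run_record(rid, tr, seg_tr, a, b, dt, rows)
    }
  }
  if (!length(runs))
    return(data.frame(run_id = integer(0), track_id = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      n_points = integer(0), duration_s = numeric(0),
                      length_um = numeric(0), net_um = numeric(0),
                      speed_um_s = numeric(0), vx = numeric(0),
                      vy = numeric(0), com_x = numeric(0), com_y = numeric(0),
                      start_x = numeric(0), start_y = numeric(0),
                      row_start = integer(0), row_end = integer(0)))
  do.call(rbind, runs)
}

## maximal position windows [a, b] in which every interior cosine is
## strictly above the threshold; windows carry at least one cosine
## (>= 3 positions) -- shorter windows cannot pass either variant filter
maximal_directional_segments <- function(tr, dt, thr) {
  v <- compute_velocities(tr, dt)
  m <- nrow(v)
  if (m < 2L) return(list())
  ok <- !is.na(v$cos_prev[-1]) & v$cos_prev[-1] > thr   # cosine k: v[k] vs v[k+1]
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    a <- starts[i]          # first satisfied cosine index
    b <- ends[i]
    segs[[length(segs) + 1L]] <- c(a, b + 2L)   # positions a .. b+2
  }
  segs
}

## split a run wherever >= min_steps consecutive steps are <= max_step;
## the pause itself is removed from both fragments
split_at_pauses <- function(seg, tr, max_step_um, min_steps) {
  a <- seg[1]; b <- seg[2]
  idx <- a:(b - 1L)
  step <- sqrt(diff(tr$x_um[a:b])^2 + diff(tr$y_um[a:b])^2)
  paused <- step <= max_step_um
  r <- rle(paused)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cut_from <- integer(0); cut_to <- integer(0)
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= min_steps) {
      cut_from <- c(cut_from, idx[starts[i]])     # first paused step
      cut_to <- c(cut_to, idx[ends[i]] + 1L)      # position after the pause
    }
  }
  if (!length(cut_from)) return(list(seg))
  out <- list()
  lo <- a
  for (i in seq_along(cut_from)) {
    if (cut_from[i] > lo) out[[length(out) + 1L]] <- c(lo, cut_from[i])
    lo <- cut_to[i]
  }
  if (b > lo) out[[length(out) + 1L]] <- c(lo, b)
  out
}

run_record <- function(rid, tr, seg_tr, a, b, dt, rows) {
  v <- compute_velocities(seg_tr[a:b, ], dt)
  dur <- (seg_tr$frame[b] - seg_tr$frame[a]) * dt
  len <- sum(v$step_um)
  net <- sqrt((seg_tr$x_um[b] - seg_tr$x_um[a])^2 +
              (seg_tr$y_um[b] - seg_tr$y_um[a])^2)
  data.frame(run_id = rid,
             track_id = tr$track_id[1],
             start_frame = seg_tr$frame[a], end_frame = seg_tr$frame[b],
             n_points = b - a + 1L, duration_s = dur, length_um = len,
             net_um = net, speed_um_s = len / dur,
             vx = mean(v$vx), vy = mean(v$vy),
             com_x = mean(seg_tr$x_um[a:b]), com_y = mean(seg_tr$y_um[a:b]),
             start_x = seg_tr$x_um[a], start_y = seg_tr$y_um[a],
             row_start = rows[a], row_end = rows[b])
}

#' Metrics of a single run
#'
#' @param positions data frame with `frame`, `x_um`, `y_um` of the run.
#' @param dt frame interval, seconds.
#' @return named list: `duration_s` (true time span), `length_um` (summed
#'   step lengths), `net_um` (start-to-end displacement) and `speed_um_s`
#'   (path length over duration).
#' @export
run_metrics <- function(positions, dt = 0.1) {
  stopifnot(nrow(positions) >= 2L)
  v <- compute_velocities(positions, dt)
  n <- nrow(positions)
  dur <- (positions$frame[n] - positions$frame[1]) * dt
  len <- sum(v$step_um)
  net <- sqrt((positions$x_um[n] - positions$x_um[1])^2 +
              (positions$y_um[n] - positions$y_um[1])^2)
  list(duration_s = dur, length_um = len, net_um = net,
       speed_um_s = len / dur)
}

#' Per-cell run-fraction statistics
#'
#' Summarizes, per cell, how much of the vesicle motility is processive:
#' the percentage of tracks containing at least one run, the cumulated run
#' duration as a percentage of the total track duration, the per-track
#' fraction of processive motion among run-containing tracks, and the mean
#' duration of tracks with versus without runs.
#'
#' @param tracks data frame with `track_id`, `frame` and a `cell` column.
#' @param runs output of [segment_runs()] for those tracks.
#' @param dt frame interval, seconds.
#' @return list with `per_cell` (one row per cell) and `per_track`
#'   (track-level durations and processive fractions).
#' @export
run_fraction_stats <- function(tracks, runs, dt = 0.1) {
  if (is.null(tracks$cell)) tracks$cell <- 1L
  tr_cell <- tapply(tracks$cell, tracks$track_id, function(x) x[1])
  fr_min <- tapply(tracks$frame, tracks$track_id, min)
  fr_max <- tapply(tracks$frame, tracks$track_id, max)
  per_track <- data.frame(track_id = as.integer(names(tr_cell)),
                          cell = as.vector(tr_cell),
                          duration_s = as.vector(fr_max - fr_min) * dt)
  run_dur <- rep(0, nrow(per_track))
  if (nrow(runs)) {
    agg <- tapply(runs$duration_s, runs$track_id, sum)
    m <- match(as.integer(names(agg)), per_track$track_id)
    run_dur[m] <- as.vector(agg)
  }
  per_track$run_duration_s <- run_dur
  per_track$has_runs <- run_dur > 0
  per_track$frac_processive <- ifelse(per_track$duration_s > 0,
                                      pmin(1, run_dur / per_track$duration_s),
                                      NA_real_)
  cells <- unique(per_track$cell)
  per_cell <- do.call(rbind, lapply(cells, function(cl) {
    pt <- per_track[per_track$cell == cl, ]
    if (nrow(pt) == 0L) return(NULL)
    with_runs <- pt[pt$has_runs, ]
    data.frame(cell = cl,
               n_tracks = nrow(pt),
               pct_tracks_with_runs = 100 * mean(pt$has_runs),
               pct_run_duration = if (sum(pt$duration_s) > 0)
                 100 * sum(pt$run_duration_s) / sum(pt$duration_s) else NA_real_,
               mean_frac_processive = if (nrow(with_runs))
                 mean(with_runs$frac_processive) else NA_real_,
               mean_duration_with_runs = if (nrow(with_runs))
                 mean(with_runs$duration_s) else NA_real_,
               mean_duration_without_runs = if (any(!pt$has_runs))
                 mean(pt$duration_s[!pt$has_runs]) else NA_real_)
  }))
  list(per_cell = per_cell, per_track = per_track)
}
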