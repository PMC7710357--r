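## Two-channel colocalization pairing and multi-frame track assembly.
## Pairing: per-frame one-to-one nearest-neighbour matching under 0.52 um
## (8 px at 0.065 um/px); the averaged (midpoint) coordinate is stored along
## with the original per-channel coordinates. Linking: frame-to-frame
## nearest-neighbour assignment under 0.65 um (10 px) with gap closing over
## up to 5 fully missing frames. Positions are never interpolated across
## gaps; velocities later use the true time difference.

#' Pair green and red detections per frame
#'
#' One-to-one colocalization pairing of two detection tables registered to
#' a common coordinate frame. Within each frame, pairing maximizes the
#' number of pairs within `threshold` and, among those, minimizes the total
#' pair distance. Unpaired detections are discarded from the colocalization
#' analysis.
#'
#' @param green,red detection data frames (`frame`, `x_um`, `y_um`).
#' @param threshold pairing distance threshold, micrometres (default
#'   0.52 um = 8 px at 0.065 um/px).
#' @param method assignment mode, see [match_points()].
#' @return data frame with `frame`, averaged `x_um`, `y_um` (midpoint),
#'   per-channel originals `gx`, `gy`, `rx`, `ry`, and `pair_dist` (um).
#' @export
pair_channels <- function(green, red, threshold = 0.52,
                          method = c("optimal", "greedy")) {
  method <- match.arg(method)
  frames <- intersect(unique(green$frame), unique(red$frame))
  gs <- split(seq_len(nrow(green)), green$frame)
  rs <- split(seq_len(nrow(red)), red$frame)
  out <- lapply(as.character(sort(frames)), function(f) {
    gi <- gs[[f]]; ri <- rs[[f]]
    m <- match_points(cbind(green$x_um[gi], green$y_um[gi]),
                      cbind(red$x_um[ri], red$y_um[ri]),
                      threshold, method = method)
    if (nrow(m) == 0L) return(NULL)
    gi <- gi[m[, 1]]; ri <- ri[m[, 2]]
    data.frame(frame = green$frame[gi],
               x_um = (green$x_um[gi] + red$x_um[ri]) / 2,
               y_um = (green$y_um[gi] + red$y_um[ri]) / 2,
               gx = green$x_um[gi], gy = green$y_um[gi],
               rx = red$x_um[ri], ry = red$y_um[ri],
               pair_dist = attr(m, "dist"))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                      gx = numeric(0), gy = numeric(0), rx = numeric(0),
                      ry = numeric(0), pair_dist = numeric(0))
  rownames(out) <- NULL
  out
}

#' Link detections into tracks with gap closing
#'
#' Frame-to-frame nearest-neighbour track assembly: at each frame, open
#' tracks (those whose last detection is at most `max_gap_frames + 1` frames
#' old) compete for the frame's detections under a one-to-one
#' minimal-total-distance assignment with distance threshold `threshold`.
#' Unassigned detections seed new tracks. Tracks with fewer than
#' `min_track_frames` detections are discarded.
#'
#' @param detections data frame with `frame`, `x_um`, `y_um`; any further
#'   columns (e.g. per-channel coordinates from [pair_channels()]) are
#'   carried through.
#' @param threshold link distance threshold, micrometres (default 0.65 um =
#'   10 px at 0.065 um/px).
#' @param max_gap_frames maximum number of fully missing frames bridged by
#'   gap closing.
#' @param min_track_frames minimum detections per kept track.
#' @param method assignment mode, see [match_points()].
#' @return data frame of the input rows ordered by (`track_id`, `frame`)
#'   with a `track_id` column prepended.
#' @export
link_tracks <- function(detections, threshold = 0.65, max_gap_frames = 5L,
                        min_track_frames = 20L,
                        method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (nrow(detections) == 0L)
    return(cbind(track_id = integer(0), detections))
  o <- order(detections$frame)
  detections <- detections[o, ]
  frames <- sort(unique(detections$frame))
  idx_by_frame <- split(seq_len(nrow(detections)), detections$frame)

  track_of <- integer(nrow(detections))
  ## open track state
  tr_last_x <- numeric(0); tr_last_y <- numeric(0)
  tr_last_f <- integer(0); tr_id <- integer(0)
  next_id <- 1L

  for (f in frames) {
    di <- idx_by_frame[[as.character(f)]]
    open <- which(tr_last_f >= f - (max_gap_frames + 1L))
    assigned <- rep(FALSE, length(di))
    if (length(open)) {
      m <- match_points(cbind(tr_last_x[open], tr_last_y[open]),
                        cbind(detections$x_um[di], detections$y_um[di]),
                        threshold, method = method)
      if (nrow(m)) {
        ti <- open[m[, 1]]; dj <- di[m[, 2]]
        track_of[dj] <- tr_id[ti]
        tr_last_x[ti] <- detections$x_um[dj]
        tr_last_y[ti] <- detections$y_um[dj]
        tr_last_f[ti] <- f
        assigned[m[, 2]] <- TRUE
      }
    }
    for (j in di[!assigned]) {
      tr_id <- c(tr_id, next_id)
      tr_last_x <- c(tr_last_x, detections$x_um[j])
      tr_last_y <- c(tr_last_y, detections$y_um[j])
      tr_last_f <- c(tr_last_f, f)
      track_of[j] <- next_id
      next_id <- next_id + 1L
    }
  }
  out <- cbind(track_id = track_of, detections)
  counts <- table(out$track_id)
  keep <- names(counts)[counts >= min_track_frames]
  out <- out[out$track_id %in% as.integer(keep), ]
  out <- out[order(out$track_id, out$frame), ]
  ## renumber consecutively
  out$track_id <- match(out$track_id, unique(out$track_id))
  rownames(out) <- NULL
  out
}
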