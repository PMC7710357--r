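## Motor-on-cargo geometry. For every frame of a colocalized run the vector
## l from the cargo centre to the motor centre is projected onto the axis
## defined by the cargo's instantaneous velocity v:
##   d = (v . l) / |v|          (signed; positive = motor ahead)
##   alpha = arccos(d / |l|)    (degrees, [0, 180])
## d is computed from the registration-corrected per-channel original
## coordinates, not from the averaged position (averaging the two channels
## would halve the offset).

#' Projected motor-cargo distance
#'
#' @param cargo,motor two-column matrices (or data frames) of positions,
#'   micrometres.
#' @param v two-column matrix of cargo velocity vectors, um/s.
#' @return data frame with `d_um` (signed projected distance), `alpha_deg`
#'   (angle between distance and velocity vectors) and `l_um` (absolute
#'   distance). Rows with zero-length velocity get NA (excluded upstream);
#'   `alpha_deg` is NA when `l_um` is 0.
#' @export
projected_distance <- function(cargo, motor, v) {
  cargo <- as.matrix(cargo); motor <- as.matrix(motor); v <- as.matrix(v)
  lx <- motor[, 1] - cargo[, 1]
  ly <- motor[, 2] - cargo[, 2]
  vn <- sqrt(v[, 1]^2 + v[, 2]^2)
  l <- sqrt(lx^2 + ly^2)
  d <- ifelse(vn > 0, (v[, 1] * lx + v[, 2] * ly) / vn, NA_real_)
  ratio <- ifelse(l > 0, pmin(1, pmax(-1, d / l)), NA_real_)
  alpha <- acos(ratio) * 180 / pi
  data.frame(d_um = d, alpha_deg = alpha, l_um = l)
}

#' Per-timepoint geometry of colocalized runs
#'
#' Computes the projected distance `d`, angle `alpha` and absolute distance
#' `|l|` at every timepoint of every run. The instantaneous velocity at an
#' interior frame is the central difference of the cargo positions: a
#' one-sided difference at frame `t` shares the cargo's localization error
#' with the motor-cargo vector `l(t)` and that common term biases `d`
#' upward by roughly `2 sigma_loc^2 / (|v| dt)` (a few nanometres at
#' typical noise), whereas the central difference excludes the frame's own
#' error and is bias-free. The run's first and last frames use the only
#' available one-sided differences. Per-run averages are attached to the
#' run table.
#'
#' @param tracks colocalized track data frame (`track_id`, `frame`,
#'   `x_um`, `y_um`, `gx`, `gy`, `rx`, `ry`), ordered as passed to
#'   [segment_runs()].
#' @param runs run table from [segment_runs()] (carries `row_start`,
#'   `row_end`).
#' @param dt frame interval, seconds.
#' @param cargo_cols,motor_cols column names of the cargo and motor
#'   channel coordinates.
#' @return list with `samples` (data frame `run_id`, `track_id`, `frame`,
#'   `d_um`, `alpha_deg`, `l_um`) and `runs` (the input run table with
#'   `d_bar`, `alpha_bar`, `l_bar`, `n_geom` columns added). Frames with
#'   undefined velocity are skipped and counted in attribute `n_excluded`.
#' @export
run_geometry <- function(tracks, runs, dt = 0.1,
                         cargo_cols = c("gx", "gy"),
                         motor_cols = c("rx", "ry")) {
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  if (!all(cargo_cols %in% names(tracks)))
    cargo_cols <- c("x_um", "y_um")
  if (!all(motor_cols %in% names(tracks)))
    stop_config("run_geometry: motor coordinate columns %s missing - tracks must come from the colocalized pairing",
                paste(motor_cols, collapse = ","))
  n_excl <- 0L
  samples <- vector("list", nrow(runs))
  d_bar <- alpha_bar <- l_bar <- rep(NA_real_, nrow(runs))
  n_geom <- integer(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    rows <- runs$row_start[i]:runs$row_end[i]
    tr <- tracks[rows, ]
    np <- nrow(tr)
    cx <- tr[[cargo_cols[1]]]; cy <- tr[[cargo_cols[2]]]
    vx <- numeric(np); vy <- numeric(np)
    if (np >= 3L) {
      span <- (tr$frame[3:np] - tr$frame[1:(np - 2L)]) * dt
      vx[2:(np - 1L)] <- (cx[3:np] - cx[1:(np - 2L)]) / span
      vy[2:(np - 1L)] <- (cy[3:np] - cy[1:(np - 2L)]) / span
    }
    d1 <- (tr$frame[2] - tr$frame[1]) * dt
    dn <- (tr$frame[np] - tr$frame[np - 1L]) * dt
    vx[1] <- (cx[2] - cx[1]) / d1; vy[1] <- (cy[2] - cy[1]) / d1
    vx[np] <- (cx[np] - cx[np - 1L]) / dn
    vy[np] <- (cy[np] - cy[np - 1L]) / dn
    g <- projected_distance(cbind(cx, cy),
                            cbind(tr[[motor_cols[1]]], tr[[motor_cols[2]]]),
                            cbind(vx, vy))
    ok <- !is.na(g$d_um)
    n_excl <- n_excl + sum(!ok)
    g <- g[ok, ]
    if (nrow(g) == 0L) next
    samples[[i]] <- data.frame(run_id = runs$run_id[i],
                               track_id = runs$track_id[i],
                               frame = tr$frame[ok], g)
    d_bar[i] <- mean(g$d_um)
    alpha_bar[i] <- mean(g$alpha_deg, na.rm = TRUE)
    l_bar[i] <- mean(g$l_um)
    n_geom[i] <- nrow(g)
  }
  samples <- do.call(rbind, samples)
  if (is.null(samples))
    samples <- data.frame(run_id = integer(0), track_id = integer(0),
                          frame = integer(0), d_um = numeric(0),
                          alpha_deg = numeric(0), l_um = numeric(0))
  runs$d_bar <- d_bar; runs$alpha_bar <- alpha_bar
  runs$l_bar <- l_bar; runs$n_geom <- n_geom
  structure(list(samples = samples, runs = runs), n_excluded = n_excl)
}

#' Experiment-averaged histograms
#'
#' Builds a normalized frequency histogram per experiment group and then
#' averages bin-wise across experiments, reporting per-bin mean and SEM.
#'
#' @param values numeric vector of samples.
#' @param group experiment label per sample.
#' @param breaks bin edges (values outside are dropped).
#' @return data frame with `bin_mid`, `bin_lo`, `bin_hi`, `mean` and `sem`
#'   (NA with a single experiment); per-experiment frequencies in attribute
#'   `per_experiment`.
#' @export
aggregate_histograms <- function(values, group, breaks) {
  stopifnot(length(values) == length(group))
  keep <- values >= breaks[1] & values <= breaks[length(breaks)] &
    !is.na(values)
  values <- values[keep]; group <- group[keep]
  groups <- unique(group)
  freq <- sapply(groups, function(g) {
    h <- hist(values[group == g], breaks = breaks, plot = FALSE)
    if (sum(h$counts) == 0) rep(NA_real_, length(h$counts))
    else h$counts / sum(h$counts)
  })
  freq <- matrix(freq, ncol = length(groups),
                 dimnames = list(NULL, as.character(groups)))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- data.frame(bin_mid = mids,
                    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    mean = rowMeans(freq, na.rm = TRUE),
                    sem = if (length(groups) > 1L)
                      apply(freq, 1, sd, na.rm = TRUE) / sqrt(length(groups))
                    else NA_real_)
  attr(out, "per_experiment") <- freq
  out
}

#' Opposite-polarity run pairs within tracks
#'
#' Lists, per track, all run pairs whose average velocity vectors point in
#' nearly opposite directions (cosine below `cos_threshold`, default -0.6,
#' i.e. an angle above ~125 degrees) and whose run centres of mass are
#' closer than `max_com_sep`. Within each pair the run with the larger
#' average projected distance is labelled forward, the other backward. A
#' run may appear in several pairs.
#'
#' @param runs run table carrying `vx`, `vy`, `com_x`, `com_y`, `d_bar`
#'   (from [run_geometry()]).
#' @param cos_threshold opposite-polarity cosine threshold (strictly
#'   below).
#' @param max_com_sep maximum centre-of-mass separation, micrometres
#'   (strictly below).
#' @return data frame with `track_id`, `fwd_run_id`, `bwd_run_id`,
#'   `cosine`, `com_sep_um`.
#' @export
find_opposite_pairs <- function(runs, cos_threshold = -0.6,
                                max_com_sep = 1) {
  empty <- data.frame(track_id = integer(0), fwd_run_id = integer(0),
                      bwd_run_id = integer(0), cosine = numeric(0),
                      com_sep_um = numeric(0))
  if (nrow(runs) < 2L) return(empty)
  out <- list()
  for (tid in unique(runs$track_id)) {
    rr <- runs[runs$track_id == tid, ]
    if (nrow(rr) < 2L) next
    for (i in seq_len(nrow(rr) - 1L)) {
      for (j in (i + 1L):nrow(rr)) {
        vi <- c(rr$vx[i], rr$vy[i]); vj <- c(rr$vx[j], rr$vy[j])
        ni <- sqrt(sum(vi^2)); nj <- sqrt(sum(vj^2))
        if (ni == 0 || nj == 0) next
        cs <- sum(vi * vj) / (ni * nj)
        if (cs >= cos_threshold) next
        sep <- sqrt((rr$com_x[i] - rr$com_x[j])^2 +
                    (rr$com_y[i] - rr$com_y[j])^2)
        if (sep >= max_com_sep) next
        di <- rr$d_bar[i]; dj <- rr$d_bar[j]
        if (is.na(di) || is.na(dj)) next
        fwd <- if (di >= dj) i else j
        bwd <- if (di >= dj) j else i
        out[[length(out) + 1L]] <-
          data.frame(track_id = tid, fwd_run_id = rr$run_id[fwd],
                     bwd_run_id = rr$run_id[bwd], cosine = cs,
                     com_sep_um = sep)
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Forward/backward projected-displacement statistics
#'
#' Pools the instantaneous (per-frame) projected distances of all forward
#' runs and all backward runs of the opposite-polarity pairs and reports
#' mean and SEM per class, with pair and timepoint counts. Runs appearing
#' in several pairs contribute once per pair.
#'
#' @param pairs output of [find_opposite_pairs()].
#' @param samples per-timepoint geometry samples from [run_geometry()].
#' @return list with `forward` and `backward` (`mean_um`, `sem_um`,
#'   `n_points`), `n_pairs`, and the pooled sample vectors.
#' @export
forward_backward_stats <- function(pairs, samples) {
  pool <- function(ids) {
    v <- unlist(lapply(ids, function(id)
      samples$d_um[samples$run_id == id]))
    v %||% numeric(0)
  }
  fwd <- pool(pairs$fwd_run_id)
  bwd <- pool(pairs$bwd_run_id)
  summarize <- function(v) list(
    mean_um = if (length(v)) mean(v) else NA_real_,
    sem_um = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_,
    n_points = length(v))
  list(forward = summarize(fwd), backward = summarize(bwd),
       n_pairs = nrow(pairs), forward_d = fwd, backward_d = bwd)
}
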