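# Independent oracles used by the property tests. These recompute the
# quantities with naive enumeration, separate from the package's scanning
# or assignment code paths.

# Exhaustive maximal-window scan for directional segments: every window of
# positions [i, j] (j >= i + 2) whose interior consecutive-velocity cosines
# are all defined and strictly above `thr`, reduced to windows not contained
# in any larger valid window. Velocities and cosines are recomputed here
# with plain loops.
oracle_directional_segments <- function(track, dt, thr) {
  n <- nrow(track)
  if (n < 3L) return(list())
  vx <- vy <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    tdiff <- (track$frame[i + 1L] - track$frame[i]) * dt
    vx[i] <- (track$x_um[i + 1L] - track$x_um[i]) / tdiff
    vy[i] <- (track$y_um[i + 1L] - track$y_um[i]) / tdiff
  }
  cosv <- rep(NA_real_, n - 2L)
  for (i in seq_len(n - 2L)) {
    n1 <- sqrt(vx[i]^2 + vy[i]^2)
    n2 <- sqrt(vx[i + 1L]^2 + vy[i + 1L]^2)
    if (n1 > 0 && n2 > 0)
      cosv[i] <- (vx[i] * vx[i + 1L] + vy[i] * vy[i + 1L]) / (n1 * n2)
  }
  valid <- function(i, j) {
    ks <- i:(j - 2L)
    all(!is.na(cosv[ks]) & cosv[ks] > thr)
  }
  wins <- list()
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (valid(i, j)) wins[[length(wins) + 1L]] <- c(i, j)
    }
  }
  if (!length(wins)) return(list())
  keep <- vapply(seq_along(wins), function(a) {
    wa <- wins[[a]]
    !any(vapply(seq_along(wins), function(b) {
      if (a == b) return(FALSE)
      wb <- wins[[b]]
      wb[1] <= wa[1] && wb[2] >= wa[2]
    }, logical(1)))
  }, logical(1))
  wins[keep]
}

# Brute-force one-to-one matching: enumerate all assignments of rows of `a`
# to rows of `b` (or to nothing), maximize pair count then minimize total
# distance. Only usable for tiny inputs.
oracle_match <- function(a, b, threshold) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- nrow(a); nb <- nrow(b)
  best <- NULL; best_count <- -1L; best_total <- Inf
  assignments <- function(i, cur, used) {
    if (i > na) {
      pairs <- which(cur > 0L)
      count <- length(pairs)
      total <- sum(vapply(pairs, function(p)
        sqrt(sum((a[p, ] - b[cur[p], ])^2)), numeric(1)))
      if (count > best_count ||
          (count == best_count && total < best_total - 1e-12)) {
        best <<- cur; best_count <<- count; best_total <<- total
      }
      return(invisible())
    }
    assignments(i + 1L, cur, used)
    for (j in seq_len(nb)) {
      if (used[j]) next
      if (sqrt(sum((a[i, ] - b[j, ])^2)) > threshold) next
      cur[i] <- j; used[j] <- TRUE
      assignments(i + 1L, cur, used)
      cur[i] <- 0L; used[j] <- FALSE
    }
  }
  assignments(1L, integer(na), logical(nb))
  list(assign = best, count = best_count, total = best_total)
}

# Random jagged track for segmentation properties: uniform step directions.
random_walk_track <- function(n_frames, step_um = 0.13) {
  th <- runif(n_frames - 1L, 0, 2 * pi)
  data.frame(frame = 0:(n_frames - 1L),
             x_um = c(0, cumsum(step_um * cos(th))),
             y_um = c(0, cumsum(step_um * sin(th))))
}

# Straight constant-speed track.
straight_track <- function(n_frames, step_um = 0.13, dir = c(1, 0),
                           origin = c(0, 0)) {
  u <- dir / sqrt(sum(dir^2))
  data.frame(frame = 0:(n_frames - 1L),
             x_um = origin[1] + u[1] * step_um * (0:(n_frames - 1L)),
             y_um = origin[2] + u[2] * step_um * (0:(n_frames - 1L)))
}

run_bounds <- function(runs) {
  if (nrow(runs) == 0L) return(matrix(numeric(0), ncol = 2))
  m <- as.matrix(runs[, c("start_frame", "end_frame")])
  m[order(m[, 1]), , drop = FALSE]
}
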