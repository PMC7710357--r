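test_that("velocities are forward differences over true time", {
  tr <- data.frame(frame = 0:1, x_um = c(0, 0.1), y_um = 0)
  v <- compute_velocities(tr, dt = 0.1)
  expect_equal(c(v$vx, v$vy), c(1.0, 0), tolerance = 1e-12)

  # across a gap the actual time difference divides
  trg <- data.frame(frame = c(0, 1, 4), x_um = c(0, 0.1, 0.7), y_um = 0)
  vg <- compute_velocities(trg, dt = 0.1)
  expect_equal(vg$vx, c(1.0, 2.0), tolerance = 1e-12)

  stat <- data.frame(frame = 0:4, x_um = 1, y_um = 1)
  vs <- compute_velocities(stat, dt = 0.1)
  expect_true(all(vs$speed == 0))
  expect_true(all(is.na(vs$cos_prev[-1])))

  straight <- straight_track(10)
  vstr <- compute_velocities(straight, dt = 0.1)
  expect_equal(vstr$cos_prev[-1], rep(1, 8), tolerance = 1e-12)
})

test_that("straight tracks give one run; sharp turns split runs", {
  tr <- straight_track(30)
  runs <- segment_runs(tr, variant = "single_channel", dt = 0.1)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start_frame, 0L)
  expect_equal(runs$end_frame, 29L)

  # 90 degree turn at frame 15: cosine 0 at the turn
  turn <- data.frame(frame = 0:29,
                     x_um = c(seq(0, 1.95, by = 0.13), rep(1.95, 14)),
                     y_um = c(rep(0, 16), seq(0.13, 1.82, by = 0.13)))
  runs2 <- segment_runs(turn, variant = "single_channel", dt = 0.1)
  expect_equal(nrow(runs2), 2L)
  expect_equal(runs2$end_frame[1], 15L)
  expect_equal(runs2$start_frame[2], 15L)
})

test_that("pauses of more than three small steps split single-channel runs", {
  # straight fast track with 4 consecutive 0.06 um steps in the middle
  steps <- c(rep(0.13, 12), rep(0.06, 4), rep(0.13, 12))
  tr <- data.frame(frame = 0:length(steps),
                   x_um = c(0, cumsum(steps)), y_um = 0)
  runs <- segment_runs(tr, variant = "single_channel", dt = 0.1,
                       pixel_size = 0.063)
  expect_equal(nrow(runs), 2L)
  expect_equal(runs$end_frame[1], 12L)
  expect_equal(runs$start_frame[2], 16L)

  # 3 small steps only: no split
  steps3 <- c(rep(0.13, 12), rep(0.06, 3), rep(0.13, 12))
  tr3 <- data.frame(frame = 0:length(steps3),
                    x_um = c(0, cumsum(steps3)), y_um = 0)
  expect_equal(nrow(segment_runs(tr3, variant = "single_channel", dt = 0.1,
                                 pixel_size = 0.063)), 1L)
})

test_that("single-channel length filters follow the frame thresholds", {
  # track below 20 frames: no runs at all
  short <- straight_track(19)
  expect_equal(nrow(segment_runs(short, variant = "single_channel")), 0L)

  # run of exactly 7 positions passes; 6 does not
  mk <- function(n_straight) {
    th <- c(rep(0, n_straight - 1L), seq(pi / 2, by = 2.5, length.out = 24))
    data.frame(frame = 0:length(th),
               x_um = c(0, cumsum(0.13 * cos(th))),
               y_um = c(0, cumsum(0.13 * sin(th))))
  }
  r7 <- segment_runs(mk(7L), variant = "single_channel")
  expect_true(any(r7$n_points >= 7L))
  r6 <- segment_runs(mk(6L), variant = "single_channel")
  expect_true(all(r6$n_points >= 7L))
})

test_that("colocalized run filters enforce duration and displacement", {
  # 0.25 s straight run, 1 um displacement, in a long jiggling track
  set.seed(5)
  jig <- random_walk_track(20L, step_um = 0.02)
  fast <- data.frame(frame = 20:23,
                     x_um = jig$x_um[20] + c(0.34, 0.67, 1.0, 1.34),
                     y_um = jig$y_um[20])
  tr <- rbind(jig, fast)
  tr$frame <- 0:(nrow(tr) - 1L)
  runs <- segment_runs(tr, variant = "colocalized", dt = 0.1)
  expect_true(all(runs$duration_s > 0.3))

  long <- straight_track(12L)   # 1.1 s, 1.43 um
  rl <- segment_runs(long, variant = "colocalized", dt = 0.1)
  expect_equal(nrow(rl), 1L)
  # same geometry but small displacement: rejected
  slow <- straight_track(12L, step_um = 0.04)  # net 0.44 um < 0.5
  expect_equal(nrow(segment_runs(slow, variant = "colocalized", dt = 0.1)), 0L)
})

test_that("segmentation equals the exhaustive maximal-window oracle", {
  set.seed(90)
  for (i in 1:100) {
    tr <- random_walk_track(50L)
    got <- segment_runs(tr, variant = "colocalized", dt = 0.1,
                        min_duration_s = 0, min_displacement_um = 0)
    want <- oracle_directional_segments(tr, dt = 0.1, thr = 0.6)
    want_frames <- if (length(want))
      t(vapply(want, function(w) c(tr$frame[w[1]], tr$frame[w[2]]),
               numeric(2)))
    else matrix(numeric(0), ncol = 2)
    expect_equal(run_bounds(got), want_frames, ignore_attr = TRUE)
  }
})

test_that("raising the cosine threshold never extends run coverage", {
  set.seed(33)
  for (i in 1:20) {
    tr <- random_walk_track(60L)
    lo <- segment_runs(tr, variant = "colocalized", cos_threshold = 0.3,
                       min_duration_s = 0, min_displacement_um = 0)
    hi <- segment_runs(tr, variant = "colocalized", cos_threshold = 0.8,
                       min_duration_s = 0, min_displacement_um = 0)
    cover <- function(runs) sum(runs$end_frame - runs$start_frame)
    expect_lte(cover(hi), cover(lo))
    # every high-threshold run lies inside some low-threshold run
    if (nrow(hi)) {
      for (j in seq_len(nrow(hi))) {
        expect_true(any(lo$start_frame <= hi$start_frame[j] &
                          lo$end_frame >= hi$end_frame[j]))
      }
    }
  }
})

test_that("run boundaries track the true state transitions on clean data", {
  cfg <- simulation_config(n_vesicles = 10L, n_frames = 200L,
                           localization_noise_sd = 0, angular_noise_sd = 0.05,
                           diffusion_coefficient = 0,
                           p_reverse = 0, field_size = c(150, 150), seed = 2L)
  trs <- simulate_vesicle_tracks(cfg)
  hits <- 0L; total <- 0L
  for (tr in trs) {
    runs <- segment_runs(data.frame(frame = tr$frame, x_um = tr$x_um,
                                    y_um = tr$y_um),
                         variant = "colocalized", dt = cfg$dt)
    if (!nrow(runs)) next
    # true bout starts: diffusive -> processive transitions
    # state at frame t governs the displacement t -> t+1, so a bout over
    # state-frames [s, e] shows directional motion over positions [s, e+1]
    st <- tr$state == "processive"
    starts <- tr$frame[which(diff(c(FALSE, st)) == 1)]
    ends <- tr$frame[which(diff(c(st, FALSE)) == -1)] + 1L
    for (j in seq_len(nrow(runs))) {
      total <- total + 1L
      ok_start <- any(abs(starts - runs$start_frame[j]) <= 1)
      ok_end <- any(abs(ends - runs$end_frame[j]) <= 1)
      hits <- hits + as.integer(ok_start && ok_end)
    }
  }
  expect_gt(total, 10L)
  expect_gte(hits / total, 0.9)
})

test_that("run metrics agree with hand arithmetic", {
  tr <- straight_track(10)
  m <- run_metrics(tr, dt = 0.1)
  expect_equal(m$duration_s, 0.9, tolerance = 1e-12)
  expect_equal(m$length_um, 1.17, tolerance = 1e-12)
  expect_equal(m$speed_um_s, 1.3, tolerance = 1e-12)
  expect_equal(m$net_um, 1.17, tolerance = 1e-12)

  # zig-zag inside the cone: path length exceeds net displacement
  th <- rep(c(0.3, -0.3), 10)
  zig <- data.frame(frame = 0:20, x_um = c(0, cumsum(0.13 * cos(th))),
                    y_um = c(0, cumsum(0.13 * sin(th))))
  mz <- run_metrics(zig, dt = 0.1)
  expect_gt(mz$length_um, mz$net_um)

  # speed equals mean instantaneous speed for constant-speed runs
  v <- compute_velocities(zig, dt = 0.1)
  expect_equal(mz$speed_um_s, mean(v$speed), tolerance = 1e-12)
})

test_that("per-cell run fractions summarize correctly", {
  mk_track <- function(id, n, cell) {
    tr <- straight_track(n)
    tr$track_id <- id; tr$cell <- cell
    tr
  }
  # cell 1: 10 tracks, 2 with runs (straight 30) and 8 jiggling
  set.seed(51)
  tracks <- list()
  for (i in 1:2) tracks[[i]] <- mk_track(i, 30L, 1L)
  for (i in 3:10) {
    tr <- random_walk_track(30L, step_um = 0.02)
    tr$track_id <- i; tr$cell <- 1L
    tracks[[i]] <- tr
  }
  tracks <- do.call(rbind, tracks)
  runs <- segment_runs(tracks, variant = "colocalized", dt = 0.1)
  expect_setequal(unique(runs$track_id), 1:2)
  st <- run_fraction_stats(tracks, runs, dt = 0.1)
  expect_equal(st$per_cell$pct_tracks_with_runs, 20)
  # straight tracks are fully covered by their single run
  covered <- st$per_track$frac_processive[st$per_track$track_id %in% 1:2]
  expect_equal(covered, c(1, 1), tolerance = 1e-12)
})
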