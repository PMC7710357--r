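test_that("projected distance and angle follow the dot-product definition", {
  g <- projected_distance(cbind(0, 0), cbind(0.10, 0), cbind(1, 0))
  expect_equal(g$d_um, 0.10, tolerance = 1e-12)
  expect_equal(g$alpha_deg, 0, tolerance = 1e-9)

  g2 <- projected_distance(cbind(0, 0), cbind(0, 0.08), cbind(1, 0))
  expect_equal(g2$d_um, 0, tolerance = 1e-12)
  expect_equal(g2$alpha_deg, 90, tolerance = 1e-9)

  # 3-4-5 triangle: motor (-0.03, 0.04), v along +y
  g3 <- projected_distance(cbind(0, 0), cbind(-0.03, 0.04), cbind(0, 2))
  expect_equal(g3$d_um, 0.04, tolerance = 1e-12)
  expect_equal(g3$l_um, 0.05, tolerance = 1e-12)
  expect_equal(g3$alpha_deg, acos(0.04 / 0.05) * 180 / pi, tolerance = 1e-9)

  # zero velocity excluded
  g4 <- projected_distance(cbind(0, 0), cbind(0.1, 0), cbind(0, 0))
  expect_true(is.na(g4$d_um))
})

test_that("geometric identities hold on random samples", {
  set.seed(61)
  n <- 1e4
  cargo <- matrix(rnorm(2 * n), ncol = 2)
  motor <- cargo + matrix(rnorm(2 * n, 0, 0.1), ncol = 2)
  v <- matrix(rnorm(2 * n), ncol = 2)
  g <- projected_distance(cargo, motor, v)
  l <- motor - cargo
  # |d| <= |l| and d = |l| cos(alpha)
  expect_true(all(abs(g$d_um) <= g$l_um + 1e-12))
  expect_equal(g$d_um, g$l_um * cos(g$alpha_deg * pi / 180),
               tolerance = 1e-9)
  # Pythagoras: d^2 + perp^2 = |l|^2
  vn <- sqrt(rowSums(v^2))
  perp <- (v[, 1] * l[, 2] - v[, 2] * l[, 1]) / vn
  expect_equal(g$d_um^2 + perp^2, g$l_um^2, tolerance = 1e-9)
  # antisymmetry under velocity reversal
  gr <- projected_distance(cargo, motor, -v)
  expect_equal(gr$d_um, -g$d_um, tolerance = 1e-9)
  expect_equal(gr$alpha_deg, 180 - g$alpha_deg, tolerance = 1e-9)
})

make_coloc_track <- function(n, step = 0.13, motor_offset = c(0, 0),
                             frame0 = 0L, origin = c(0, 0), dir = c(1, 0)) {
  u <- dir / sqrt(sum(dir^2))
  idx <- 0:(n - 1L)
  gx <- origin[1] + u[1] * step * idx
  gy <- origin[2] + u[2] * step * idx
  data.frame(track_id = 1L, frame = frame0 + idx,
             x_um = gx, y_um = gy, gx = gx, gy = gy,
             rx = gx + motor_offset[1], ry = gy + motor_offset[2])
}

test_that("run geometry recovers constant offsets exactly", {
  tr <- make_coloc_track(12L, motor_offset = c(0.1, 0))
  runs <- segment_runs(tr, variant = "colocalized", dt = 0.1)
  geo <- run_geometry(tr, runs, dt = 0.1)
  expect_equal(geo$samples$d_um, rep(0.1, nrow(geo$samples)),
               tolerance = 1e-12)
  expect_equal(geo$runs$d_bar, 0.1, tolerance = 1e-12)

  perp <- make_coloc_track(12L, motor_offset = c(0, 0.08))
  runs2 <- segment_runs(perp, variant = "colocalized", dt = 0.1)
  geo2 <- run_geometry(perp, runs2, dt = 0.1)
  expect_equal(geo2$runs$d_bar, 0, tolerance = 1e-12)
  expect_equal(geo2$runs$alpha_bar, 90, tolerance = 1e-9)
})

test_that("isotropic motor jitter gives a symmetric d and uniform alpha", {
  # marker with no directional preference (PAUF-like null)
  cfg <- simulation_config(n_vesicles = 60L, n_frames = 300L,
                           motor_offset_mean = 0, motor_offset_sd = 0,
                           motor_lateral_sd = 0.05,
                           localization_noise_sd = 0.02,
                           field_size = c(150, 150), seed = 41L)
  trs <- simulate_vesicle_tracks(cfg)
  det <- attach_motor_channel(trs, aberration_identity(), cfg)
  paired <- pair_channels(det$green, det$red)
  linked <- link_tracks(paired, min_track_frames = 5L)
  runs <- segment_runs(linked, variant = "colocalized", dt = cfg$dt)
  geo <- run_geometry(linked, runs, dt = cfg$dt)
  d <- geo$samples$d_um
  expect_gt(length(d), 500L)
  se_med <- 1.2533 * sd(d) / sqrt(length(d))
  expect_lt(abs(median(d)), 4 * se_med)
  # alpha approximately uniform on [0, 180]
  a <- geo$samples$alpha_deg[!is.na(geo$samples$alpha_deg)]
  ks <- suppressWarnings(ks.test(a, "punif", 0, 180))
  expect_gt(ks$p.value, 0.001)
})

test_that("experiment-averaged histograms conserve normalization", {
  vals <- c(rnorm(100, 0), rnorm(100, 0))
  grp <- rep(c("a", "b"), each = 100)
  br <- seq(-4, 4, by = 0.5)
  h <- aggregate_histograms(vals, grp, br)
  expect_equal(sum(h$mean), 1, tolerance = 1e-12)

  # two identical experiments: SEM zero in every bin
  vals2 <- rep(c(-1, 0, 0, 1), 2)
  grp2 <- rep(c("a", "b"), each = 4)
  h2 <- aggregate_histograms(vals2, grp2, c(-2, -0.5, 0.5, 2))
  expect_equal(h2$sem, rep(0, 3), tolerance = 1e-12)

  # mean equals hand-computed per-bin average of per-experiment freqs
  va <- c(0.1, 0.1, 0.9); vb <- c(0.1, 0.9, 0.9, 0.9)
  h3 <- aggregate_histograms(c(va, vb), rep(c("a", "b"), c(3, 4)),
                             c(0, 0.5, 1))
  expect_equal(h3$mean, c(mean(c(2 / 3, 1 / 4)), mean(c(1 / 3, 3 / 4))),
               tolerance = 1e-12)

  # single experiment: SEM undefined
  h4 <- aggregate_histograms(va, rep("a", 3), c(0, 0.5, 1))
  expect_true(all(is.na(h4$sem)))
})

test_that("opposite-run pairing follows cosine, separation and d-ordering", {
  runs <- data.frame(run_id = 1:2, track_id = 1L,
                     vx = c(1, -0.9), vy = c(0, 0.1),
                     com_x = c(0, 0.5), com_y = c(0, 0),
                     d_bar = c(0.060, -0.010))
  p <- find_opposite_pairs(runs)
  expect_equal(nrow(p), 1L)
  expect_lt(p$cosine, -0.6)
  expect_equal(p$fwd_run_id, 1L)
  expect_equal(p$bwd_run_id, 2L)

  # orthogonal runs never pair
  runs2 <- data.frame(run_id = 1:2, track_id = 1L, vx = c(1, 0),
                      vy = c(0, 1), com_x = 0, com_y = 0,
                      d_bar = c(0.1, 0))
  expect_equal(nrow(find_opposite_pairs(runs2)), 0L)

  # far-apart centres of mass never pair
  runs3 <- runs
  runs3$com_x <- c(0, 1.5)
  expect_equal(nrow(find_opposite_pairs(runs3)), 0L)

  # A(+x), B(-x), C(+x): pairs (A,B) and (B,C) only
  runs4 <- data.frame(run_id = 1:3, track_id = 1L,
                      vx = c(1, -1, 1), vy = 0,
                      com_x = c(0, 0.3, 0.6), com_y = 0,
                      d_bar = c(0.06, -0.01, 0.05))
  p4 <- find_opposite_pairs(runs4)
  expect_equal(nrow(p4), 2L)
  expect_setequal(paste(p4$fwd_run_id, p4$bwd_run_id),
                  c("1 2", "3 2"))
})

test_that("forward/backward pooling matches hand arithmetic", {
  samples <- data.frame(run_id = c(1, 1, 1, 2, 2),
                        d_um = c(0.07, 0.08, 0.09, -0.02, -0.04))
  pairs <- data.frame(track_id = 1L, fwd_run_id = 1L, bwd_run_id = 2L,
                      cosine = -0.95, com_sep_um = 0.4)
  fb <- forward_backward_stats(pairs, samples)
  expect_equal(fb$forward$mean_um, 0.08, tolerance = 1e-12)
  expect_equal(fb$backward$mean_um, -0.03, tolerance = 1e-12)
  expect_equal(fb$forward$n_points, 3L)
  expect_equal(fb$backward$sem_um, sd(c(-0.02, -0.04)) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(fb$n_pairs, 1L)
})

test_that("simulated reversing vesicles recover class-specific offsets", {
  cfg <- simulation_config(n_vesicles = 60L, n_frames = 300L,
                           p_go = 0.05, p_stop = 0.05, p_reverse = 0.02,
                           motor_offset_mean = 0.070,
                           motor_offset_mean_backward = -0.030,
                           motor_offset_sd = 0.01, motor_lateral_sd = 0.01,
                           localization_noise_sd = 0.025,
                           field_size = c(200, 200), seed = 73L)
  trs <- simulate_vesicle_tracks(cfg)
  det <- attach_motor_channel(trs, aberration_identity(), cfg)
  paired <- pair_channels(det$green, det$red)
  linked <- link_tracks(paired, min_track_frames = 5L)
  runs <- segment_runs(linked, variant = "colocalized", dt = cfg$dt)
  geo <- run_geometry(linked, runs, dt = cfg$dt)
  pairs <- find_opposite_pairs(geo$runs)
  expect_gt(nrow(pairs), 10L)
  fb <- forward_backward_stats(pairs, geo$samples)
  expect_lt(abs(fb$forward$mean_um - 0.070), 3 * fb$forward$sem_um + 0.005)
  expect_lt(abs(fb$backward$mean_um + 0.030), 3 * fb$backward$sem_um + 0.005)
})
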