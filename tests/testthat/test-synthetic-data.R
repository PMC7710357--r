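test_that("degenerate Markov chain gives a perfectly straight track", {
  cfg <- simulation_config(n_vesicles = 1L, n_frames = 40L,
                           p_go = 1, p_stop = 0, p_reverse = 0,
                           angular_noise_sd = 0,
                           speed_components = data.frame(weight = 1,
                                                         mean = 1.3, sd = 0),
                           diffusion_coefficient = 0,
                           motor_offset_sd = 0, motor_lateral_sd = 0,
                           localization_noise_sd = 0,
                           field_size = c(500, 500), seed = 3L)
  tr <- simulate_vesicle_tracks(cfg)[[1]]
  expect_true(all(tr$state == "processive"))
  steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  expect_equal(steps, rep(1.3 * cfg$dt, 39L), tolerance = 1e-12)
  # straight: all displacement vectors parallel
  dx <- diff(tr$x_um); dy <- diff(tr$y_um)
  expect_equal(max(abs(dx[1] * dy - dy[1] * dx)), 0, tolerance = 1e-12)
})

test_that("noise-free geometry puts the motor exactly offset_mean ahead", {
  cfg <- simulation_config(n_vesicles = 3L, n_frames = 60L,
                           p_go = 1, p_stop = 0,
                           diffusion_coefficient = 0,
                           motor_offset_mean = 0.08, motor_offset_sd = 0,
                           motor_lateral_sd = 0, localization_noise_sd = 0,
                           field_size = c(500, 500), seed = 11L)
  trs <- simulate_vesicle_tracks(cfg)
  for (tr in trs) {
    pro <- tr$state == "processive" & sqrt(tr$vx^2 + tr$vy^2) > 0
    un <- cbind(tr$vx, tr$vy)[pro, ] / sqrt(tr$vx^2 + tr$vy^2)[pro]
    proj <- (tr$mx_um[pro] - tr$x_um[pro]) * un[, 1] +
      (tr$my_um[pro] - tr$y_um[pro]) * un[, 2]
    expect_equal(proj, rep(0.08, sum(pro)), tolerance = 1e-10)
  }
})

test_that("processive occupancy matches the stationary distribution", {
  cfg <- simulation_config(n_vesicles = 100L, n_frames = 500L, seed = 5L,
                           field_size = c(200, 200))
  trs <- simulate_vesicle_tracks(cfg)
  states <- unlist(lapply(trs, `[[`, "state"))
  frac <- mean(states == "processive")
  p_stat <- cfg$p_go / (cfg$p_go + cfg$p_stop)
  # frames within a vesicle are autocorrelated; SE from effective n of
  # independent bouts (~ n * (p_go + p_stop) switch opportunities)
  n_eff <- cfg$n_vesicles * cfg$n_frames * (cfg$p_go + cfg$p_stop) / 2
  se <- sqrt(p_stat * (1 - p_stat) / n_eff)
  expect_lt(abs(frac - p_stat), 3 * se)
})

test_that("identical seeds give bit-identical simulations and detections", {
  cfg <- simulation_config(n_vesicles = 5L, n_frames = 50L, seed = 42L)
  a <- simulate_vesicle_tracks(cfg)
  b <- simulate_vesicle_tracks(cfg)
  expect_identical(a, b)
  da <- attach_motor_channel(a, aberration_identity(), cfg)
  db <- attach_motor_channel(b, aberration_identity(), cfg)
  expect_identical(da, db)
})

test_that("detection tables respect the aberration and noise model", {
  cfg <- simulation_config(n_vesicles = 4L, n_frames = 30L,
                           localization_noise_sd = 0, seed = 8L)
  trs <- simulate_vesicle_tracks(cfg)
  det <- attach_motor_channel(trs, aberration_identity(), cfg)
  expect_equal(det$red$x_um, det$truth$mx_um, tolerance = 1e-12)
  expect_equal(det$green$y_um, det$truth$y_um, tolerance = 1e-12)

  shift <- aberration_affine(translation = c(0.05, 0))
  det2 <- attach_motor_channel(trs, shift, cfg)
  expect_equal(det2$red$x_um - det2$truth$mx_um,
               rep(0.05, nrow(det2$red)), tolerance = 1e-12)
  expect_equal(det2$red$y_um, det2$truth$my_um, tolerance = 1e-12)

  # Monte-Carlo check of the localization noise scale
  cfg3 <- simulation_config(n_vesicles = 25L, n_frames = 500L,
                            localization_noise_sd = 0.025, seed = 9L,
                            field_size = c(200, 200))
  trs3 <- simulate_vesicle_tracks(cfg3)
  det3 <- attach_motor_channel(trs3, aberration_identity(), cfg3)
  dev2 <- (det3$green$x_um - det3$truth$x_um)^2 +
    (det3$green$y_um - det3$truth$y_um)^2
  rms <- sqrt(mean(dev2))   # two axes: expect 0.025 * sqrt(2)
  expect_equal(rms, 0.025 * sqrt(2), tolerance = 0.02)
})

test_that("calibration grids have the expected geometry", {
  g <- make_calibration_grid(spacing = 2, field_size = c(33, 33))
  expect_equal(nrow(g$green), 17L * 17L)
  expect_equal(g$red, g$green)

  expect_error(make_calibration_grid(spacing = 0.8, feature_size = 0.5),
               "feature size")

  ab <- aberration_affine(scale = 1.002, center = c(16, 16))
  g2 <- make_calibration_grid(spacing = 2, field_size = c(32, 32),
                              aberration = ab)
  disp <- sqrt((g2$red$x_um - g2$green$x_um)^2 +
               (g2$red$y_um - g2$green$y_um)^2)
  r <- sqrt((g2$green$x_um - 16)^2 + (g2$green$y_um - 16)^2)
  expect_equal(disp, 0.002 * r, tolerance = 1e-9)
  expect_equal(which.max(disp), which.max(r))
})

test_that("mixture speed sampling is seeded and matches closed form", {
  one <- sample_mixture_speeds(data.frame(weight = 1, mean = 1, sd = 0),
                               n = 20L, seed = 1L)
  expect_equal(one, rep(1, 20L))
  a <- sample_mixture_speeds(data.frame(weight = c(.5, .5),
                                        mean = c(1.2, 1.71),
                                        sd = c(.26, .49)), 1000L, seed = 4L)
  b <- sample_mixture_speeds(data.frame(weight = c(.5, .5),
                                        mean = c(1.2, 1.71),
                                        sd = c(.26, .49)), 1000L, seed = 4L)
  expect_identical(a, b)
  expect_true(all(a > 0))

  comps <- data.frame(weight = c(.5, .5), mean = c(1.2, 1.71),
                      sd = c(.26, .49))
  x <- sample_mixture_speeds(comps, 1e5, seed = 2L)
  # truncation-corrected component means for rejection sampling at 0
  tmean <- function(m, s) m + s * dnorm(-m / s) / (1 - pnorm(-m / s))
  p_pos <- 1 - pnorm(-comps$mean / comps$sd)
  mu <- sum(comps$weight * p_pos * tmean(comps$mean, comps$sd)) /
    sum(comps$weight * p_pos)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
  expect_error(sample_mixture_speeds(data.frame(weight = numeric(0),
                                                mean = numeric(0),
                                                sd = numeric(0)), 10L),
               "empty")
})

test_that("rendered spots integrate to the photon scale", {
  blank <- render_image_stack(data.frame(frame = 0L, x_um = 1, y_um = 1),
                              photon_scale = 0, background = 100,
                              field_size = c(2, 2), poisson_noise = FALSE)
  expect_true(all(blank[[1]] == 100L))

  one <- render_image_stack(data.frame(frame = 0L, x_um = 1.0, y_um = 1.0),
                            pixel_size = 0.065, field_size = c(2, 2),
                            psf_sigma = 1.3, photon_scale = 5e4,
                            background = 0, poisson_noise = FALSE)
  expect_equal(sum(one[[1]]), 5e4, tolerance = 1e-3)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(p_go = 1.4), "probability")
  expect_error(simulation_config(motor_offset_sd = -1), "non-negative")
  expect_error(simulation_config(
    speed_components = data.frame(weight = c(.6, .6),
                                  mean = c(1, 2), sd = c(.1, .1))),
    "sum to 1")
  expect_error(simulation_config(dt = 0), "positive")
})
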