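## Synthetic-data generator. Emulates TIRF movies of secretory vesicles
## that alternate between diffusive "jiggling" and processive, motor-driven
## directional motion, with a second channel reporting the motor position
## offset along the instantaneous velocity. All coordinates are micrometres;
## acquisition defaults follow the imaging conditions the analysis targets:
## 0.065 um/pixel and 0.1 s per frame over 500-frame movies.

#' Simulation configuration
#'
#' Builds and validates the parameter set for the vesicle-transport
#' simulator. Motion is a two-state Markov chain: in the diffusive state the
#' vesicle performs Brownian jiggling with diffusion coefficient
#' `diffusion_coefficient`; in the processive state it moves with a speed
#' drawn once per bout from the Gaussian mixture `speed_components`, its
#' direction following a fixed per-vesicle track axis up to Gaussian jitter,
#' with rare 180-degree reversals (`p_reverse`). The motor channel sits at
#' cargo + offset * unit(velocity) + lateral jitter, where the signed
#' along-velocity offset is drawn per frame from
#' N(`motor_offset_mean`, `motor_offset_sd`) during forward-polarity motion
#' and from N(`motor_offset_mean_backward`, `motor_offset_sd`) after a
#' reversal (defaults to the forward mean). Both channels carry isotropic
#' localization noise when detections are emitted.
#'
#' @param n_vesicles number of vesicles.
#' @param n_frames frames per movie.
#' @param dt frame interval, seconds.
#' @param pixel_size micrometres per pixel (used for rendering and for
#'   pixel-denominated thresholds only).
#' @param field_size length-2 field of view, micrometres.
#' @param p_go per-frame probability of a diffusive-to-processive switch.
#' @param p_stop per-frame probability of a processive-to-diffusive switch.
#' @param speed_components data frame with columns `weight`, `mean`, `sd`
#'   (micrometres/second) describing the per-bout speed mixture.
#' @param diffusion_coefficient diffusive-state D, um^2/s.
#' @param angular_noise_sd per-frame direction jitter about the vesicle's
#'   track axis, radians (non-accumulating; the default 0.05 rad keeps
#'   processive runs nearly straight, as expected for transport guided
#'   along microtubules).
#' @param p_reverse per-frame probability of a 180-degree reversal during
#'   processive motion.
#' @param motor_offset_mean,motor_offset_sd signed along-velocity motor
#'   offset distribution, micrometres.
#' @param motor_offset_mean_backward offset mean used after a reversal
#'   (backward-polarity bouts); `NULL` reuses `motor_offset_mean`.
#' @param motor_lateral_sd lateral (perpendicular) motor jitter, micrometres.
#' @param localization_noise_sd per-axis, per-channel localization noise,
#'   micrometres.
#' @param seed integer RNG seed; identical configurations give identical
#'   output.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_vesicles = 50L,
                              n_frames = 500L,
                              dt = 0.1,
                              pixel_size = 0.065,
                              field_size = c(60, 60),
                              p_go = 0.03,
                              p_stop = 0.08,
                              speed_components = data.frame(
                                weight = c(0.5, 0.5),
                                mean = c(1.20, 1.71),
                                sd = c(0.26, 0.49)),
                              diffusion_coefficient = 0.01,
                              angular_noise_sd = 0.05,
                              p_reverse = 0,
                              motor_offset_mean = 0,
                              motor_offset_sd = 0.03,
                              motor_offset_mean_backward = NULL,
                              motor_lateral_sd = 0.03,
                              localization_noise_sd = 0.025,
                              seed = 1L) {
  check_pos(n_vesicles, "n_vesicles"); check_pos(n_frames, "n_frames")
  check_pos(dt, "dt"); check_pos(pixel_size, "pixel_size")
  if (length(field_size) != 2L || any(field_size <= 0))
    stop_config("configuration error: 'field_size' must be two positive lengths")
  check_prob(p_go, "p_go"); check_prob(p_stop, "p_stop")
  check_prob(p_reverse, "p_reverse")
  check_nonneg(diffusion_coefficient, "diffusion_coefficient")
  check_nonneg(angular_noise_sd, "angular_noise_sd")
  check_nonneg(motor_offset_sd, "motor_offset_sd")
  check_nonneg(motor_lateral_sd, "motor_lateral_sd")
  check_nonneg(localization_noise_sd, "localization_noise_sd")
  sc <- as.data.frame(speed_components)
  if (!all(c("weight", "mean", "sd") %in% names(sc)) || nrow(sc) == 0L)
    stop_config("configuration error: 'speed_components' needs columns weight, mean, sd")
  if (any(sc$sd < 0) || any(sc$weight < 0))
    stop_config("configuration error: speed component weights and sds must be >= 0")
  if (abs(sum(sc$weight) - 1) > 1e-8)
    stop_config("configuration error: speed component weights must sum to 1")
  cfg <- list(n_vesicles = as.integer(n_vesicles),
              n_frames = as.integer(n_frames),
              dt = dt, pixel_size = pixel_size,
              field_size = as.numeric(field_size),
              p_go = p_go, p_stop = p_stop,
              speed_components = sc,
              diffusion_coefficient = diffusion_coefficient,
              angular_noise_sd = angular_noise_sd,
              p_reverse = p_reverse,
              motor_offset_mean = motor_offset_mean,
              motor_offset_sd = motor_offset_sd,
              motor_offset_mean_backward = motor_offset_mean_backward %||% motor_offset_mean,
              motor_lateral_sd = motor_lateral_sd,
              localization_noise_sd = localization_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>", x$n_vesicles, "vesicles x", x$n_frames,
      "frames, dt", x$dt, "s, field",
      paste(x$field_size, collapse = " x "), "um\n")
  cat("  p_go", x$p_go, "p_stop", x$p_stop,
      "(stationary processive fraction",
      signif(x$p_go / (x$p_go + x$p_stop), 3), ")\n")
  cat("  motor offset", x$motor_offset_mean * 1000, "+/-",
      x$motor_offset_sd * 1000, "nm; localization noise",
      x$localization_noise_sd * 1000, "nm/channel\n")
  invisible(x)
}

#' Simulate ground-truthed vesicle tracks
#'
#' Runs the two-state motion model of [simulation_config()] and returns one
#' data frame per vesicle with the true cargo and motor positions. The
#' initial state is drawn from the stationary distribution of the Markov
#' chain, `p_go / (p_go + p_stop)` processive. Reversals negate the
#' direction vector, flip the vesicle's polarity flag and (if configured)
#' switch the ground-truth motor offset mean. Reflecting boundaries keep
#' vesicles inside the field of view.
#'
#' @param config a `simulation_config`.
#' @return list of data frames (one per vesicle), each with columns
#'   `frame` (0-based), `state` ("diffusive"/"processive"), `polarity`
#'   ("forward"/"backward"), `x_um`, `y_um` (cargo), `mx_um`, `my_um`
#'   (motor), `offset_um` (signed along-velocity offset), `vx`, `vy`
#'   (true velocity, um/s), `speed` (bout speed). The configuration is
#'   attached as attribute `config`.
#' @export
simulate_vesicle_tracks <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  lapply(seq_len(config$n_vesicles), function(id)
    simulate_one_track(id, config))
}

simulate_one_track <- function(id, cfg) {
  n <- cfg$n_frames
  fx <- cfg$field_size[1]; fy <- cfg$field_size[2]
  p_stat <- if (cfg$p_go + cfg$p_stop > 0) cfg$p_go / (cfg$p_go + cfg$p_stop) else 0
  state <- character(n); pol <- character(n)
  x <- numeric(n); y <- numeric(n); mx <- numeric(n); my <- numeric(n)
  vx <- numeric(n); vy <- numeric(n); off <- numeric(n); spd <- numeric(n)

  ## spawn away from the field walls: the imaged region of a cell excludes
  ## its borders, and wall reflections would reverse motion without a
  ## corresponding motor-state change
  mx_margin <- min(0.15 * fx, fx / 2)
  my_margin <- min(0.15 * fy, fy / 2)
  x[1] <- runif(1, mx_margin, fx - mx_margin)
  y[1] <- runif(1, my_margin, fy - my_margin)
  s <- if (runif(1) < p_stat) "processive" else "diffusive"
  ## processive motion is guided along one (locally straight) cytoskeletal
  ## track per vesicle: a fixed axis, travelled in the "forward" or
  ## (after a reversal) "backward" direction, with non-accumulating
  ## per-frame angular jitter about the axis. This keeps opposite-polarity
  ## runs of one trajectory retracing the same path, as they do on a
  ## microtubule, instead of letting the direction random-walk.
  phi <- runif(1, 0, 2 * pi)
  axis_sign <- 1
  polarity <- "forward"
  u <- c(cos(phi), sin(phi))
  bout_speed <- draw_bout_speed(cfg)
  sd_diff <- sqrt(2 * cfg$diffusion_coefficient * cfg$dt)

  for (t in seq_len(n)) {
    if (s == "processive") {
      if (cfg$p_reverse > 0 && runif(1) < cfg$p_reverse) {
        axis_sign <- -axis_sign
        polarity <- if (polarity == "forward") "backward" else "forward"
      }
      dth <- if (cfg$angular_noise_sd > 0)
        rnorm(1, 0, cfg$angular_noise_sd) else 0
      u <- axis_sign * c(cos(phi + dth), sin(phi + dth))
      v <- bout_speed * u
    } else {
      v <- c(0, 0)
    }
    state[t] <- s; pol[t] <- polarity
    om <- if (polarity == "forward") cfg$motor_offset_mean else cfg$motor_offset_mean_backward
    off[t] <- rnorm(1, om, cfg$motor_offset_sd)
    lat <- if (cfg$motor_lateral_sd > 0) rnorm(2, 0, cfg$motor_lateral_sd) else c(0, 0)
    mx[t] <- x[t] + off[t] * u[1] + lat[1]
    my[t] <- y[t] + off[t] * u[2] + lat[2]
    vx[t] <- v[1]; vy[t] <- v[2]; spd[t] <- if (s == "processive") bout_speed else 0

    if (t < n) {
      if (s == "processive") {
        nx <- x[t] + v[1] * cfg$dt
        ny <- y[t] + v[2] * cfg$dt
        ## a processive wall hit is treated as a full reversal event (the
        ## vesicle turns back at the cell edge): direction negates and the
        ## polarity state flips, keeping ground-truth motor labels
        ## consistent with the actual motion direction
        if (nx < 0 || nx > fx || ny < 0 || ny > fy) {
          nx <- x[t]; ny <- y[t]
          axis_sign <- -axis_sign
          u <- -u
          polarity <- if (polarity == "forward") "backward" else "forward"
        }
      } else {
        nx <- x[t] + rnorm(1, 0, sd_diff)
        ny <- y[t] + rnorm(1, 0, sd_diff)
        ## diffusive steps mirror off the walls; the stored processive
        ## direction is untouched
        if (nx < 0) nx <- -nx
        if (nx > fx) nx <- 2 * fx - nx
        if (ny < 0) ny <- -ny
        if (ny > fy) ny <- 2 * fy - ny
      }
      x[t + 1] <- nx; y[t + 1] <- ny
      ## state switch for the next frame
      if (s == "processive") {
        if (runif(1) < cfg$p_stop) s <- "diffusive"
      } else {
        if (runif(1) < cfg$p_go) {
          s <- "processive"
          bout_speed <- draw_bout_speed(cfg)   # redrawn at each new bout
        }
      }
    }
  }
  data.frame(vesicle_id = id, frame = 0:(n - 1L), state = state,
             polarity = pol, x_um = x, y_um = y, mx_um = mx, my_um = my,
             offset_um = off, vx = vx, vy = vy, speed = spd)
}

## one positive speed from the mixture (negative draws rejected)
draw_bout_speed <- function(cfg) {
  sc <- cfg$speed_components
  repeat {
    k <- sample.int(nrow(sc), 1L, prob = sc$weight)
    s <- rnorm(1, sc$mean[k], sc$sd[k])
    if (s > 0) return(s)
  }
}

#' Emit two-channel detection tables from ground-truth tracks
#'
#' Converts simulated tracks into the per-frame detection tables the
#' localization-free pipeline consumes: the green channel holds
#' noise-corrupted cargo positions, the red channel holds motor positions
#' passed through the chromatic aberration model and corrupted by the same
#' localization noise. Truth linkage is retained in a separate table.
#'
#' @param tracks output of [simulate_vesicle_tracks()].
#' @param aberration an `aberration` applied to red-channel coordinates.
#' @param config the `simulation_config` used to simulate.
#' @return list with data frames `green`, `red` (columns `frame`, `channel`,
#'   `x_um`, `y_um`, `intensity`, plus `vesicle_id` for truth linkage) and
#'   `truth` (frame, vesicle_id, state, cargo/motor truth, offset).
#' @export
attach_motor_channel <- function(tracks, aberration = aberration_identity(),
                                 config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  truth <- do.call(rbind, tracks)
  n <- nrow(truth)
  sdl <- config$localization_noise_sd
  gx <- truth$x_um + rnorm(n, 0, sdl)
  gy <- truth$y_um + rnorm(n, 0, sdl)
  red_true <- apply_aberration(aberration, cbind(truth$mx_um, truth$my_um))
  rx <- red_true[, 1] + rnorm(n, 0, sdl)
  ry <- red_true[, 2] + rnorm(n, 0, sdl)
  green <- data.frame(frame = truth$frame, channel = "green",
                      x_um = gx, y_um = gy,
                      intensity = 1000, vesicle_id = truth$vesicle_id)
  red <- data.frame(frame = truth$frame, channel = "red",
                    x_um = rx, y_um = ry,
                    intensity = 1000, vesicle_id = truth$vesicle_id)
  o <- order(green$frame, green$vesicle_id)
  truth_tab <- truth[o, c("frame", "vesicle_id", "state", "polarity",
                          "x_um", "y_um", "mx_um", "my_um", "offset_um")]
  rownames(truth_tab) <- NULL
  list(green = green[o, ], red = red[o, ], truth = truth_tab)
}

#' Calibration grid for channel registration
#'
#' Generates paired green/red detection tables emulating bright-field images
#' of a calibration photomask: round features on a regular square grid
#' (default 2 um spacing), imaged in both channels, with the red channel
#' displaced by the chromatic aberration. Optional isotropic jitter models
#' feature-localization error.
#'
#' @param spacing grid pitch, micrometres.
#' @param field_size length-2 field, micrometres.
#' @param aberration an `aberration` for the red channel.
#' @param jitter per-axis localization jitter sd, micrometres.
#' @param feature_size feature diameter, micrometres (spacing must exceed
#'   twice this).
#' @param seed RNG seed for the jitter.
#' @return list of data frames `green` and `red` with `x_um`, `y_um`.
#' @export
make_calibration_grid <- function(spacing = 2, field_size = c(33, 33),
                                  aberration = aberration_identity(),
                                  jitter = 0, feature_size = 0.5,
                                  seed = 1L) {
  check_pos(spacing, "spacing")
  if (spacing < 2 * feature_size)
    stop_config("spacing %.3g um is below twice the feature size (%.3g um)",
                spacing, feature_size)
  set.seed(seed)
  xs <- seq(0, field_size[1], by = spacing)
  ys <- seq(0, field_size[2], by = spacing)
  g <- expand.grid(x_um = xs, y_um = ys)
  attr(g, "out.attrs") <- NULL
  n <- nrow(g)
  if (jitter > 0) {
    g$x_um <- g$x_um + rnorm(n, 0, jitter)
    g$y_um <- g$y_um + rnorm(n, 0, jitter)
  }
  r <- apply_aberration(aberration, as.matrix(g))
  red <- data.frame(x_um = r[, 1], y_um = r[, 2])
  if (jitter > 0) {
    red$x_um <- red$x_um + rnorm(n, 0, jitter)
    red$y_um <- red$y_um + rnorm(n, 0, jitter)
  }
  list(green = g, red = red)
}

#' Sample run speeds from a Gaussian mixture
#'
#' Draws positive speeds from a mixture of Gaussian components; negative
#' draws are rejected and redrawn (speeds are positive by construction).
#'
#' @param components data frame with columns `weight`, `mean`, `sd`.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return numeric vector of length `n`.
#' @export
sample_mixture_speeds <- function(components, n, seed = 1L) {
  sc <- as.data.frame(components)
  if (nrow(sc) == 0L)
    stop_config("configuration error: empty speed component list")
  if (abs(sum(sc$weight) - 1) > 1e-8)
    stop_config("configuration error: mixture weights must sum to 1")
  set.seed(seed)
  comp <- sample.int(nrow(sc), n, replace = TRUE, prob = sc$weight)
  out <- rnorm(n, sc$mean[comp], sc$sd[comp])
  bad <- which(out <= 0)
  while (length(bad)) {
    comp2 <- sample.int(nrow(sc), length(bad), replace = TRUE, prob = sc$weight)
    out[bad] <- rnorm(length(bad), sc$mean[comp2], sc$sd[comp2])
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Render detections as a synthetic image stack
#'
#' Draws each detection as an integrated 2D Gaussian point-spread function
#' on a 16-bit pixel grid, adds a constant background and (optionally)
#' Poisson shot noise. Pixel `(r, c)` covers `[c-1, c] x [r-1, r]` in pixel
#' units so a spot at pixel coordinate `x_px` has its centre `x_px` pixels
#' from the left edge.
#'
#' @param detections data frame with `frame`, `x_um`, `y_um` and optionally
#'   `intensity` (photon scale multiplier, default 1).
#' @param pixel_size micrometres per pixel.
#' @param field_size field of view in micrometres (sets image dimensions).
#' @param psf_sigma PSF sigma in pixels.
#' @param photon_scale expected photons per unit intensity.
#' @param background constant background level (counts).
#' @param poisson_noise add Poisson noise?
#' @param seed RNG seed for the noise.
#' @return list of integer matrices (one per frame, row = y), class
#'   `image_stack`; attributes `pixel_size`, `frames` (0-based frame ids).
#' @export
render_image_stack <- function(detections, pixel_size = 0.065,
                               field_size = c(33, 33), psf_sigma = 1.3,
                               photon_scale = 5000, background = 100,
                               poisson_noise = TRUE, seed = 1L) {
  set.seed(seed)
  nx <- ceiling(field_size[1] / pixel_size)
  ny <- ceiling(field_size[2] / pixel_size)
  if (is.null(detections$frame)) detections$frame <- 0L
  if (is.null(detections$intensity)) detections$intensity <- 1
  frames <- sort(unique(detections$frame))
  inside <- detections$x_um >= 0 & detections$x_um <= field_size[1] &
    detections$y_um >= 0 & detections$y_um <= field_size[2]
  if (any(!inside)) {
    warning(sprintf("%d detections outside the field were clipped",
                    sum(!inside)))
    detections <- detections[inside, ]
  }
  half <- ceiling(5 * psf_sigma)
  stack <- lapply(frames, function(f) {
    img <- matrix(background, nrow = ny, ncol = nx)
    sel <- detections[detections$frame == f, ]
    for (i in seq_len(nrow(sel))) {
      xpx <- sel$x_um[i] / pixel_size
      ypx <- sel$y_um[i] / pixel_size
      c0 <- max(1L, floor(xpx) - half); c1 <- min(nx, ceiling(xpx) + half)
      r0 <- max(1L, floor(ypx) - half); r1 <- min(ny, ceiling(ypx) + half)
      if (c0 > c1 || r0 > r1) next
      cx <- pnorm(c0:c1, xpx, psf_sigma) - pnorm((c0:c1) - 1, xpx, psf_sigma)
      cy <- pnorm(r0:r1, ypx, psf_sigma) - pnorm((r0:r1) - 1, ypx, psf_sigma)
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
        photon_scale * sel$intensity[i] * outer(cy, cx)
    }
    if (poisson_noise) img <- matrix(rpois(length(img), img), nrow = ny)
    img <- round(img)
    img[img > 65535] <- 65535
    storage.mode(img) <- "integer"
    img
  })
  structure(stack, pixel_size = pixel_size, frames = frames,
            class = "image_stack")
}

#' Write an image stack as multi-page 16-bit TIFF
#'
#' @param stack an `image_stack` (list of integer matrices).
#' @param path output file.
#' @export
write_tiff_stack <- function(stack, path) {
  pages <- lapply(stack, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file.
#' @param pixel_size micrometres per pixel to attach to the stack.
#' @return an `image_stack`.
#' @export
read_tiff_stack <- function(path, pixel_size = 0.065) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- lapply(pages, function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "integer"
    m
  })
  structure(stack, pixel_size = pixel_size,
            frames = seq_along(stack) - 1L, class = "image_stack")
}
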