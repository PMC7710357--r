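## Sub-pixel spot localization and two-channel chromatic registration.
## Detection: candidate local maxima above an SD-based threshold, refined by
## least-squares 2D Gaussian fits. Registration: mutual-nearest-neighbour
## correspondence on a calibration grid, a least-squares affine map from red
## to green coordinates, and an optional smooth (thin-plate) residual field.

#' Sub-pixel spot detection by 2D Gaussian fitting
#'
#' Finds candidate spots as local intensity maxima more than
#' `intensity_threshold` robust standard deviations above the frame
#' background (median/MAD), then refines each candidate with a least-squares
#' 2D Gaussian fit (amplitude, centre, sigma, offset) in a square window.
#' Non-converged fits and fits that wander out of their window are
#' discarded. Detections closer than `2 * sigma` are merged keeping the
#' brighter fit.
#'
#' @param stack an `image_stack` (list of matrices) or a single matrix.
#' @param intensity_threshold detection threshold in robust SDs above
#'   background.
#' @param fit_window full width of the square fit window, pixels (odd).
#' @param pixel_size micrometres per pixel (taken from the stack attribute
#'   when present).
#' @param psf_sigma_start starting sigma for the fits, pixels.
#' @return data frame with `frame` (0-based), `x_um`, `y_um`, `x_px`,
#'   `y_px`, `intensity` (integrated flux), `amplitude`, `fit_sigma`,
#'   `background`.
#' @export
detect_spots <- function(stack, intensity_threshold = 5, fit_window = 11L,
                         pixel_size = NULL, psf_sigma_start = 1.3) {
  if (is.matrix(stack)) stack <- structure(list(stack), frames = 0L)
  pixel_size <- pixel_size %||% attr(stack, "pixel_size") %||% 0.065
  check_pos(intensity_threshold, "intensity_threshold")
  frames <- attr(stack, "frames") %||% (seq_along(stack) - 1L)
  out <- lapply(seq_along(stack), function(i) {
    d <- detect_spots_frame(stack[[i]], intensity_threshold, fit_window,
                            psf_sigma_start)
    if (nrow(d)) d$frame <- frames[i]
    d
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), amplitude = numeric(0),
                      fit_sigma = numeric(0), background = numeric(0)))
  }
  out$x_um <- out$x_px * pixel_size
  out$y_um <- out$y_px * pixel_size
  out[, c("frame", "x_um", "y_um", "x_px", "y_px", "intensity",
          "amplitude", "fit_sigma", "background")]
}

detect_spots_frame <- function(img, thr, fit_window, sigma0) {
  img <- img * 1.0
  bg <- median(img)
  s <- mad(img)
  if (s == 0) s <- sd(img)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), amplitude = numeric(0),
                      fit_sigma = numeric(0), background = numeric(0))
  if (s == 0) return(empty)
  cut <- bg + thr * s
  nr <- nrow(img); nc <- ncol(img)
  cand <- which(img > cut, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nr & cand[, 2] > 1 & cand[, 2] < nc, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- img[(r - 1):(r + 1), (c - 1):(c + 1)]
    img[r, c] >= max(nb)
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  half <- fit_window %/% 2L
  fits <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    r0 <- max(1L, r - half); r1 <- min(nr, r + half)
    c0 <- max(1L, c - half); c1 <- min(nc, c + half)
    win <- img[r0:r1, c0:c1]
    fit_gaussian_spot(win, c0, r0, sigma0, bg)
  })
  fits <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  if (is.null(fits) || nrow(fits) == 0L) return(empty)
  fits <- as.data.frame(fits)
  ## merge detections closer than 2 sigma, keeping the brighter fit
  if (nrow(fits) > 1L) {
    fits <- fits[order(-fits$amplitude), ]
    kept <- rep(TRUE, nrow(fits))
    for (i in seq_len(nrow(fits) - 1L)) {
      if (!kept[i]) next
      j <- (i + 1L):nrow(fits)
      dd <- sqrt((fits$x_px[j] - fits$x_px[i])^2 +
                 (fits$y_px[j] - fits$y_px[i])^2)
      kept[j[dd < 2 * fits$fit_sigma[i]]] <- FALSE
    }
    fits <- fits[kept, ]
  }
  rownames(fits) <- NULL
  fits
}

## least-squares integrated-Gaussian fit in one window; returns NULL on
## failure. Window pixel (row i, col j) corresponds to absolute pixel
## (r0+i-1, c0+j-1); centres are at (col - 0.5, row - 0.5).
fit_gaussian_spot <- function(win, c0, r0, sigma0, bg) {
  nr <- nrow(win); nc <- ncol(win)
  cols <- c0 + seq_len(nc) - 1L
  rows <- r0 + seq_len(nr) - 1L
  z <- as.vector(win)
  df <- data.frame(x = rep(cols - 0.5, each = nr),
                   y = rep(rows - 0.5, times = nc), z = z)
  ## centroid start from background-subtracted weights
  w <- pmax(z - bg, 0)
  if (sum(w) == 0) return(NULL)
  x0 <- sum(df$x * w) / sum(w)
  y0 <- sum(df$y * w) / sum(w)
  a0 <- max(z) - bg
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((x - mx)^2 + (y - my)^2) / (2 * s^2)),
      data = df,
      start = list(b = bg, A = a0, mx = x0, my = y0, s = sigma0),
      lower = c(b = -Inf, A = 0, mx = min(cols) - 1, my = min(rows) - 1,
                s = 0.3),
      upper = c(b = Inf, A = Inf, mx = max(cols) + 1, my = max(rows) + 1,
                s = max(nr, nc)),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- coef(fit)
  if (p[["A"]] <= 0) return(NULL)
  if (p[["mx"]] < min(cols) - 1 || p[["mx"]] > max(cols) ||
      p[["my"]] < min(rows) - 1 || p[["my"]] > max(rows)) return(NULL)
  c(x_px = p[["mx"]], y_px = p[["my"]],
    intensity = 2 * pi * p[["A"]] * p[["s"]]^2,
    amplitude = p[["A"]], fit_sigma = p[["s"]], background = p[["b"]])
}

#' Fit a channel registration model from calibration detections
#'
#' Establishes mutual-nearest-neighbour correspondences between green and
#' red calibration detections, fits a least-squares affine map taking red
#' coordinates into the green frame, and optionally fits a smooth thin-plate
#' residual displacement field on top of the affine part. The green channel
#' is never transformed; correction direction is red into green.
#'
#' @param green,red data frames with `x_um`, `y_um` calibration detections.
#' @param match_threshold maximum correspondence distance, micrometres.
#' @param residual fit a smooth residual field after the affine part?
#' @param k basis dimension of the thin-plate smooth (per axis).
#' @return object of class `registration_model` with elements `affine`
#'   (2x3 matrix), `points` (matched red points and post-affine residuals),
#'   `rms_um` (post-fit RMS residual), `bbox` (calibration bounding box) and
#'   the residual smoothers when requested.
#' @export
fit_registration <- function(green, red, match_threshold = 1,
                             residual = TRUE, k = 27L) {
  g <- as.matrix(green[, c("x_um", "y_um")])
  r <- as.matrix(red[, c("x_um", "y_um")])
  pairs <- mutual_nearest(g, r, match_threshold)
  if (nrow(pairs) < 3L)
    stop_config("registration needs at least 3 matched features, got %d",
                nrow(pairs))
  gm <- g[pairs[, 1], , drop = FALSE]
  rm_ <- r[pairs[, 2], , drop = FALSE]
  X <- cbind(1, rm_)
  beta <- solve(crossprod(X), crossprod(X, gm))   # 3 x 2
  affine <- t(beta)                               # 2 x 3: (b | A)
  pred <- X %*% beta
  res <- gm - pred
  model <- list(affine = affine,
                points = data.frame(rx = rm_[, 1], ry = rm_[, 2],
                                    res_x = res[, 1], res_y = res[, 2]),
                bbox = c(xmin = min(rm_[, 1]), xmax = max(rm_[, 1]),
                         ymin = min(rm_[, 2]), ymax = max(rm_[, 2])),
                residual = FALSE, k = as.integer(k))
  if (residual && nrow(pairs) >= k + 3L) {
    model$residual <- TRUE
    model$gam_x <- mgcv::gam(res_x ~ s(rx, ry, k = k), data = model$points)
    model$gam_y <- mgcv::gam(res_y ~ s(rx, ry, k = k), data = model$points)
    fx <- fitted(model$gam_x); fy <- fitted(model$gam_y)
    res <- cbind(res[, 1] - fx, res[, 2] - fy)
  }
  model$rms_um <- sqrt(mean(res^2) * 2)   # radial RMS (both axes)
  model$n_points <- nrow(pairs)
  class(model) <- "registration_model"
  model
}

mutual_nearest <- function(a, b, threshold) {
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  nn_ab <- apply(d, 1, which.min)
  nn_ba <- apply(d, 2, which.min)
  ii <- which(nn_ba[nn_ab] == seq_len(nrow(a)))
  ii <- ii[d[cbind(ii, nn_ab[ii])] <= threshold]
  cbind(a = ii, b = nn_ab[ii])
}

#' @export
print.registration_model <- function(x, ...) {
  cat("<registration_model>", x$n_points, "matched features, RMS residual",
      signif(x$rms_um * 1000, 4), "nm\n")
  cat("  affine (red -> green):\n")
  print(signif(x$affine, 6))
  cat("  smooth residual field:", if (x$residual) "yes" else "no", "\n")
  invisible(x)
}

#' Apply a registration model to red-channel detections
#'
#' Maps red coordinates into the green frame using the fitted affine map
#' plus (inside the calibration region) the smooth residual field. Points
#' outside the calibration bounding box (with a half-micron margin) get the
#' affine correction only.
#'
#' @param model a `registration_model`.
#' @param detections data frame with `x_um`, `y_um` (other columns kept).
#' @return the detections with corrected coordinates.
#' @export
apply_registration <- function(model, detections) {
  stopifnot(inherits(model, "registration_model"))
  xy <- as.matrix(detections[, c("x_um", "y_um")])
  A <- model$affine[, 2:3]; b <- model$affine[, 1]
  out <- xy %*% t(A)
  out[, 1] <- out[, 1] + b[1]
  out[, 2] <- out[, 2] + b[2]
  if (isTRUE(model$residual) && nrow(xy)) {
    margin <- 0.5
    inside <- xy[, 1] >= model$bbox["xmin"] - margin &
      xy[, 1] <= model$bbox["xmax"] + margin &
      xy[, 2] >= model$bbox["ymin"] - margin &
      xy[, 2] <= model$bbox["ymax"] + margin
    if (any(inside)) {
      nd <- data.frame(rx = xy[inside, 1], ry = xy[inside, 2])
      out[inside, 1] <- out[inside, 1] +
        as.numeric(predict(model$gam_x, newdata = nd))
      out[inside, 2] <- out[inside, 2] +
        as.numeric(predict(model$gam_y, newdata = nd))
    }
  }
  detections$x_um <- out[, 1]
  detections$y_um <- out[, 2]
  detections
}

#' Serialize / restore a registration model
#'
#' The model is stored as JSON holding the affine matrix and the matched
#' control points; the smooth residual field is refitted on load.
#'
#' @param model a `registration_model`.
#' @param path JSON file path.
#' @export
write_registration <- function(model, path) {
  obj <- list(affine = model$affine, points = model$points,
              residual = model$residual, k = model$k,
              bbox = as.list(model$bbox), rms_um = model$rms_um,
              n_points = model$n_points)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_registration
#' @export
read_registration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(affine = matrix(unlist(obj$affine), nrow = 2),
                points = as.data.frame(obj$points),
                bbox = unlist(obj$bbox), residual = isTRUE(obj$residual),
                k = as.integer(obj$k), rms_um = obj$rms_um,
                n_points = obj$n_points)
  names(model$bbox) <- c("xmin", "xmax", "ymin", "ymax")
  if (model$residual) {
    model$gam_x <- mgcv::gam(res_x ~ s(rx, ry, k = model$k),
                             data = model$points)
    model$gam_y <- mgcv::gam(res_y ~ s(rx, ry, k = model$k),
                             data = model$points)
  }
  class(model) <- "registration_model"
  model
}
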