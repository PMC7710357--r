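## Chromatic-aberration models. An aberration maps true ("green"-frame)
## coordinates to the coordinates observed in the red channel. The
## registration stage estimates and inverts this mapping.

#' Chromatic aberration models
#'
#' Constructors for the displacement field applied to the red (motor)
#' channel of simulated data. `aberration_identity()` is a no-op;
#' `aberration_affine()` builds an affine map from scale, rotation and
#' translation about a centre; `aberration_smooth()` adds a smooth,
#' low-frequency sinusoidal residual field on top of an affine part,
#' emulating the non-linear component of objective chromatic aberration.
#'
#' @param scale isotropic scale factor (or length-2 per-axis vector).
#' @param rotation_deg rotation in degrees about `center`.
#' @param translation length-2 translation in micrometres.
#' @param center length-2 centre of scaling/rotation in micrometres.
#' @param affine an affine aberration to which the residual is added.
#' @param amplitude peak residual displacement in micrometres.
#' @param wavelength spatial period of the residual field in micrometres.
#' @return an object of class `aberration`.
#' @export
aberration_identity <- function() {
  structure(list(type = "identity"), class = "aberration")
}

#' @rdname aberration_identity
#' @export
aberration_affine <- function(scale = 1, rotation_deg = 0,
                              translation = c(0, 0), center = c(0, 0)) {
  scale <- rep_len(scale, 2L)
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  A <- R %*% diag(scale, 2L)
  ## x' = A (x - c) + c + t
  b <- center - A %*% center + translation
  structure(list(type = "affine", A = A, b = as.numeric(b)),
            class = "aberration")
}

#' @rdname aberration_identity
#' @export
aberration_smooth <- function(affine = aberration_affine(),
                              amplitude = 0.05, wavelength = 20) {
  stopifnot(inherits(affine, "aberration"), affine$type %in% c("identity", "affine"))
  check_nonneg(amplitude, "amplitude")
  check_pos(wavelength, "wavelength")
  out <- list(type = "smooth",
              A = affine$A %||% diag(2), b = affine$b %||% c(0, 0),
              amplitude = amplitude, wavelength = wavelength)
  structure(out, class = "aberration")
}

#' Apply an aberration to coordinates
#'
#' @param ab an `aberration` object.
#' @param xy two-column matrix or data frame of (x, y) micrometre positions.
#' @return matrix of transformed positions.
#' @export
apply_aberration <- function(ab, xy) {
  stopifnot(inherits(ab, "aberration"))
  xy <- as.matrix(xy)
  if (ab$type == "identity") return(xy)
  out <- xy %*% t(ab$A)
  out[, 1] <- out[, 1] + ab$b[1]
  out[, 2] <- out[, 2] + ab$b[2]
  if (ab$type == "smooth") {
    w <- 2 * pi / ab$wavelength
    out[, 1] <- out[, 1] + ab$amplitude * sin(w * xy[, 2])
    out[, 2] <- out[, 2] + ab$amplitude * sin(w * xy[, 1])
  }
  out
}

#' @export
print.aberration <- function(x, ...) {
  cat("<aberration:", x$type, ">\n")
  if (!is.null(x$A)) {
    cat("  affine A = [", paste(signif(t(x$A), 6), collapse = ", "),
        "], b = (", paste(signif(x$b, 6), collapse = ", "), ") um\n")
  }
  if (x$type == "smooth")
    cat("  residual amplitude", x$amplitude, "um, wavelength",
        x$wavelength, "um\n")
  invisible(x)
}
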