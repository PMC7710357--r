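## Aperture photometry for motor copy-number estimation and FRAP traces.
## Spot intensity is the mean in a circular aperture (default 7 px
## diameter) minus the mean in an equal-sized background aperture placed
## just next to the spot. Pixel membership uses centre-of-pixel inclusion
## by default; sub-pixel area weighting is available.

#' Background-corrected spot intensity
#'
#' Measures the mean intensity in a circular aperture centred on a spot and
#' subtracts the mean of an equal-sized background aperture offset by one
#' aperture diameter. The background position is chosen among 8 candidate
#' directions to stay inside the image and away from other spots.
#'
#' @param image numeric matrix (row = y).
#' @param center length-2 spot centre in pixel coordinates (x, y).
#' @param diameter_px aperture diameter in pixels.
#' @param other_spots optional two-column matrix of other spot centres to
#'   avoid when placing the background aperture.
#' @param weighting `"center"` (centre-of-pixel membership, default) or
#'   `"area"` (sub-pixel area weights from a 4x4 subdivision).
#' @return list with `raw_mean`, `background_mean`, `corrected`,
#'   `n_pixels`, `background_center` and `flagged` (TRUE when no valid
#'   background position existed and the least-bad one was used).
#' @export
spot_intensity <- function(image, center, diameter_px = 7,
                           other_spots = NULL,
                           weighting = c("center", "area")) {
  weighting <- match.arg(weighting)
  r <- diameter_px / 2
  ap <- aperture_mean(image, center, r, weighting)
  if (is.null(ap))
    stop_config("aperture at (%.1f, %.1f) does not fit inside the image",
                center[1], center[2])
  dirs <- cbind(c(1, -1, 0, 0, 1, 1, -1, -1), c(0, 0, 1, -1, 1, -1, 1, -1))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  best <- NULL; flagged <- TRUE
  for (i in seq_len(nrow(dirs))) {
    bc <- center + dirs[i, ] * diameter_px
    bg <- aperture_mean(image, bc, r, weighting)
    if (is.null(bg)) next
    clash <- FALSE
    if (!is.null(other_spots) && nrow(other_spots)) {
      dd <- sqrt((other_spots[, 1] - bc[1])^2 + (other_spots[, 2] - bc[2])^2)
      clash <- any(dd < diameter_px)
    }
    if (is.null(best)) best <- list(bg = bg, bc = bc)
    if (!clash) { best <- list(bg = bg, bc = bc); flagged <- FALSE; break }
  }
  if (is.null(best))
    stop_config("no background aperture fits next to (%.1f, %.1f)",
                center[1], center[2])
  list(raw_mean = ap$mean, background_mean = best$bg$mean,
       corrected = ap$mean - best$bg$mean, n_pixels = ap$n,
       background_center = best$bc, flagged = flagged)
}

## mean over a circular aperture; NULL if it does not fit in the image.
## pixel (row, col) has centre (col - 0.5, row - 0.5) in (x, y).
aperture_mean <- function(image, center, radius, weighting) {
  nr <- nrow(image); nc <- ncol(image)
  if (center[1] - radius < 0 || center[1] + radius > nc ||
      center[2] - radius < 0 || center[2] + radius > nr) return(NULL)
  c0 <- max(1L, floor(center[1] - radius)); c1 <- min(nc, ceiling(center[1] + radius))
  r0 <- max(1L, floor(center[2] - radius)); r1 <- min(nr, ceiling(center[2] + radius))
  cols <- c0:c1; rows <- r0:r1
  cx <- rep(cols - 0.5, each = length(rows))
  cy <- rep(rows - 0.5, times = length(cols))
  vals <- as.vector(image[rows, cols])
  if (weighting == "center") {
    inside <- (cx - center[1])^2 + (cy - center[2])^2 <= radius^2
    if (!any(inside)) return(NULL)
    list(mean = mean(vals[inside]), n = sum(inside))
  } else {
    sub <- seq(-0.375, 0.375, by = 0.25)
    w <- numeric(length(vals))
    for (ox in sub) for (oy in sub)
      w <- w + (((cx + ox) - center[1])^2 + ((cy + oy) - center[2])^2 <= radius^2)
    w <- w / length(sub)^2
    if (sum(w) == 0) return(NULL)
    list(mean = sum(vals * w) / sum(w), n = sum(w))
  }
}

#' Motor copy-number estimates from a single-motor standard
#'
#' Expresses background-corrected spot intensities in units of the mean of
#' a single-motor reference distribution, yielding a continuous and a
#' rounded copy-number estimate per spot.
#'
#' @param intensities corrected spot intensities.
#' @param reference corrected intensities of the single-motor standard.
#' @return data frame with `intensity`, `copies` (continuous) and
#'   `copies_rounded`; the unit intensity is attached as attribute `unit`.
#' @export
estimate_copy_number <- function(intensities, reference) {
  if (!length(reference))
    stop_config("empty reference distribution")
  unit <- mean(reference)
  if (!is.finite(unit) || unit <= 0)
    stop_config("reference distribution has non-positive mean intensity")
  out <- data.frame(intensity = intensities,
                    copies = intensities / unit,
                    copies_rounded = round(intensities / unit))
  attr(out, "unit") <- unit
  out
}

#' Normalize a FRAP trace
#'
#' Subtracts a background trace, then divides by the mean of the 10 time
#' points preceding the bleach frame. A zero pre-bleach mean (background
#' equal to signal) yields an all-NA trace flagged in the result.
#'
#' @param raw raw intensity trace.
#' @param background background trace (same length) or a scalar.
#' @param bleach_frame 1-based index of the first post-bleach time point.
#' @param n_prebleach number of pre-bleach points to average (default 10).
#' @return list with `normalized`, `prebleach_mean`, `bleach_frame` and
#'   `flagged`.
#' @export
frap_normalize <- function(raw, background, bleach_frame,
                           n_prebleach = 10L) {
  if (length(background) == 1L) background <- rep(background, length(raw))
  stopifnot(length(background) == length(raw))
  if (bleach_frame <= n_prebleach)
    stop_config("FRAP normalization requires at least %d pre-bleach time points, got %d",
                n_prebleach, bleach_frame - 1L)
  corrected <- raw - background
  pre <- corrected[(bleach_frame - n_prebleach):(bleach_frame - 1L)]
  m <- mean(pre)
  if (!is.finite(m) || m == 0) {
    return(list(normalized = rep(NA_real_, length(raw)),
                prebleach_mean = m, bleach_frame = bleach_frame,
                flagged = TRUE))
  }
  list(normalized = corrected / m, prebleach_mean = m,
       bleach_frame = bleach_frame, flagged = FALSE)
}

#' Average normalized FRAP traces over vesicles
#'
#' @param traces list of normalized traces (equal length).
#' @return data frame with `time_index`, `mean`, `sem`, `n`.
#' @export
average_frap_traces <- function(traces) {
  stopifnot(length(traces) >= 1L)
  mat <- do.call(cbind, traces)
  data.frame(time_index = seq_len(nrow(mat)),
             mean = rowMeans(mat, na.rm = TRUE),
             sem = apply(mat, 1, function(v) {
               v <- v[!is.na(v)]
               if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
             }),
             n = apply(mat, 1, function(v) sum(!is.na(v))))
}
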