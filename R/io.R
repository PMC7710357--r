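## Plain-text interchange formats. Detection tables, tracks, runs and
## geometry samples are CSV; configurations and fit reports are JSON or
## YAML. Frames are written 0-based; distances in the geometry CSV are
## nanometres to match how projected distances are usually reported.

#' Read / write detection tables
#'
#' Detection CSVs have the header `frame,channel,x_um,y_um,intensity`
#' (frames 0-based integers). Auxiliary columns such as the simulator's
#' `vesicle_id` truth linkage are dropped on write.
#'
#' @param detections detection data frame.
#' @param path CSV file path.
#' @export
write_detections <- function(detections, path) {
  cols <- intersect(c("frame", "channel", "x_um", "y_um", "intensity"),
                    names(detections))
  utils::write.csv(detections[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  utils::read.csv(path)
}

#' Write colocalized or single-channel tracks
#'
#' Track CSVs carry `track_id,frame,x_um,y_um` plus, for colocalized
#' tracks, the per-channel originals `gx,gy,rx,ry` and `pair_dist`.
#'
#' @param tracks track data frame.
#' @param path CSV file path.
#' @export
write_tracks <- function(tracks, path) {
  cols <- intersect(c("track_id", "frame", "x_um", "y_um",
                      "gx", "gy", "rx", "ry", "pair_dist"), names(tracks))
  utils::write.csv(tracks[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  utils::read.csv(path)
}

#' Write a run table
#'
#' @param runs run table from [segment_runs()].
#' @param path CSV file path.
#' @export
write_runs <- function(runs, path) {
  cols <- intersect(c("run_id", "track_id", "start_frame", "end_frame",
                      "duration_s", "length_um", "net_um", "speed_um_s",
                      "vx", "vy", "com_x", "com_y", "d_bar", "alpha_bar",
                      "l_bar"), names(runs))
  utils::write.csv(runs[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write per-timepoint geometry samples (distances in nm)
#'
#' @param samples geometry samples from [run_geometry()].
#' @param path CSV file path.
#' @export
write_geometry <- function(samples, path) {
  out <- data.frame(run_id = samples$run_id, frame = samples$frame,
                    d_nm = samples$d_um * 1000,
                    alpha_deg = samples$alpha_deg,
                    abs_l_nm = samples$l_um * 1000)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write opposite-polarity run pairs
#'
#' @param pairs pair table from [find_opposite_pairs()].
#' @param path CSV file path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return a named list of configuration values.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
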