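## End-to-end orchestration: simulate -> (optionally render + localize +
## register) -> pair -> link -> segment -> geometry -> reversals ->
## speed statistics. Defaults are the thresholds the analysis was designed
## around: cosine 0.6, pairing 0.52 um (8 px), linking 0.65 um (10 px),
## 5 gap frames, colocalized run filters 0.3 s and 0.5 um, 0.065 um/px,
## 0.1 s per frame.

#' Pipeline configuration
#'
#' Assembles the full parameter set of [run_pipeline()]: a
#' [simulation_config()] for the synthetic input, the chromatic aberration
#' applied to the red channel, the stage list and all stage thresholds.
#'
#' @param simulation a `simulation_config`.
#' @param aberration aberration applied to the simulated red channel.
#' @param stages character vector of stages to run, in order, from
#'   `"simulate"`, `"register"`, `"pair"`, `"link"`, `"segment"`,
#'   `"geometry"`, `"reversals"`, `"speedfit"`. Later stages require their
#'   upstream stages to be present.
#' @param pairing_threshold,link_threshold micrometre thresholds.
#' @param max_gap_frames gap-closing limit.
#' @param link_min_frames minimum detections per colocalized track.
#' @param cos_threshold run-segmentation cosine threshold.
#' @param min_duration_s,min_displacement_um colocalized run filters.
#' @param segment_channel coordinates driving segmentation (see
#'   [segment_runs()]).
#' @param bin_width speed-histogram bin width, um/s.
#' @param out_dir optional output directory for CSV/JSON reports.
#' @param seed master seed; overrides the simulation seed so one integer
#'   reproduces the whole analysis.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            aberration = aberration_identity(),
                            stages = c("simulate", "pair", "link", "segment",
                                       "geometry", "reversals", "speedfit"),
                            pairing_threshold = 0.52,
                            link_threshold = 0.65,
                            max_gap_frames = 5L,
                            link_min_frames = 5L,
                            cos_threshold = 0.6,
                            min_duration_s = 0.3,
                            min_displacement_um = 0.5,
                            segment_channel = "cargo",
                            bin_width = 0.1,
                            out_dir = NULL,
                            seed = NULL) {
  known <- c("simulate", "register", "pair", "link", "segment", "geometry",
             "reversals", "speedfit")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop_config("unknown pipeline stage(s): %s", paste(bad, collapse = ", "))
  if (!is.null(seed)) {
    simulation$seed <- as.integer(seed)
  }
  cfg <- list(simulation = simulation, aberration = aberration,
              stages = stages,
              pairing_threshold = pairing_threshold,
              link_threshold = link_threshold,
              max_gap_frames = as.integer(max_gap_frames),
              link_min_frames = as.integer(link_min_frames),
              cos_threshold = cos_threshold,
              min_duration_s = min_duration_s,
              min_displacement_um = min_displacement_um,
              segment_channel = segment_channel,
              bin_width = bin_width,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

require_stage <- function(cfg, stage, needed) {
  missing <- setdiff(needed, cfg$stages)
  if (length(missing))
    stop_config("stage '%s' requires stage(s) %s to be enabled",
                stage, paste(sQuote(missing), collapse = ", "))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order and returns a report with
#' per-stage counts and the headline statistics: detection/pair/track/run
#' counts, the median instantaneous projected distance, forward/backward
#' means from the opposite-run analysis and the speed-mixture parameters.
#' The result is a pure function of the configuration (and its seed).
#'
#' @param config a `pipeline_config`.
#' @return a list of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rep <- list(config = config, counts = list(), stats = list())

  deps <- list(pair = "simulate", link = "pair", segment = c("pair", "link"),
               geometry = c("pair", "link", "segment"),
               reversals = c("pair", "link", "segment", "geometry"),
               speedfit = c("pair", "link", "segment"))
  for (st in intersect(names(deps), config$stages))
    require_stage(config, st, deps[[st]])

  require_stage(config, "pipeline", "simulate")
  tracks <- simulate_vesicle_tracks(config$simulation)
  det <- attach_motor_channel(tracks, config$aberration, config$simulation)
  rep$counts$detections_green <- nrow(det$green)
  rep$counts$detections_red <- nrow(det$red)

  red <- det$red
  if ("register" %in% config$stages) {
    grid <- make_calibration_grid(
      spacing = 2, field_size = config$simulation$field_size,
      aberration = config$aberration, jitter = 0.005,
      seed = config$simulation$seed + 2L)
    regmod <- fit_registration(grid$green, grid$red)
    red <- apply_registration(regmod, red)
    rep$stats$registration_rms_nm <- regmod$rms_um * 1000
    rep$registration <- regmod
  }

  if (!"pair" %in% config$stages) return(finish_report(rep))
  paired <- pair_channels(det$green, red, threshold = config$pairing_threshold)
  rep$counts$pairs <- nrow(paired)

  if (!"link" %in% config$stages) return(finish_report(rep))
  require_stage(config, "link", "pair")
  linked <- link_tracks(paired, threshold = config$link_threshold,
                        max_gap_frames = config$max_gap_frames,
                        min_track_frames = config$link_min_frames)
  rep$counts$tracks <- length(unique(linked$track_id))
  rep$tracks <- linked

  if (!"segment" %in% config$stages) return(finish_report(rep))
  require_stage(config, "segment", c("pair", "link"))
  runs <- segment_runs(linked, variant = "colocalized",
                       dt = config$simulation$dt,
                       cos_threshold = config$cos_threshold,
                       min_duration_s = config$min_duration_s,
                       min_displacement_um = config$min_displacement_um,
                       pixel_size = config$simulation$pixel_size,
                       segment_channel = config$segment_channel)
  rep$counts$runs <- nrow(runs)

  if ("geometry" %in% config$stages) {
    require_stage(config, "geometry", c("pair", "link", "segment"))
    geo <- run_geometry(linked, runs, dt = config$simulation$dt)
    runs <- geo$runs
    rep$samples <- geo$samples
    rep$counts$geometry_timepoints <- nrow(geo$samples)
    rep$stats$median_d_nm <- 1000 * median(geo$samples$d_um)
    rep$stats$median_d_run_avg_nm <- 1000 * median(runs$d_bar, na.rm = TRUE)
    rep$stats$median_alpha_deg <- median(geo$samples$alpha_deg, na.rm = TRUE)
  }
  rep$runs <- runs

  if ("reversals" %in% config$stages) {
    require_stage(config, "reversals", c("pair", "link", "segment", "geometry"))
    pairs <- find_opposite_pairs(runs)
    rep$counts$opposite_pairs <- nrow(pairs)
    if (nrow(pairs)) {
      fb <- forward_backward_stats(pairs, rep$samples)
      rep$stats$forward_mean_nm <- 1000 * fb$forward$mean_um
      rep$stats$forward_sem_nm <- 1000 * fb$forward$sem_um
      rep$stats$backward_mean_nm <- 1000 * fb$backward$mean_um
      rep$stats$backward_sem_nm <- 1000 * fb$backward$sem_um
      rep$reversals <- fb
    }
    rep$opposite_pairs <- pairs
  }

  if ("speedfit" %in% config$stages) {
    require_stage(config, "speedfit", c("pair", "link", "segment"))
    speeds <- runs$speed_um_s
    if (length(speeds) >= 50L) {
      f1 <- fit_speed_mixture(speeds, k = 1L, bin_width = config$bin_width)
      f2 <- fit_speed_mixture(speeds, k = 2L, bin_width = config$bin_width)
      cmp <- extra_ss_ftest(f1, f2)
      rep$stats$mixture_means <- f2$means
      rep$stats$mixture_sds <- f2$sds
      rep$stats$mixture_weights <- f2$weights
      rep$stats$f_test_p <- cmp$p
      rep$stats$preferred_k <- cmp$preferred
      rep$speed_fit <- list(k1 = f1, k2 = f2, comparison = cmp)
    }
  }
  finish_report(rep)
}

finish_report <- function(rep) {
  class(rep) <- "pipeline_report"
  if (!is.null(rep$config$out_dir)) write_report(rep, rep$config$out_dir)
  rep
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n counts:\n")
  for (nm in names(x$counts))
    cat(sprintf("   %-22s %d\n", nm, x$counts[[nm]]))
  if (length(x$stats)) {
    cat(" stats:\n")
    for (nm in names(x$stats)) {
      v <- x$stats[[nm]]
      cat(sprintf("   %-22s %s\n", nm,
                  paste(signif(v, 4), collapse = ", ")))
    }
  }
  invisible(x)
}

write_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(rep$tracks))
    write_tracks(rep$tracks, file.path(out_dir, "tracks.csv"))
  if (!is.null(rep$runs))
    write_runs(rep$runs, file.path(out_dir, "runs.csv"))
  if (!is.null(rep$samples))
    write_geometry(rep$samples, file.path(out_dir, "geometry.csv"))
  if (!is.null(rep$opposite_pairs))
    write_pairs(rep$opposite_pairs, file.path(out_dir, "opposite_pairs.csv"))
  summary <- list(counts = rep$counts, stats = rep$stats,
                  parameters = report_parameters(rep$config))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

report_parameters <- function(cfg) {
  sim <- unclass(cfg$simulation)
  sim$speed_components <- as.list(sim$speed_components)
  list(stages = cfg$stages,
       pairing_threshold_um = cfg$pairing_threshold,
       link_threshold_um = cfg$link_threshold,
       max_gap_frames = cfg$max_gap_frames,
       link_min_frames = cfg$link_min_frames,
       cos_threshold = cfg$cos_threshold,
       min_duration_s = cfg$min_duration_s,
       min_displacement_um = cfg$min_displacement_um,
       segment_channel = cfg$segment_channel,
       bin_width = cfg$bin_width,
       simulation = sim)
}
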