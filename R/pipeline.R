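# End-to-end orchestration: config validation, staged pipeline, reporting.

default_config <- function() {
  list(
    seed = 1L,
    condition = "effective",
    scenario = list(),
    segmentation = list(
      smoothing_sigma_um = 2,
      threshold = 0.1,
      min_area_um2 = 20,
      max_area_um2 = 2000,
      closing_radius_um = 15
    ),
    tracking = list(
      threshold = 0.1,
      volume_gate_low_um3 = 280,    # single-cell volume gate, lower bound
      volume_gate_high_um3 = 10000, # and upper bound (um^3)
      max_displacement_um = 30,
      min_duration_h = 10
    ),
    motility = list(
      max_lag_h = 25,
      population_max_lag_h = 30,
      t_d_h = 10                    # diffusive-fraction lag
    )
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, fills defaults (volume gate
#' 280--10,000 um^3, diffusive-fraction lag 10 h, 10 um z-step, 1 h frame
#' interval via the scenario defaults) and validates every numeric range.
#' Unknown keys and out-of-range values raise named errors.
#'
#' @param config path to a YAML config file, a nested list, or `NULL` for
#'   the full default configuration.
#' @return A validated `pipeline_config` list with a `scenario` element that
#'   is an [assay_scenario()].
#' @export
validate_config <- function(config = NULL) {
  raw <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else abort("`config` must be a path, a list, or NULL.")
  def <- default_config()
  bad <- setdiff(names(raw), names(def))
  if (length(bad)) abort(paste0("unknown config keys: ",
                                paste(bad, collapse = ", ")))
  for (sec in c("segmentation", "tracking", "motility")) {
    extra <- setdiff(names(raw[[sec]]), names(def[[sec]]))
    if (length(extra)) {
      abort(paste0("unknown keys in `", sec, "`: ",
                   paste(extra, collapse = ", ")))
    }
    def[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  for (k in c("seed", "condition")) if (!is.null(raw[[k]])) def[[k]] <- raw[[k]]
  if (!def$condition %in% c("effective", "ineffective")) {
    abort("`condition` must be 'effective' or 'ineffective'.")
  }
  sc_args <- raw$scenario %||% list()
  sc_args$seed <- sc_args$seed %||% def$seed
  def$scenario <- do.call(assay_scenario, sc_args)
  trk <- def$tracking
  if (trk$volume_gate_low_um3 >= trk$volume_gate_high_um3) {
    abort("tracking volume gate: low bound must be below high bound.")
  }
  if (trk$volume_gate_low_um3 < 0) abort("volume gate bounds must be >= 0.")
  if (trk$max_displacement_um <= 0) abort("`max_displacement_um` must be > 0.")
  if (trk$min_duration_h < 0) abort("`min_duration_h` must be >= 0.")
  mot <- def$motility
  if (mot$max_lag_h <= 0 || mot$population_max_lag_h <= 0) {
    abort("motility lags must be > 0.")
  }
  if (mot$t_d_h <= 0) abort("`t_d_h` must be > 0.")
  seg <- def$segmentation
  if (seg$min_area_um2 < 0 || seg$max_area_um2 <= seg$min_area_um2) {
    abort("segmentation area bounds: need 0 <= min < max.")
  }
  structure(def, class = "pipeline_config")
}

#' Run the full synthetic-assay analysis pipeline
#'
#' Simulates the configured scenario, renders each frame, and runs the full
#' analysis chain: per-plane segmentation of the three channels, tumoroid
#' boundary masking, in/out T-cell partition, whole-tumoroid killing and
#' recruitment readouts, volume-gated 3D detection, Hungarian linking,
#' track filtering and MSD motility fits. Frames are rendered and analysed
#' one at a time so memory stays bounded. Deterministic for a fixed config
#' (the seed drives simulation and rendering noise).
#'
#' @param config a [validate_config()] input (path, list or `NULL`).
#' @param output_dir if non-`NULL`, CSV/JSON outputs and a run log are
#'   written there.
#' @param verbose print stage progress.
#' @return A `pipeline_result` list: `counts`, `series` (tumoroid time
#'   series), `detections`, `trajectories` (filtered), `fits`,
#'   `population_summary`, `population_msd`, `ground_truth`, `config`.
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL, verbose = FALSE) {
  cfg <- validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  preset <- if (cfg$condition == "effective") {
    scenario_effective(cfg$scenario)
  } else {
    scenario_ineffective(cfg$scenario)
  }
  say("stage simulate: %d nuclei, %d T-cells, %d frames",
      cfg$scenario$n_nuclei, cfg$scenario$n_tcells, cfg$scenario$n_frames)
  gt <- simulate_tcells(preset$scenario, preset$motility, preset$killing)

  seg <- cfg$segmentation
  trk <- cfg$tracking
  counts <- vector("list", cfg$scenario$n_frames)
  detections <- vector("list", cfg$scenario$n_frames)
  say("stage segment/quantify/detect: streaming %d frames",
      cfg$scenario$n_frames)
  for (ti in seq_len(cfg$scenario$n_frames)) {
    stack <- render_frames(gt, timepoints = ti,
                           rng_seed = cfg$scenario$seed + ti)
    nz <- dim(stack$data)[2]
    frame_counts <- vector("list", nz)
    for (zi in seq_len(nz)) {
      nuc <- segment_objects(get_plane(stack, 1, zi, "nuclei"),
                             stack$lateral_pixel_size,
                             smoothing_sigma_um = seg$smoothing_sigma_um,
                             threshold = seg$threshold,
                             min_area_um2 = seg$min_area_um2,
                             max_area_um2 = seg$max_area_um2,
                             class = "nucleus", t = ti, z = zi)
      pio <- segment_objects(get_plane(stack, 1, zi, "pi"),
                             stack$lateral_pixel_size,
                             smoothing_sigma_um = seg$smoothing_sigma_um,
                             threshold = seg$threshold,
                             min_area_um2 = seg$min_area_um2,
                             max_area_um2 = seg$max_area_um2,
                             class = "pi", t = ti, z = zi)
      tco <- segment_objects(get_plane(stack, 1, zi, "tcell"),
                             stack$lateral_pixel_size,
                             smoothing_sigma_um = seg$smoothing_sigma_um,
                             threshold = seg$threshold,
                             min_area_um2 = seg$min_area_um2,
                             max_area_um2 = seg$max_area_um2,
                             class = "tcell", t = ti, z = zi)
      mask <- build_tumoroid_mask(nuc, closing_radius_um = seg$closing_radius_um)
      parts <- mask_tcells(tco, mask)
      frame_counts[[zi]] <- plane_counts(nuc, pio, parts$inside)
    }
    counts[[ti]] <- dplyr::bind_rows(frame_counts)
    vol <- get_volume(stack, 1, "tcell")
    detections[[ti]] <- detect_3d(
      vol, stack$lateral_pixel_size, stack$z_step,
      threshold = trk$threshold,
      volume_gate = c(trk$volume_gate_low_um3, trk$volume_gate_high_um3),
      t_h = (ti - 1) * cfg$scenario$frame_interval)
  }
  counts <- dplyr::bind_rows(counts)
  detections <- dplyr::bind_rows(detections)
  series <- aggregate_stack(counts)
  if (any(series$zero_denominator)) {
    warn("some timepoints had no detected nuclei (killing fraction set to 0).")
  }

  say("stage track/motility: %d detections", nrow(detections))
  trajectories <- link_tracks(detections,
                              max_displacement = trk$max_displacement_um)
  trajectories <- filter_tracks(trajectories,
                                min_duration_h = trk$min_duration_h)
  fits <- fit_trajectories(trajectories, max_lag_h = cfg$motility$max_lag_h,
                           t_D = cfg$motility$t_d_h)
  result <- structure(
    list(counts = counts, series = series, detections = detections,
         trajectories = trajectories, fits = fits,
         population_summary = if (nrow(fits)) summarize_population(fits),
         population_msd = if (dplyr::n_distinct(trajectories$cell_id) >= 2) {
           population_msd(trajectories,
                          max_lag_h = cfg$motility$population_max_lag_h)
         },
         ground_truth = gt, config = cfg),
    class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$counts, file.path(output_dir, "plane_counts.csv"))
  readr::write_csv(result$series, file.path(output_dir, "tumoroid_series.csv"))
  readr::write_csv(result$detections, file.path(output_dir, "detections.csv"))
  readr::write_csv(result$trajectories,
                   file.path(output_dir, "trajectories.csv"))
  readr::write_csv(result$fits, file.path(output_dir, "motility_fits.csv"))
  if (!is.null(result$population_summary)) {
    jsonlite::write_json(result$population_summary,
                         file.path(output_dir, "population_summary.json"),
                         dataframe = "rows", digits = NA)
  }
  cfg <- result$config
  log <- list(
    package_version = as.character(utils::packageVersion("tumoroidtk")),
    seed = cfg$seed,
    condition = cfg$condition,
    config_hash = rlang::hash(unclass(cfg)),
    defaults = list(
      volume_gate_um3 = c(cfg$tracking$volume_gate_low_um3,
                          cfg$tracking$volume_gate_high_um3),
      t_d_h = cfg$motility$t_d_h,
      z_step_um = cfg$scenario$z_step,
      frame_interval_h = cfg$scenario$frame_interval
    ),
    warnings = list(
      zero_denominator_timepoints = sum(result$series$zero_denominator),
      undefined_fd = if (nrow(result$fits)) sum(!is.finite(result$fits$fD))
                     else 0L
    )
  )
  jsonlite::write_json(log, file.path(output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$config$condition, "scenario\n")
  cat(sprintf("  final killing fraction  %.3f\n",
              tail(x$series$killing_fraction, 1)))
  cat(sprintf("  peak T-cell count       %d (frame %d of %d)\n",
              max(x$series$tcell_count), which.max(x$series$tcell_count),
              nrow(x$series)))
  cat(sprintf("  tracked cells (>= %g h) %d\n",
              x$config$tracking$min_duration_h,
              dplyr::n_distinct(x$trajectories$cell_id)))
  invisible(x)
}
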