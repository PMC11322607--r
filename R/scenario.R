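#' Define a synthetic co-culture assay scenario
#'
#' An `assay_scenario` captures the geometry, calibration and sampling of one
#' simulated tumoroid/T-cell co-culture: a roughly spherical tumoroid of
#' densely packed nuclei embedded mid-volume in an ECM block, T-cells seeded
#' on top of the gel, imaged as a 3-channel z-stack at a fixed frame interval.
#' Defaults emulate the assay layout: ~150 um initial tumoroid diameter
#' (radius 75 um), 10 um z-step, hourly frames for 72 h, with the cell counts
#' and volume scaled to a desk-size benchmark (300 nuclei, 100 T-cells in a
#' 400 x 400 x 200 um block).
#'
#' @param volume_size numeric length-3, imaged volume extents (x, y, z) in um.
#' @param lateral_pixel_size lateral calibration, um per pixel.
#' @param z_step axial plane spacing in um (one image every `z_step` um).
#' @param frame_interval time between frames in hours.
#' @param n_frames number of timepoints.
#' @param tumoroid_center numeric length-3, tumoroid centre (x, y, z) in um.
#' @param tumoroid_radius tumoroid radius in um (75 um = ~150 um diameter).
#' @param n_nuclei number of tumor-cell nuclei packed into the tumoroid.
#' @param n_tcells number of T-cells seeded on top of the volume.
#' @param tcell_entry `"top"` (uniform over the top face) or `"offset-top"`
#'   (seeded over one half of the top face, the tilted-gel layout used for
#'   motility imaging).
#' @param nucleus_spacing minimum centre-to-centre nucleus distance in um.
#' @param seed integer seed; fixes the whole scenario's randomness.
#'
#' @return An object of class `assay_scenario` (a validated named list).
#' @examples
#' sc <- assay_scenario(n_nuclei = 50, n_tcells = 10, n_frames = 12)
#' sc$tumoroid_radius
#' @export
assay_scenario <- function(volume_size = c(400, 400, 200),
                           lateral_pixel_size = 2,
                           z_step = 10,
                           frame_interval = 1,
                           n_frames = 72,
                           tumoroid_center = volume_size / 2,
                           tumoroid_radius = 75,
                           n_nuclei = 300,
                           n_tcells = 100,
                           tcell_entry = c("top", "offset-top"),
                           nucleus_spacing = 7,
                           seed = 1L) {
  tcell_entry <- match.arg(tcell_entry)
  sc <- structure(
    list(
      volume_size = as.numeric(volume_size),
      lateral_pixel_size = as.numeric(lateral_pixel_size),
      z_step = as.numeric(z_step),
      frame_interval = as.numeric(frame_interval),
      n_frames = as.integer(n_frames),
      tumoroid_center = as.numeric(tumoroid_center),
      tumoroid_radius = as.numeric(tumoroid_radius),
      n_nuclei = as.integer(n_nuclei),
      n_tcells = as.integer(n_tcells),
      tcell_entry = tcell_entry,
      nucleus_spacing = as.numeric(nucleus_spacing),
      seed = as.integer(seed)
    ),
    class = "assay_scenario"
  )
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "assay_scenario"))
  if (length(sc$volume_size) != 3 || any(sc$volume_size <= 0)) {
    abort("`volume_size` must be 3 positive extents (x, y, z) in um.")
  }
  if (length(sc$tumoroid_center) != 3) {
    abort("`tumoroid_center` must be a 3D point (x, y, z) in um.")
  }
  for (fld in c("lateral_pixel_size", "z_step", "frame_interval",
                "tumoroid_radius", "nucleus_spacing")) {
    if (!is.finite(sc[[fld]]) || sc[[fld]] <= 0) {
      abort(paste0("`", fld, "` must be a positive number."))
    }
  }
  if (sc$n_frames < 1L) abort("`n_frames` must be >= 1.")
  if (sc$n_nuclei < 0L || sc$n_tcells < 0L) abort("cell counts must be >= 0.")
  lo <- sc$tumoroid_center - sc$tumoroid_radius
  hi <- sc$tumoroid_center + sc$tumoroid_radius
  if (any(lo < 0) || any(hi > sc$volume_size)) {
    abort("tumoroid must fit entirely inside the imaged volume.")
  }
  sc
}

#' @export
print.assay_scenario <- function(x, ...) {
  cat("<assay_scenario>\n")
  cat(sprintf("  volume       %g x %g x %g um (%g um/px lateral, %g um z-step)\n",
              x$volume_size[1], x$volume_size[2], x$volume_size[3],
              x$lateral_pixel_size, x$z_step))
  cat(sprintf("  tumoroid     radius %g um at (%g, %g, %g), %d nuclei\n",
              x$tumoroid_radius, x$tumoroid_center[1], x$tumoroid_center[2],
              x$tumoroid_center[3], x$n_nuclei))
  cat(sprintf("  T-cells      %d, entry: %s\n", x$n_tcells, x$tcell_entry))
  cat(sprintf("  time         %d frames every %g h, seed %d\n",
              x$n_frames, x$frame_interval, x$seed))
  invisible(x)
}

#' T-cell motility parameters for the synthetic generator
#'
#' Parameterises the two-phase motility the assay exhibits: an initial
#' unbiased random walk (per-axis diffusion coefficient `d_axis`), switching
#' -- on the first T-cell/tumoroid contact when `switch_mode =
#' "on_first_contact"` -- to a recruitment phase in which T-cells within
#' `sensing_radius` of the tumoroid surface add a directed drift of magnitude
#' `speed` toward the tumoroid.
#'
#' Note on conventions: `d_axis` is the per-axis diffusion coefficient, so a
#' pure random walk has 3D mean squared displacement `6 * d_axis * t`. The
#' MSD model fitted downstream uses the 2D-form diffusive term `4 D t`, so a
#' fit to pure-random-walk 3D tracks recovers `D = 1.5 * d_axis`.
#'
#' @param d_axis per-axis diffusion coefficient, um^2/h.
#' @param speed directed drift speed during recruitment, um/h.
#' @param sensing_radius distance from the tumoroid surface (um) within which
#'   a T-cell responds to the recruitment signal.
#' @param contact_radius centre-to-centre distance (um) counting as contact,
#'   both for the recruitment trigger and for nucleus killing.
#' @param switch_mode `"on_first_contact"` (recruitment wave triggered by the
#'   first contact) or `"never"` (pure random walk throughout; the
#'   ineffective-antibody scenario).
#' @param disengage_alive_frac once the fraction of surviving nuclei drops
#'   below this, the recruitment signal ceases and intratumoral T-cells drift
#'   outward (they disengage from a dead target); set to 0 to disable.
#'
#' @return An object of class `motility_params`.
#' @export
motility_params <- function(d_axis = 6,
                            speed = 8,
                            sensing_radius = 150,
                            contact_radius = 15,
                            switch_mode = c("on_first_contact", "never"),
                            disengage_alive_frac = 0.1) {
  switch_mode <- match.arg(switch_mode)
  mp <- structure(
    list(
      d_axis = as.numeric(d_axis),
      speed = as.numeric(speed),
      sensing_radius = as.numeric(sensing_radius),
      contact_radius = as.numeric(contact_radius),
      switch_mode = switch_mode,
      disengage_alive_frac = as.numeric(disengage_alive_frac)
    ),
    class = "motility_params"
  )
  if (mp$d_axis < 0) abort("`d_axis` must be >= 0.")
  if (mp$speed < 0) abort("`speed` must be >= 0.")
  if (mp$sensing_radius < 0 || mp$contact_radius < 0) {
    abort("radii must be >= 0.")
  }
  if (mp$disengage_alive_frac < 0 || mp$disengage_alive_frac > 1) {
    abort("`disengage_alive_frac` must be in [0, 1].")
  }
  mp
}

#' Contact-killing parameters for the synthetic generator
#'
#' Nuclei simultaneously contacted by at least `contacts_required` T-cells
#' (within the motility `contact_radius`) die with hazard
#' `kill_rate_per_contact`; the PI (dead-cell dye) signal appears
#' `pi_onset_delay` hours after death.
#'
#' @param kill_rate_per_contact death hazard while contacted, 1/h.
#' @param pi_onset_delay delay between death and PI positivity, h.
#' @param contacts_required simultaneous T-cell contacts needed.
#' @return An object of class `killing_params`.
#' @export
killing_params <- function(kill_rate_per_contact = 0.5,
                           pi_onset_delay = 2,
                           contacts_required = 1L) {
  kp <- structure(
    list(
      kill_rate_per_contact = as.numeric(kill_rate_per_contact),
      pi_onset_delay = as.numeric(pi_onset_delay),
      contacts_required = as.integer(contacts_required)
    ),
    class = "killing_params"
  )
  if (kp$kill_rate_per_contact < 0) abort("`kill_rate_per_contact` must be >= 0.")
  if (kp$pi_onset_delay < 0) abort("`pi_onset_delay` must be >= 0.")
  if (kp$contacts_required < 1L) abort("`contacts_required` must be >= 1.")
  kp
}

#' Preset effective / ineffective antibody scenarios
#'
#' The two benchmark conditions differ only in the motility switch and the
#' killing parameters, never in geometry: the "effective" preset triggers the
#' contact-dependent recruitment wave and contact killing; the "ineffective"
#' preset keeps T-cells in the unbiased random-walk phase with no killing.
#'
#' @param scenario an [assay_scenario()].
#' @return A list with elements `scenario`, `motility`, `killing`.
#' @export
scenario_effective <- function(scenario = assay_scenario()) {
  list(scenario = scenario,
       motility = motility_params(switch_mode = "on_first_contact"),
       killing = killing_params())
}

#' @rdname scenario_effective
#' @export
scenario_ineffective <- function(scenario = assay_scenario()) {
  list(scenario = scenario,
       motility = motility_params(switch_mode = "never"),
       killing = killing_params(kill_rate_per_contact = 0))
}

# plain-text (YAML) round trip ------------------------------------------------

#' Write / read a scenario configuration file
#'
#' Serialises an [assay_scenario()] to a plain-text YAML file and back;
#' `read_scenario_config()` reconstructs an identical scenario object.
#'
#' @param scenario an [assay_scenario()].
#' @param path file path.
#' @return `write_scenario_config()` returns `path` invisibly;
#'   `read_scenario_config()` returns an [assay_scenario()].
#' @export
write_scenario_config <- function(scenario, path) {
  validate_scenario(scenario)
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(assay_scenario, raw[setdiff(names(raw), character())])
}
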