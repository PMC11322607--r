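# Calibrated multi-channel time-lapse stacks and their disk round trip.

CHANNEL_ROLES <- c(nuclei = 1L, pi = 2L, tcell = 3L)

#' Construct a calibrated image stack
#'
#' A 5-D intensity array with axes ordered `T, Z, C, Y, X`, plus voxel
#' calibration (lateral um/px, z-step um, frame interval h) and a map from
#' channel roles (`nuclei`, `pi`, `tcell`) to channel indices. Intensities
#' are kept on a 16-bit grid in `[0, 1]` (multiples of `1/65535`) so the TIFF
#' round trip is bit-exact.
#'
#' @param data numeric array with `dim = c(T, Z, C, Y, X)`.
#' @param lateral_pixel_size um per pixel (x and y).
#' @param z_step um between z-planes.
#' @param frame_interval hours between frames.
#' @param channels named integer vector mapping roles to channel indices.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, lateral_pixel_size, z_step, frame_interval,
                        channels = CHANNEL_ROLES) {
  if (length(dim(data)) != 5) abort("`data` must be a 5-D array (T,Z,C,Y,X).")
  if (any(data < 0)) abort("intensities must be non-negative.")
  if (lateral_pixel_size <= 0 || z_step <= 0 || frame_interval <= 0) {
    abort("calibration values must be positive.")
  }
  if (is.null(names(channels)) || max(channels) > dim(data)[3]) {
    abort("`channels` must name valid channel indices.")
  }
  structure(
    list(data = data, lateral_pixel_size = lateral_pixel_size,
         z_step = z_step, frame_interval = frame_interval,
         channels = channels),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d frames x %d planes x %d channels x %d x %d px\n",
    d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  calibration: %g um/px lateral, %g um z-step, %g h/frame\n",
              x$lateral_pixel_size, x$z_step, x$frame_interval))
  cat(sprintf("  channels: %s\n",
              paste(names(x$channels), x$channels, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Extract one z-plane or one 3D channel volume
#'
#' @param stack an [image_stack()].
#' @param t frame index (1-based).
#' @param z plane index (1-based).
#' @param channel channel role name (`"nuclei"`, `"pi"`, `"tcell"`) or index.
#' @return `get_plane()`: a `Y x X` matrix; `get_volume()`: a `Y x X x Z`
#'   array.
#' @export
get_plane <- function(stack, t, z, channel) {
  ci <- resolve_channel(stack, channel)
  stack$data[t, z, ci, , ]
}

#' @rdname get_plane
#' @export
get_volume <- function(stack, t, channel) {
  ci <- resolve_channel(stack, channel)
  aperm(stack$data[t, , ci, , , drop = FALSE][1, , 1, , ], c(2, 3, 1))
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    if (!channel %in% names(stack$channels)) {
      abort(sprintf("unknown channel role '%s'", channel))
    }
    unname(stack$channels[channel])
  } else as.integer(channel)
}

# physical <-> voxel coordinate conventions: 0-based pixel index i spans
# [i*s, (i+1)*s) um, its centre sits at (i + 0.5) * s.
um_to_index0 <- function(um, step) um / step - 0.5
index0_to_um <- function(i, step) (i + 0.5) * step

#' Render ground truth into a fluorescence image stack
#'
#' Draws one isotropic Gaussian blob per object per channel at its calibrated
#' voxel position: nuclei (all, dead or alive) in the nuclei channel, PI
#' blobs only for nuclei dead for at least `pi_onset_delay` hours, T-cells at
#' their frame positions. Adds a constant background and Poisson shot noise
#' (photon-count model with `photons_full_scale` photons at intensity 1),
#' then quantises to a 16-bit grid.
#'
#' @param ground_truth a `ground_truth` from [simulate_tcells()].
#' @param scenario an [assay_scenario()]; defaults to the one recorded in the
#'   ground truth.
#' @param blob_sigma_um named numeric, Gaussian sigma per channel role (um).
#'   Sigmas below one pixel are clamped with a warning.
#' @param amplitude named numeric, peak intensity per channel role.
#' @param background constant background intensity (0 disables).
#' @param photons_full_scale photon count corresponding to intensity 1;
#'   `0` disables shot noise.
#' @param timepoints frames to render (default all); rendering a subset keeps
#'   memory bounded for long movies.
#' @param rng_seed integer seed for the noise.
#' @return An [image_stack()] with axes `T, Z, C, Y, X`.
#' @export
render_frames <- function(ground_truth,
                          scenario = ground_truth$scenario,
                          blob_sigma_um = c(nuclei = 4, pi = 4, tcell = 4),
                          amplitude = c(nuclei = 0.6, pi = 0.6, tcell = 0.6),
                          background = 0.02,
                          photons_full_scale = 200,
                          timepoints = NULL,
                          rng_seed = scenario$seed) {
  validate_scenario(scenario)
  px <- scenario$lateral_pixel_size
  if (any(blob_sigma_um < px)) {
    warn(sprintf("blob sigma below one pixel (%g um); clamping.", px))
    blob_sigma_um[blob_sigma_um < px] <- px
  }
  nx <- max(1L, round(scenario$volume_size[1] / px))
  ny <- max(1L, round(scenario$volume_size[2] / px))
  nz <- max(1L, round(scenario$volume_size[3] / scenario$z_step))
  if (is.null(timepoints)) timepoints <- seq_len(scenario$n_frames)
  nT <- length(timepoints)
  t_h <- (timepoints - 1L) * scenario$frame_interval

  nuc <- ground_truth$nuclei
  trj <- ground_truth$trajectories
  delay <- ground_truth$killing$pi_onset_delay %||% 0

  out <- array(0, c(nT, nz, 3L, ny, nx))
  for (ti in seq_len(nT)) {
    tt <- t_h[ti]
    objs <- list(
      nuclei = cbind(nuc$x_um, nuc$y_um, nuc$z_um),
      pi = {
        dead <- !is.na(nuc$death_time_h) & tt >= nuc$death_time_h + delay
        cbind(nuc$x_um, nuc$y_um, nuc$z_um)[dead, , drop = FALSE]
      },
      tcell = {
        fr <- trj[abs(trj$t_h - tt) < 1e-9, , drop = FALSE]
        cbind(fr$x_um, fr$y_um, fr$z_um)
      }
    )
    for (role in names(CHANNEL_ROLES)) {
      ci <- CHANNEL_ROLES[[role]]
      sig <- blob_sigma_um[[role]]
      amp <- amplitude[[role]]
      vol <- render_blobs(objs[[role]], nx, ny, nz, px, scenario$z_step,
                          sig, amp)
      out[ti, , ci, , ] <- aperm(vol, c(3, 1, 2))
    }
  }
  out <- out + background
  if (photons_full_scale > 0) {
    out <- with_seed(rng_seed, {
      array(rpois(length(out), lambda = out * photons_full_scale),
            dim(out)) / photons_full_scale
    })
  }
  out <- pmin(pmax(out, 0), 1)
  out <- round(out * 65535) / 65535   # 16-bit grid; exact TIFF round trip
  image_stack(out, px, scenario$z_step, scenario$frame_interval)
}

# additive Gaussian blobs on a Y x X x Z grid; positions in um
render_blobs <- function(xyz, nx, ny, nz, px, z_step, sigma, amplitude) {
  vol <- array(0, c(ny, nx, nz))
  if (is.null(xyz) || nrow(xyz) == 0) return(vol)
  half_xy <- ceiling(3 * sigma / px)
  half_z <- ceiling(3 * sigma / z_step)
  for (k in seq_len(nrow(xyz))) {
    cx <- um_to_index0(xyz[k, 1], px)        # 0-based fractional indices
    cy <- um_to_index0(xyz[k, 2], px)
    cz <- um_to_index0(xyz[k, 3], z_step)
    xs <- max(0L, floor(cx) - half_xy):min(nx - 1L, ceiling(cx) + half_xy)
    ys <- max(0L, floor(cy) - half_xy):min(ny - 1L, ceiling(cy) + half_xy)
    zs <- max(0L, floor(cz) - half_z):min(nz - 1L, ceiling(cz) + half_z)
    if (!length(xs) || !length(ys) || !length(zs)) next
    gx <- exp(-((xs - cx) * px)^2 / (2 * sigma^2))
    gy <- exp(-((ys - cy) * px)^2 / (2 * sigma^2))
    gz <- exp(-((zs - cz) * z_step)^2 / (2 * sigma^2))
    blob <- amplitude * outer(outer(gy, gx), gz)
    vol[ys + 1L, xs + 1L, zs + 1L] <- vol[ys + 1L, xs + 1L, zs + 1L] + blob
  }
  vol
}

#' Write / read a full synthetic scenario bundle
#'
#' `write_scenario()` writes the rendered stack as a per-timepoint TIFF
#' series (16-bit, pages ordered z-major then channel), the ground-truth
#' tables as CSV (`trajectories.csv`: `cell_id, t_h, x_um, y_um, z_um`;
#' `nuclei.csv`: `nucleus_id, x_um, y_um, z_um, death_time_h`) and the
#' scenario configuration as YAML. `read_scenario()` reconstructs the stack
#' voxel-for-voxel together with the tables.
#'
#' @param stack an [image_stack()].
#' @param ground_truth the matching `ground_truth` object.
#' @param dir output directory (created if missing).
#' @return `write_scenario()`: `dir`, invisibly. `read_scenario()`: a list
#'   with `stack`, `nuclei`, `trajectories`, `scenario`.
#' @export
write_scenario <- function(stack, ground_truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory '%s'", dir))
  d <- dim(stack$data)
  for (t in seq_len(d[1])) {
    pages <- vector("list", d[2] * d[3])
    i <- 0L
    for (z in seq_len(d[2])) {
      for (c in seq_len(d[3])) {
        i <- i + 1L
        pages[[i]] <- stack$data[t, z, c, , ]
      }
    }
    tiff::writeTIFF(pages, file.path(dir, sprintf("frame_%03d.tif", t)),
                    bits.per.sample = 16L)
  }
  readr::write_csv(ground_truth$trajectories,
                   file.path(dir, "trajectories.csv"))
  readr::write_csv(ground_truth$nuclei, file.path(dir, "nuclei.csv"))
  write_scenario_config(ground_truth$scenario, file.path(dir, "scenario.yaml"))
  meta <- list(n_frames = d[1], n_planes = d[2], n_channels = d[3],
               channels = as.list(stack$channels))
  yaml::write_yaml(meta, file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("no such directory '%s'", dir))
  scenario <- read_scenario_config(file.path(dir, "scenario.yaml"))
  meta <- yaml::read_yaml(file.path(dir, "stack.yaml"))
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.tif$",
                           full.names = TRUE))
  if (length(files) != meta$n_frames) abort("frame files missing.")
  first <- tiff::readTIFF(files[1], all = TRUE)
  ny <- nrow(first[[1]]); nx <- ncol(first[[1]])
  data <- array(0, c(meta$n_frames, meta$n_planes, meta$n_channels, ny, nx))
  for (t in seq_along(files)) {
    pages <- if (t == 1) first else tiff::readTIFF(files[t], all = TRUE)
    i <- 0L
    for (z in seq_len(meta$n_planes)) {
      for (c in seq_len(meta$n_channels)) {
        i <- i + 1L
        data[t, z, c, , ] <- pages[[i]]
      }
    }
  }
  chans <- unlist(meta$channels)
  list(
    stack = image_stack(data, scenario$lateral_pixel_size, scenario$z_step,
                        scenario$frame_interval, channels = chans),
    nuclei = readr::read_csv(file.path(dir, "nuclei.csv"),
                             show_col_types = FALSE),
    trajectories = readr::read_csv(file.path(dir, "trajectories.csv"),
                                   show_col_types = FALSE),
    scenario = scenario
  )
}
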