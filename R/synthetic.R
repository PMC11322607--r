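# Synthetic scenario generator: ground-truthed tumoroid/T-cell co-cultures.

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Pack nuclei into a spherical tumoroid
#'
#' Places `n_nuclei` points uniformly inside the tumoroid sphere by dart
#' throwing with a hard minimum spacing, emulating densely packed nuclei in a
#' ~150 um diameter tumoroid. Deterministic for a fixed seed.
#'
#' @param scenario an [assay_scenario()].
#' @param rng_seed integer seed; defaults to the scenario seed.
#' @param max_attempts_per_nucleus rejection-sampling budget per nucleus.
#' @return A tibble with columns `nucleus_id, x_um, y_um, z_um`.
#' @examples
#' nuc <- make_tumoroid(assay_scenario(n_nuclei = 40))
#' max(sqrt(rowSums((as.matrix(nuc[, 2:4]) - 200)^2)))  # < tumoroid radius
#' @export
make_tumoroid <- function(scenario, rng_seed = scenario$seed,
                          max_attempts_per_nucleus = 500) {
  validate_scenario(scenario)
  n <- scenario$n_nuclei
  r <- scenario$tumoroid_radius
  ctr <- scenario$tumoroid_center
  spacing <- scenario$nucleus_spacing
  if (n == 0L) {
    return(tibble(nucleus_id = integer(), x_um = numeric(),
                  y_um = numeric(), z_um = numeric()))
  }
  pts <- with_seed(rng_seed, {
    out <- matrix(NA_real_, n, 3)
    placed <- 0L
    attempts <- 0L
    budget <- max_attempts_per_nucleus * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > budget) {
        abort(sprintf(
          paste0("could not pack %d nuclei at spacing %g um into a sphere of ",
                 "radius %g um (packing density too high; placed %d)"),
          n, spacing, r, placed))
      }
      # uniform point in the sphere
      p <- ctr + r * (2 * runif(3) - 1)
      if (sum((p - ctr)^2) > r^2) next
      if (placed > 0L) {
        d2 <- colSums((t(out[seq_len(placed), , drop = FALSE]) - p)^2)
        if (any(d2 < spacing^2)) next
      }
      placed <- placed + 1L
      out[placed, ] <- p
    }
    out
  })
  tibble(nucleus_id = seq_len(n),
         x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3])
}

# initial T-cell positions on top of the gel
tcell_start_positions <- function(scenario) {
  n <- scenario$n_tcells
  L <- scenario$volume_size
  x_max <- if (scenario$tcell_entry == "offset-top") L[1] / 2 else L[1]
  cbind(runif(n, 0, x_max), runif(n, 0, L[2]), rep(L[3] - 5, n))
}

reflect_into <- function(x, lo, hi) {
  # reflecting boundaries; at most a few bounces per sub-step
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  x <- ifelse(x > span, 2 * span - x, x)
  x + lo
}

#' Simulate T-cell motility and contact killing in a tumoroid co-culture
#'
#' Agent-based simulation of the assay's two observed motility phases. Each
#' T-cell performs a per-axis Gaussian random walk (step variance
#' `2 * d_axis * dt` per axis). With `switch_mode = "on_first_contact"`, the
#' first T-cell/tumoroid contact (within `contact_radius` of the tumoroid
#' surface) triggers the recruitment wave: from then on every T-cell within
#' `sensing_radius` of the surface adds a drift of magnitude `speed` directed
#' toward the tumoroid surface; cells that have reached the tumoroid steer
#' toward their nearest surviving nucleus, so the attack sweeps the whole
#' sphere from the outside in. Nuclei simultaneously contacted by
#' `contacts_required` or more T-cells die with hazard
#' `kill_rate_per_contact`. Once the surviving-nucleus fraction falls below
#' `disengage_alive_frac` the recruitment signal ceases and intratumoral
#' T-cells drift outward. Boundaries of the volume reflect. `switch_mode =
#' "always"` forces the drift on from t = 0 (ballistic benchmark);
#' `"never"` keeps the pure random walk throughout.
#'
#' @param scenario an [assay_scenario()].
#' @param motility a [motility_params()]; `switch_mode` may also be `"always"`.
#' @param killing a [killing_params()].
#' @param rng_seed integer seed; defaults to the scenario seed.
#' @param dt simulation sub-step, h (must divide the frame interval).
#' @return An object of class `ground_truth`: a list with tibbles
#'   `nuclei` (`nucleus_id, x_um, y_um, z_um, death_time_h`; `NA` = alive),
#'   `trajectories` (`cell_id, t_h, x_um, y_um, z_um`, sampled at frame
#'   times), `switch_times` (`cell_id, switch_time_h`; first time the drift
#'   acted on that cell, `NA` = never), plus the scenario and parameters.
#' @export
simulate_tcells <- function(scenario,
                            motility = motility_params(),
                            killing = killing_params(),
                            rng_seed = scenario$seed,
                            dt = 0.1) {
  validate_scenario(scenario)
  if (!is.finite(dt) || dt <= 0) abort("`dt` must be > 0.")
  if (dt > scenario$frame_interval + 1e-12) {
    abort("`dt` must not exceed the frame interval.")
  }
  n_sub <- round(scenario$frame_interval / dt)
  if (abs(n_sub * dt - scenario$frame_interval) > 1e-9) {
    abort("`dt` must divide the frame interval evenly.")
  }
  if (!motility$switch_mode %in% c("on_first_contact", "never", "always")) {
    abort("unknown `switch_mode`.")
  }

  nuclei <- make_tumoroid(scenario, rng_seed)
  nuc_xyz <- as.matrix(nuclei[, c("x_um", "y_um", "z_um")])
  n_nuc <- nrow(nuclei)
  n_tc <- scenario$n_tcells
  L <- scenario$volume_size
  ctr <- scenario$tumoroid_center
  R <- scenario$tumoroid_radius

  with_seed(rng_seed + 1L, {
    pos <- tcell_start_positions(scenario)
    step_sd <- sqrt(2 * motility$d_axis * dt)
    frames <- scenario$n_frames
    traj <- array(NA_real_, c(frames, n_tc, 3))
    traj[1, , ] <- pos
    death_time <- rep(NA_real_, n_nuc)
    switch_time <- rep(NA_real_, n_tc)
    switched <- motility$switch_mode == "always"
    p_kill <- 1 - exp(-killing$kill_rate_per_contact * dt)

    for (f in seq_len(max(frames - 1L, 0L))) {
      for (s in seq_len(n_sub)) {
        t_now <- (f - 1L) * scenario$frame_interval + s * dt
        # diffusive component
        if (step_sd > 0) {
          pos <- pos + matrix(rnorm(3 * n_tc, sd = step_sd), n_tc, 3)
        }
        dvec <- sweep(pos, 2, ctr)
        dist <- sqrt(rowSums(dvec^2))
        # recruitment trigger: first contact with the tumoroid surface
        if (!switched && motility$switch_mode == "on_first_contact" &&
            any(dist <= R + motility$contact_radius)) {
          switched <- TRUE
        }
        alive_frac <- if (n_nuc > 0) mean(is.na(death_time)) else 1
        if (switched && alive_frac >= motility$disengage_alive_frac &&
            motility$speed > 0) {
          # approaching cells drift toward the tumoroid surface; arrived
          # cells steer toward their nearest surviving nucleus
          sensed <- dist - R <= motility$sensing_radius
          arrived <- dist <= R + motility$contact_radius
          appr <- which(sensed & !arrived)
          if (length(appr)) {
            u <- dvec[appr, , drop = FALSE] / dist[appr]
            pos[appr, ] <- pos[appr, ] - motility$speed * dt * u
          }
          seek <- which(arrived)
          alive <- which(is.na(death_time))
          if (length(seek) && length(alive)) {
            tgt_xyz <- nuc_xyz[alive, , drop = FALSE]
            d2 <- outer(rowSums(pos[seek, , drop = FALSE]^2),
                        rowSums(tgt_xyz^2), "+") -
              2 * pos[seek, , drop = FALSE] %*% t(tgt_xyz)
            nearest <- max.col(-d2, ties.method = "first")
            gap <- tgt_xyz[nearest, , drop = FALSE] -
              pos[seek, , drop = FALSE]
            gapd <- sqrt(rowSums(gap^2))
            go <- gapd > motility$contact_radius / 2
            if (any(go)) {
              u <- gap[go, , drop = FALSE] / gapd[go]
              pos[seek[go], ] <- pos[seek[go], ] +
                motility$speed * dt * u
            }
          }
          act <- c(appr, seek)
          newly <- act[is.na(switch_time[act])]
          switch_time[newly] <- t_now
        } else if (switched && alive_frac < motility$disengage_alive_frac &&
                   motility$speed > 0) {
          # disengagement: intratumoral cells drift back out
          act <- which(dist <= R + motility$contact_radius & dist > 1e-9)
          if (length(act)) {
            u <- dvec[act, , drop = FALSE] / dist[act]
            pos[act, ] <- pos[act, ] + motility$speed * dt * u
          }
        }
        for (ax in 1:3) pos[, ax] <- reflect_into(pos[, ax], 0, L[ax])
        # contact killing
        if (n_nuc > 0 && killing$kill_rate_per_contact > 0 &&
            anyNA(death_time) == FALSE) {
          # all dead; skip
        } else if (n_nuc > 0 && killing$kill_rate_per_contact > 0) {
          near <- which(sqrt(rowSums(sweep(pos, 2, ctr)^2)) <=
                          R + motility$contact_radius)
          alive <- which(is.na(death_time))
          if (length(near) && length(alive)) {
            d2 <- outer(rowSums(nuc_xyz[alive, , drop = FALSE]^2),
                        rowSums(pos[near, , drop = FALSE]^2), "+") -
              2 * nuc_xyz[alive, , drop = FALSE] %*% t(pos[near, , drop = FALSE])
            n_contact <- rowSums(d2 <= motility$contact_radius^2)
            hit <- n_contact >= killing$contacts_required
            if (any(hit)) {
              dies <- hit & (runif(length(alive)) < p_kill)
              death_time[alive[dies]] <- t_now
            }
          }
        }
      }
      traj[f + 1L, , ] <- pos
    }

    t_h <- (seq_len(frames) - 1L) * scenario$frame_interval
    trajectories <- tibble(
      cell_id = rep(seq_len(n_tc), each = frames),
      t_h = rep(t_h, times = n_tc),
      x_um = as.vector(traj[, , 1]),
      y_um = as.vector(traj[, , 2]),
      z_um = as.vector(traj[, , 3])
    )
    structure(
      list(
        nuclei = dplyr::mutate(nuclei, death_time_h = death_time),
        trajectories = trajectories,
        switch_times = tibble(cell_id = seq_len(n_tc),
                              switch_time_h = switch_time),
        scenario = scenario,
        motility = motility,
        killing = killing
      ),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  nuclei        %d (%d dead)\n", nrow(x$nuclei),
              sum(!is.na(x$nuclei$death_time_h))))
  cat(sprintf("  trajectories  %d cells x %d frames\n",
              dplyr::n_distinct(x$trajectories$cell_id), x$scenario$n_frames))
  invisible(x)
}

#' Simulate free-space directed-plus-diffusive trajectories
#'
#' Trajectory-level benchmark generator: `n` cells in unbounded medium, each
#' performing a per-axis Gaussian random walk (variance `2 * d_axis * dt` per
#' axis per sub-step) plus, when `speed > 0`, a constant drift of magnitude
#' `speed` along a per-cell random unit direction. This is the clean
#' statistical counterpart of the MSD model `msd(t) = 4 D t + v^2 t^2`: a
#' pure random walk has 3D MSD `6 * d_axis * t` (so the fitted `D` equals
#' `1.5 * d_axis`) and pure drift has MSD `speed^2 t^2`.
#'
#' @param n number of cells.
#' @param d_axis per-axis diffusion coefficient, um^2/h.
#' @param speed drift speed, um/h.
#' @param n_frames number of sampled timepoints.
#' @param frame_interval sampling interval, h.
#' @param rng_seed integer seed.
#' @param dt simulation sub-step, h.
#' @return A trajectory tibble (`cell_id, t_h, x_um, y_um, z_um`).
#' @export
simulate_trajectories <- function(n, d_axis, speed = 0, n_frames = 72,
                                  frame_interval = 1, rng_seed = 1L,
                                  dt = 0.1) {
  if (n < 1) abort("`n` must be >= 1.")
  if (d_axis < 0 || speed < 0) abort("`d_axis` and `speed` must be >= 0.")
  if (dt <= 0 || dt > frame_interval) abort("invalid `dt`.")
  n_sub <- round(frame_interval / dt)
  with_seed(rng_seed, {
    dirs <- matrix(rnorm(3 * n), n, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pos <- matrix(0, n, 3)
    out <- array(NA_real_, c(n_frames, n, 3))
    out[1, , ] <- pos
    step_sd <- sqrt(2 * d_axis * dt)
    for (f in seq_len(n_frames - 1L)) {
      for (s in seq_len(n_sub)) {
        if (step_sd > 0) pos <- pos + matrix(rnorm(3 * n, sd = step_sd), n, 3)
        if (speed > 0) pos <- pos + speed * dt * dirs
      }
      out[f + 1L, , ] <- pos
    }
    t_h <- (seq_len(n_frames) - 1L) * frame_interval
    tibble(
      cell_id = rep(seq_len(n), each = n_frames),
      t_h = rep(t_h, times = n),
      x_um = as.vector(out[, , 1]),
      y_um = as.vector(out[, , 2]),
      z_um = as.vector(out[, , 3])
    )
  })
}
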