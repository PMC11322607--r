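# Independent oracles and small fixtures used across the suite.

# brute-force time-averaged MSD: explicit double loop over ordered pairs
bf_msd <- function(xyz, interval, max_k) {
  n <- nrow(xyz)
  vapply(seq_len(max_k), function(k) {
    acc <- 0
    for (i in seq_len(n - k)) {
      acc <- acc + sum((xyz[i + k, ] - xyz[i, ])^2)
    }
    acc / (n - k)
  }, numeric(1))
}

# exhaustive min-cost maximum-cardinality matching under a distance gate;
# returns list(cost=, match=) with match[i] = column for row i or NA
bf_match <- function(a, b, gate) {
  na <- nrow(a); nb <- nrow(b)
  d <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
  best <- list(cost = Inf, card = -1L, match = rep(NA_integer_, na))
  rec <- function(i, used, match, cost, card) {
    if (i > na) {
      if (card > best$card ||
          (card == best$card && cost < best$cost - 1e-12)) {
        best <<- list(cost = cost, card = card, match = match)
      }
      return(invisible())
    }
    rec(i + 1L, used, match, cost, card)               # row i unmatched
    for (j in seq_len(nb)) {
      if (!used[j] && d[i, j] <= gate) {
        used[j] <- TRUE
        match[i] <- j
        rec(i + 1L, used, match, cost + d[i, j], card + 1L)
        used[j] <- FALSE
        match[i] <- NA_integer_
      }
    }
  }
  rec(1L, rep(FALSE, nb), rep(NA_integer_, na), 0, 0L)
  best
}

# well-separated diffusing cells: simulate_trajectories cells offset onto a
# grid (pitch 60 um), the linking-fidelity benchmark scene
separated_tracks <- function(n = 100, d_axis = 2, seed = 1) {
  trj <- simulate_trajectories(n, d_axis = d_axis, speed = 0,
                               n_frames = 72, rng_seed = seed)
  side <- ceiling(sqrt(n))
  offs <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(n), ] * 60
  trj$x_um <- trj$x_um + offs$x[trj$cell_id]
  trj$y_um <- trj$y_um + offs$y[trj$cell_id]
  trj
}

# a tiny calibrated scenario for fast end-to-end style tests
small_scenario <- function(seed = 5, n_frames = 6) {
  assay_scenario(volume_size = c(160, 160, 80), lateral_pixel_size = 2,
                 n_frames = n_frames, tumoroid_radius = 30,
                 tumoroid_center = c(80, 80, 40), n_nuclei = 40,
                 n_tcells = 10, seed = seed)
}

# hand-built ground truth with arbitrary positions (no simulation)
manual_ground_truth <- function(scenario, nuclei_xyz, tcell_xyz = NULL,
                                death_times = NULL) {
  n <- nrow(nuclei_xyz)
  nuclei <- tibble::tibble(
    nucleus_id = seq_len(n),
    x_um = nuclei_xyz[, 1], y_um = nuclei_xyz[, 2], z_um = nuclei_xyz[, 3],
    death_time_h = death_times %||% rep(NA_real_, n))
  n_tc <- if (is.null(tcell_xyz)) 0L else nrow(tcell_xyz)
  times <- (seq_len(scenario$n_frames) - 1) * scenario$frame_interval
  nT <- length(times)
  trajectories <- if (n_tc) {
    tibble::tibble(
      cell_id = rep(seq_len(n_tc), each = nT),
      t_h = rep(times, n_tc),
      x_um = rep(tcell_xyz[, 1], each = nT),
      y_um = rep(tcell_xyz[, 2], each = nT),
      z_um = rep(tcell_xyz[, 3], each = nT))
  } else {
    tibble::tibble(cell_id = integer(), t_h = numeric(), x_um = numeric(),
                   y_um = numeric(), z_um = numeric())
  }
  structure(
    list(nuclei = nuclei, trajectories = trajectories,
         switch_times = tibble::tibble(cell_id = seq_len(n_tc),
                                       switch_time_h = NA_real_),
         scenario = scenario,
         motility = motility_params(),
         killing = killing_params()),
    class = "ground_truth")
}

# Gaussian blob image fixture: returns a Y x X matrix
blob_plane <- function(ny, nx, centers_px, sigma_px, amplitude = 0.8,
                       background = 0) {
  m <- matrix(background, ny, nx)
  for (k in seq_len(nrow(centers_px))) {
    cx <- centers_px[k, 1]; cy <- centers_px[k, 2]
    for (i in seq_len(ny)) {
      m[i, ] <- m[i, ] + amplitude *
        exp(-(((seq_len(nx) - cx)^2) + (i - cy)^2) / (2 * sigma_px^2))
    }
  }
  m
}
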