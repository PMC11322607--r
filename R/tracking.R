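# 3D T-cell detection per timepoint and frame-to-frame trajectory linking.

#' Detect T-cells in a 3D volume with a cell-volume gate
#'
#' Thresholds the T-cell channel volume, labels 26-connected components,
#' computes intensity-weighted 3D centres of mass in um, and retains
#' components whose physical volume lies strictly between the gate bounds
#' (default 280--10,000 um^3, the expected single-cell volume range).
#'
#' @param volume a `Y x X x Z` intensity array (one timepoint, one channel).
#' @param pixel_size lateral calibration, um/px.
#' @param z_step axial plane spacing, um.
#' @param threshold fixed intensity threshold, or `"otsu"`.
#' @param volume_gate numeric length-2 `(low, high)` in um^3; components are
#'   kept iff `low < volume < high` (strict).
#' @param t_h timestamp (h) carried into the output.
#' @return A tibble `t_h, x_um, y_um, z_um, volume_um3`, one row per
#'   retained detection; `attr(, "n_components")` holds the total component
#'   count before gating.
#' @export
detect_3d <- function(volume, pixel_size, z_step,
                      threshold = 0.1,
                      volume_gate = c(280, 10000),
                      t_h = 0) {
  if (length(dim(volume)) != 3) abort("`volume` must be a 3-D array (Y,X,Z).")
  if (!is.finite(pixel_size) || pixel_size <= 0 ||
      !is.finite(z_step) || z_step <= 0) {
    abort("voxel calibration (`pixel_size`, `z_step`) must be positive.")
  }
  if (length(volume_gate) != 2 || volume_gate[1] >= volume_gate[2]) {
    abort("`volume_gate` must be (low, high) with low < high.")
  }
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(volume), range = range(volume))
  } else as.numeric(threshold)
  mask <- volume > thr
  empty <- tibble(t_h = numeric(), x_um = numeric(), y_um = numeric(),
                  z_um = numeric(), volume_um3 = numeric())
  if (!any(mask)) {
    attr(empty, "n_components") <- 0L
    return(empty)
  }
  labels <- .label3d_cpp(as.vector(mask), dim(volume))
  n_comp <- max(labels)
  vox_vol <- pixel_size^2 * z_step
  idx <- which(labels > 0)
  lab <- labels[idx]
  npx <- tabulate(lab, n_comp)
  vols <- npx * vox_vol
  keep <- which(vols > volume_gate[1] & vols < volume_gate[2])
  if (!length(keep)) {
    attr(empty, "n_components") <- n_comp
    return(empty)
  }
  d <- dim(volume)
  row <- (idx - 1L) %% d[1]
  rest <- (idx - 1L) %/% d[1]
  col <- rest %% d[2]
  pln <- rest %/% d[2]
  w <- volume[idx]
  wsum <- vapply(split(w, lab), sum, numeric(1))
  com <- function(coord0, step) {
    s <- vapply(split(w * (coord0 + 0.5) * step, lab), sum, numeric(1))
    unname(s / wsum)
  }
  out <- tibble(t_h = t_h,
                x_um = com(col, pixel_size),
                y_um = com(row, pixel_size),
                z_um = com(pln, z_step),
                volume_um3 = vols)[keep, , drop = FALSE]
  attr(out, "n_components") <- n_comp
  out
}

# min-cost maximum-cardinality matching between two point sets under a
# displacement gate; returns integer vector: for each row of a, the matched
# row of b (NA = unmatched)
match_frame_pair <- function(a, b, max_displacement) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(rep(NA_integer_, na))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d <- sqrt(pmax(d2, 0))
  BIG <- 1e8
  n <- max(na, nb)
  cost <- matrix(BIG, n, n)
  cost[seq_len(na), seq_len(nb)] <- ifelse(d <= max_displacement, d, BIG)
  sol <- .lsap_cpp(cost)
  match <- sol[seq_len(na)]
  match[match > nb] <- NA_integer_
  ok <- !is.na(match)
  bad <- ok
  bad[ok] <- d[cbind(which(ok), match[ok])] > max_displacement
  match[bad] <- NA_integer_
  match
}

#' Link 3D detections into trajectories
#'
#' For each consecutive pair of frames, solves the global minimum-cost
#' one-to-one assignment (Hungarian algorithm) over detection pairs within
#' `max_displacement`; among all maximum-cardinality gated matchings the
#' cheapest is chosen. Unmatched detections end or begin tracks; there is no
#' gap closing, so a detection missing for one frame splits its track.
#'
#' @param detections a tibble of [detect_3d()] rows over all timepoints
#'   (columns `t_h, x_um, y_um, z_um`).
#' @param max_displacement linking gate, um per frame.
#' @return A trajectory tibble `cell_id, t_h, x_um, y_um, z_um` ordered by
#'   cell and time.
#' @export
link_tracks <- function(detections, max_displacement = 30) {
  need <- c("t_h", "x_um", "y_um", "z_um")
  if (!all(need %in% names(detections))) {
    abort("`detections` needs columns t_h, x_um, y_um, z_um.")
  }
  if (max_displacement <= 0) abort("`max_displacement` must be > 0.")
  times <- sort(unique(detections$t_h))
  if (length(times) < 2) abort("need detections at >= 2 timepoints.")
  frames <- lapply(times, function(tt) {
    as.matrix(detections[detections$t_h == tt, c("x_um", "y_um", "z_um")])
  })
  next_id <- 0L
  # active track id per detection of the current frame
  ids <- seq_len(nrow(frames[[1]])) + next_id
  next_id <- next_id + nrow(frames[[1]])
  rows <- list()
  add_rows <- function(fi, ids) {
    m <- frames[[fi]]
    if (!nrow(m)) return(NULL)
    tibble(cell_id = ids, t_h = times[fi],
           x_um = m[, 1], y_um = m[, 2], z_um = m[, 3])
  }
  rows[[1]] <- add_rows(1L, ids)
  interval <- min(diff(times))
  for (fi in seq_len(length(times) - 1L)) {
    consecutive <- (times[fi + 1L] - times[fi]) <= 1.5 * interval
    match <- if (consecutive) {
      match_frame_pair(frames[[fi]], frames[[fi + 1L]], max_displacement)
    } else {
      # a skipped frame interrupts all tracks: no gap closing
      rep(NA_integer_, nrow(frames[[fi]]))
    }
    nb <- nrow(frames[[fi + 1L]])
    new_ids <- rep(NA_integer_, nb)
    if (length(match)) {
      ok <- !is.na(match)
      new_ids[match[ok]] <- ids[ok]
    }
    unmatched <- which(is.na(new_ids))
    if (length(unmatched)) {
      new_ids[unmatched] <- next_id + seq_along(unmatched)
      next_id <- next_id + length(unmatched)
    }
    ids <- new_ids
    rows[[fi + 1L]] <- add_rows(fi + 1L, ids)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$cell_id, .data$t_h)
  # renumber ids consecutively in order of first appearance
  first <- out |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(t0 = min(.data$t_h), .groups = "drop") |>
    dplyr::arrange(.data$t0, .data$cell_id)
  out$cell_id <- match(out$cell_id, first$cell_id)
  dplyr::arrange(out, .data$cell_id, .data$t_h)
}

#' Keep trajectories observed long enough
#'
#' @param trajectories a trajectory tibble (`cell_id, t_h, ...`).
#' @param min_duration_h minimum observed duration in hours (default 10 h,
#'   matching the data requirement of the diffusive-fraction statistic at
#'   its 10-h lag).
#' @return The filtered trajectory tibble.
#' @export
filter_tracks <- function(trajectories, min_duration_h = 10) {
  trajectories |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::filter(max(.data$t_h) - min(.data$t_h) >= min_duration_h) |>
    dplyr::ungroup()
}
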