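# Per-plane object detection, tumoroid boundary mask, T-cell masking.

#' Segment fluorescent objects in one z-plane
#'
#' Standard smoothed-threshold segmentation: Gaussian smoothing, a global
#' threshold (per-plane Otsu by default, or a fixed value for
#' reproducibility across planes), optional distance-transform watershed to
#' split touching objects, then an area filter. Objects are relabelled
#' deterministically in raster order of their first pixel.
#'
#' @param plane a `Y x X` intensity matrix (values in `[0, 1]`).
#' @param pixel_size lateral calibration, um/px.
#' @param smoothing_sigma_um Gaussian smoothing sigma, um.
#' @param threshold `"otsu"` or a fixed numeric threshold in `[0, 1]`.
#' @param min_area_um2,max_area_um2 retained object area range (um^2).
#' @param split_touching split touching objects by watershed on the distance
#'   transform.
#' @param class object class tag (`"nucleus"`, `"pi"`, `"tcell"`) carried
#'   into the output.
#' @param t,z frame and plane indices carried into the output.
#' @return A `plane_objects` tibble (`t, z, class, label, x_um, y_um,
#'   area_um2`) with the label matrix in `attr(, "labels")` and the pixel
#'   size in `attr(, "pixel_size")`.
#' @export
segment_objects <- function(plane, pixel_size,
                            smoothing_sigma_um = 2,
                            threshold = "otsu",
                            min_area_um2 = 20,
                            max_area_um2 = Inf,
                            split_touching = TRUE,
                            class = "nucleus",
                            t = 1L, z = 1L) {
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  if (min_area_um2 < 0 || max_area_um2 <= min_area_um2) {
    abort("need 0 <= min_area_um2 < max_area_um2.")
  }
  img <- EBImage::Image(plane)
  sigma_px <- smoothing_sigma_um / pixel_size
  if (sigma_px > 0.3) img <- EBImage::gblur(img, sigma = sigma_px)
  thr <- if (identical(threshold, "otsu")) {
    if (max(img) > min(img)) EBImage::otsu(img, range = range(img)) else Inf
  } else {
    as.numeric(threshold)
  }
  binary <- img > thr
  if (!any(binary)) {
    return(empty_plane_objects(dim(plane), pixel_size, class, t, z))
  }
  labels <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(binary))
  } else {
    EBImage::bwlabel(binary)
  }
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(plane), ncol(plane))
  labels <- filter_relabel(labels,
                           min_px = min_area_um2 / pixel_size^2,
                           max_px = max_area_um2 / pixel_size^2)
  plane_objects_from_labels(labels, pixel_size, class, t, z)
}

empty_plane_objects <- function(dims, pixel_size, class, t, z) {
  out <- tibble(t = integer(), z = integer(), class = character(),
                label = integer(), x_um = numeric(), y_um = numeric(),
                area_um2 = numeric())
  attr(out, "labels") <- matrix(0L, dims[1], dims[2])
  attr(out, "pixel_size") <- pixel_size
  attr(out, "t") <- as.integer(t)
  attr(out, "z") <- as.integer(z)
  structure(out, class = c("plane_objects", class(out)))
}

# keep components with pixel count in (min_px, max_px); relabel 1..K in
# raster order (first pixel, column-major over the matrix)
filter_relabel <- function(labels, min_px = 0, max_px = Inf) {
  if (!any(labels > 0)) return(labels)
  counts <- tabulate(labels)
  keep <- which(counts >= min_px & counts <= max_px)
  if (!length(keep)) return(array(0L, dim(labels)))
  first_px <- vapply(keep, function(l) match(l, labels), integer(1))
  keep <- keep[order(first_px)]
  map <- integer(max(labels))
  map[keep] <- seq_along(keep)
  out <- array(0L, dim(labels))
  pos <- labels > 0
  out[pos] <- map[labels[pos]]
  out
}

plane_objects_from_labels <- function(labels, pixel_size, class, t, z) {
  n <- max(labels)
  if (n == 0) {
    out <- empty_plane_objects(dim(labels), pixel_size, class, t, z)
    return(out)
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  row <- (idx - 1L) %% nrow(labels) + 1L
  col <- (idx - 1L) %/% nrow(labels) + 1L
  npx <- tabulate(lab, n)
  # pixel-centre convention: pixel (row, col) centre = (col - 0.5, row - 0.5) px
  x_um <- (vapply(split(col, lab), mean, numeric(1)) - 0.5) * pixel_size
  y_um <- (vapply(split(row, lab), mean, numeric(1)) - 0.5) * pixel_size
  out <- tibble(t = as.integer(t), z = as.integer(z), class = class,
                label = seq_len(n), x_um = unname(x_um), y_um = unname(y_um),
                area_um2 = npx * pixel_size^2)
  attr(out, "labels") <- labels
  attr(out, "pixel_size") <- pixel_size
  attr(out, "t") <- as.integer(t)
  attr(out, "z") <- as.integer(z)
  structure(out, class = c("plane_objects", class(out)))
}

#' Build the tumoroid boundary mask from nuclei detections
#'
#' Union of nucleus footprints, morphologically closed with a disc of the
#' given radius and hole-filled: the per-plane tumoroid boundary within
#' which killing and T-cell recruitment are scored. Adding nuclei can only
#' grow the mask.
#'
#' @param nuclei a `plane_objects` result for the nuclei channel.
#' @param closing_radius_um closing disc radius, um.
#' @param fill_holes fill enclosed background regions.
#' @return A logical `Y x X` matrix of class `tumoroid_mask` with
#'   `attr(, "pixel_size")`.
#' @export
build_tumoroid_mask <- function(nuclei, closing_radius_um = 15,
                                fill_holes = TRUE) {
  labels <- attr(nuclei, "labels")
  px <- attr(nuclei, "pixel_size")
  if (is.null(labels) || is.null(px)) {
    abort("`nuclei` must carry a label grid (from segment_objects()).")
  }
  mask <- labels > 0
  if (any(mask) && closing_radius_um > 0) {
    r_px <- max(1L, round(closing_radius_um / px))
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    mask <- EBImage::closing(EBImage::Image(mask * 1), brush) > 0.5
    mask <- matrix(as.logical(mask), nrow(labels), ncol(labels))
  }
  if (fill_holes && any(mask)) {
    mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
    mask <- matrix(as.logical(mask), nrow(labels), ncol(labels))
  }
  attr(mask, "pixel_size") <- px
  structure(mask, class = c("tumoroid_mask", class(mask)))
}

#' Split T-cell detections by tumoroid membership
#'
#' A T-cell belongs to the tumoroid iff its centroid falls on a mask-true
#' pixel (centroid-in-mask rule); a centroid exactly on a boundary pixel
#' counts as inside. Counts are conserved: `inside` plus `outside` rows
#' equal the input rows.
#'
#' @param tcells a `plane_objects` result for the T-cell channel.
#' @param mask a [build_tumoroid_mask()] result from the same plane geometry.
#' @return A list with `plane_objects` tibbles `inside` and `outside`.
#' @export
mask_tcells <- function(tcells, mask) {
  labels <- attr(tcells, "labels")
  px <- attr(tcells, "pixel_size")
  if (!is.null(labels) && !identical(dim(labels), dim(mask))) {
    abort("T-cell plane and mask have different grid shapes.")
  }
  if (nrow(tcells) == 0) {
    return(list(inside = tcells, outside = tcells))
  }
  col <- pmin(pmax(floor(tcells$x_um / px) + 1L, 1L), ncol(mask))
  row <- pmin(pmax(floor(tcells$y_um / px) + 1L, 1L), nrow(mask))
  inside <- mask[cbind(row, col)]
  res_in <- tcells[inside, , drop = FALSE]
  res_out <- tcells[!inside, , drop = FALSE]
  for (nm in c("labels", "pixel_size")) {
    attr(res_in, nm) <- attr(tcells, nm)
    attr(res_out, nm) <- attr(tcells, nm)
  }
  list(inside = res_in, outside = res_out)
}
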