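test_that("a blank plane yields zero objects, not an error", {
  ob <- segment_objects(matrix(0, 40, 40), pixel_size = 2)
  expect_equal(nrow(ob), 0)
  expect_equal(dim(attr(ob, "labels")), c(40, 40))
})

test_that("disjoint blobs are found with centroids within one pixel", {
  centers <- rbind(c(10, 10), c(30, 12), c(50, 15), c(20, 40), c(45, 45))
  pl <- blob_plane(60, 60, centers, sigma_px = 2.5)
  ob <- segment_objects(pl, pixel_size = 2, smoothing_sigma_um = 2,
                        threshold = 0.2, min_area_um2 = 10)
  expect_equal(nrow(ob), 5)
  # compare detected centroids (um, pixel-centre convention) to truth
  got <- cbind(ob$x_um / 2 + 0.5, ob$y_um / 2 + 0.5)
  d <- sqrt(outer(got[, 1], centers[, 1], "-")^2 +
            outer(got[, 2], centers[, 2], "-")^2)
  expect_lt(max(apply(d, 1, min)), 1)
})

test_that("watershed splits touching blobs with distinct cores", {
  centers <- rbind(c(28, 30), c(38, 30))   # 10 px apart, sigma 3.5: merged
  pl <- blob_plane(60, 60, centers, sigma_px = 3.5)
  merged <- segment_objects(pl, pixel_size = 2, threshold = 0.15,
                            split_touching = FALSE, min_area_um2 = 10)
  split <- segment_objects(pl, pixel_size = 2, threshold = 0.15,
                           split_touching = TRUE, min_area_um2 = 10)
  expect_equal(nrow(merged), 1)
  expect_equal(nrow(split), 2)
})

test_that("object labelling is deterministic", {
  pl <- blob_plane(50, 50, rbind(c(15, 15), c(35, 35)), sigma_px = 2.5)
  a <- segment_objects(pl, pixel_size = 2, threshold = 0.2)
  b <- segment_objects(pl, pixel_size = 2, threshold = 0.2)
  expect_identical(attr(a, "labels"), attr(b, "labels"))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("tumoroid mask is a closed superset of nucleus footprints", {
  none <- segment_objects(matrix(0, 40, 40), pixel_size = 2)
  expect_false(any(build_tumoroid_mask(none)))

  pl <- blob_plane(60, 60, rbind(c(30, 30)), sigma_px = 3)
  one <- segment_objects(pl, pixel_size = 2, threshold = 0.2)
  mask <- build_tumoroid_mask(one)
  expect_true(all(mask[attr(one, "labels") > 0]))

  # adding a nucleus never shrinks the mask
  pl2 <- pl + blob_plane(60, 60, rbind(c(42, 30)), sigma_px = 3)
  two <- segment_objects(pl2, pixel_size = 2, threshold = 0.2)
  mask2 <- build_tumoroid_mask(two)
  expect_true(all(mask2[mask]))
})

test_that("mid-plane mask area of the synthetic tumoroid matches the disc", {
  sc <- assay_scenario(seed = 6)
  ine <- scenario_ineffective(sc)
  gt <- simulate_tcells(sc, ine$motility, ine$killing)
  st <- render_frames(gt, timepoints = 1)
  pl <- get_plane(st, 1, 10, "nuclei")  # plane centred at z = 95 um
  nuc <- segment_objects(pl, st$lateral_pixel_size, threshold = 0.1)
  mask <- build_tumoroid_mask(nuc)
  area <- sum(mask) * st$lateral_pixel_size^2
  expect_equal(area, pi * 75^2, tolerance = 0.15)
})

test_that("T-cell masking partitions detections by the centroid rule", {
  mask <- matrix(FALSE, 40, 40)
  mask[1:20, 1:40] <- TRUE              # upper half (y < 40 um) inside
  attr(mask, "pixel_size") <- 2
  class(mask) <- c("tumoroid_mask", class(mask))
  centers <- rbind(c(10, 5), c(20, 10), c(30, 15), c(10, 30), c(30, 35))
  pl <- blob_plane(40, 40, centers, sigma_px = 1.8)
  tc <- segment_objects(pl, pixel_size = 2, threshold = 0.2,
                        min_area_um2 = 5, class = "tcell")
  expect_equal(nrow(tc), 5)
  parts <- mask_tcells(tc, mask)
  expect_equal(nrow(parts$inside), 3)
  expect_equal(nrow(parts$outside), 2)
  expect_equal(nrow(parts$inside) + nrow(parts$outside), nrow(tc))

  empty <- mask & FALSE
  attr(empty, "pixel_size") <- 2
  parts0 <- mask_tcells(tc, empty)
  expect_equal(nrow(parts0$inside), 0)
  expect_equal(nrow(parts0$outside), 5)

  # centroid exactly on a mask-true boundary pixel counts as inside
  bmask <- matrix(FALSE, 10, 10)
  bmask[5, 5] <- TRUE
  attr(bmask, "pixel_size") <- 1
  fake <- tibble::tibble(t = 1L, z = 1L, class = "tcell", label = 1L,
                         x_um = 4.5, y_um = 4.5, area_um2 = 1)
  attr(fake, "labels") <- matrix(0L, 10, 10)
  attr(fake, "pixel_size") <- 1
  parts_b <- mask_tcells(fake, bmask)
  expect_equal(nrow(parts_b$inside), 1)
})

test_that("mismatched grids are rejected", {
  pl <- blob_plane(40, 40, rbind(c(20, 20)), sigma_px = 2)
  tc <- segment_objects(pl, pixel_size = 2, threshold = 0.2, class = "tcell")
  mask <- matrix(TRUE, 30, 30)
  attr(mask, "pixel_size") <- 2
  expect_error(mask_tcells(tc, mask), "shape")
})

test_that("detection recall and precision exceed 95% at default noise", {
  # well-separated cells on a jittered grid, default rendering noise
  set.seed(17)
  grid <- expand.grid(x = seq(25, 375, by = 35), y = seq(25, 375, by = 35))
  keep <- sample(nrow(grid), 60)
  xyz <- cbind(grid$x[keep], grid$y[keep], runif(60, 25, 175))
  sc <- assay_scenario(n_nuclei = 0, n_tcells = 60, n_frames = 1, seed = 8)
  gt <- manual_ground_truth(sc, matrix(numeric(), 0, 3), tcell_xyz = xyz)
  st <- render_frames(gt, rng_seed = 8)
  det <- detect_3d(get_volume(st, 1, "tcell"), st$lateral_pixel_size,
                   st$z_step, threshold = 0.1)
  d <- sqrt(outer(det$x_um, xyz[, 1], "-")^2 +
            outer(det$y_um, xyz[, 2], "-")^2 +
            outer(det$z_um, xyz[, 3], "-")^2)
  tp <- sum(apply(d, 1, min) < 12)
  recall <- tp / nrow(xyz)
  precision <- tp / nrow(det)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
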