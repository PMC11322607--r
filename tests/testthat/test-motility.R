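test_that("MSD matches hand-computed and closed-form examples", {
  tr <- tibble::tibble(t_h = 0:2, x_um = c(0, 1, 3), y_um = 0, z_um = 0)
  curve <- compute_msd(tr, max_lag_h = 2)
  expect_equal(curve$msd_um2, c(2.5, 9))
  expect_equal(curve$n_pairs, c(2L, 1L))

  tb <- tibble::tibble(t_h = 0:10, x_um = 3 * (0:10), y_um = 0, z_um = 0)
  cb <- compute_msd(tb, max_lag_h = 5)
  expect_equal(cb$msd_um2, 9 * (1:5)^2)

  ts <- tibble::tibble(t_h = 0:10, x_um = 4, y_um = -2, z_um = 7)
  expect_true(all(compute_msd(ts, max_lag_h = 5)$msd_um2 == 0))

  expect_error(compute_msd(tr, max_lag_h = 5), "duration")
})

test_that("MSD equals the brute-force all-pairs average on random tracks", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    xyz <- matrix(cumsum(rnorm(3 * n)), n, 3)
    tr <- tibble::tibble(t_h = seq_len(n) - 1, x_um = xyz[, 1],
                         y_um = xyz[, 2], z_um = xyz[, 3])
    max_k <- sample(seq_len(n - 1), 1)
    got <- compute_msd(tr, max_lag_h = max_k)$msd_um2
    want <- bf_msd(xyz, 1, max_k)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("the MSD model fit recovers exact curves to machine precision", {
  tau <- 1:5
  f <- fit_msd(tibble::tibble(lag_h = tau, msd_um2 = 8 * tau + tau^2))
  expect_equal(f$D_um2_h, 2, tolerance = 1e-12)
  expect_equal(f$v_um_h, 1, tolerance = 1e-12)

  fb <- fit_msd(tibble::tibble(lag_h = tau, msd_um2 = 9 * tau^2))
  expect_equal(fb$D_um2_h, 0, tolerance = 1e-12)
  expect_equal(fb$v_um_h, 3, tolerance = 1e-12)

  fd <- fit_msd(tibble::tibble(lag_h = tau, msd_um2 = 12 * tau))
  expect_equal(fd$D_um2_h, 3, tolerance = 1e-12)
  expect_equal(fd$v_um_h, 0, tolerance = 1e-12)

  expect_error(fit_msd(tibble::tibble(lag_h = 1:2, msd_um2 = 1:2)), "lags")
})

test_that("fitted coefficients are never negative on noisy decreasing curves", {
  set.seed(5)
  for (i in 1:20) {
    tau <- 1:10
    y <- pmax(0, 5 * tau - 0.4 * tau^2 + rnorm(10))  # concave: b would go < 0
    f <- fit_msd(tibble::tibble(lag_h = tau, msd_um2 = y))
    expect_gte(f$D_um2_h, 0)
    expect_gte(f$v_um_h, 0)
  }
})

test_that("diffusive fraction follows the closed form and its limits", {
  expect_equal(diffusive_fraction(2, 1, t_D = 10), 1 / (1 + 10 / 8))
  expect_equal(diffusive_fraction(5, 0, t_D = 10), 1)
  expect_equal(diffusive_fraction(0, 2, t_D = 10), 0)
  expect_true(is.na(diffusive_fraction(0, 0, t_D = 10)))
  expect_error(diffusive_fraction(1, 1, t_D = 0), "> 0")
})

test_that("diffusive fraction is monotone in D, v and t_D", {
  set.seed(3)
  for (i in 1:50) {
    D <- runif(1, 0.1, 10); v <- runif(1, 0.1, 10); td <- runif(1, 1, 30)
    f <- diffusive_fraction(D, v, td)
    expect_true(f >= 0 && f <= 1)
    expect_gt(diffusive_fraction(D * 1.5, v, td), f)   # increasing in D
    expect_lt(diffusive_fraction(D, v * 1.5, td), f)   # decreasing in v
    expect_lt(diffusive_fraction(D, v, td * 1.5), f)   # decreasing in t_D
  }
})

test_that("fits are scale covariant: x -> s x gives D -> s^2 D, v -> s v", {
  trj <- simulate_trajectories(5, d_axis = 2, speed = 1, n_frames = 40,
                               rng_seed = 14)
  fits <- fit_trajectories(trj)
  s <- 2.5
  scaled <- dplyr::mutate(trj, x_um = s * x_um, y_um = s * y_um,
                          z_um = s * z_um)
  fits_s <- fit_trajectories(scaled)
  expect_equal(fits_s$D_um2_h, s^2 * fits$D_um2_h, tolerance = 1e-9)
  expect_equal(fits_s$v_um_h, s * fits$v_um_h, tolerance = 1e-9)
})

test_that("population MSD averages per-cell curves", {
  b1 <- tibble::tibble(cell_id = 1, t_h = 0:10, x_um = 1 * (0:10),
                       y_um = 0, z_um = 0)
  b3 <- tibble::tibble(cell_id = 2, t_h = 0:10, x_um = 3 * (0:10),
                       y_um = 0, z_um = 0)
  pop <- population_msd(dplyr::bind_rows(b1, b3), max_lag_h = 5)
  expect_equal(pop$msd_um2, 5 * (1:5)^2)   # (1 + 9)/2 = 5
  expect_equal(pop$n, rep(2L, 5))

  ident <- dplyr::bind_rows(b1, dplyr::mutate(b1, cell_id = 2))
  pop_i <- population_msd(ident, max_lag_h = 5)
  expect_equal(pop_i$sd_um2, rep(0, 5))

  # unequal track lengths: n non-increasing with lag
  short <- dplyr::filter(b3, t_h <= 3) |> dplyr::mutate(cell_id = 3)
  pop_u <- population_msd(dplyr::bind_rows(b1, b3, short), max_lag_h = 8)
  expect_true(all(diff(pop_u$n) <= 0))
})

test_that("population summary reports medians, SDs and exclusions", {
  fits <- tibble::tibble(cell_id = 1:3, D_um2_h = c(1, 2, 3),
                         v_um_h = c(0, 1, 2), fD = c(1, 0.5, NA),
                         residual = 0, n_lags = 5)
  s <- summarize_population(fits)
  expect_equal(s$median[s$parameter == "D_um2_h"], 2)
  expect_equal(s$n[s$parameter == "fD"], 2)
  expect_equal(s$n_excluded[s$parameter == "fD"], 1)

  single <- summarize_population(fits[1, ])
  expect_equal(single$sd, rep(0, 3))
})

test_that("diffusive vs directed populations are distinguished end to end", {
  diff_trj <- simulate_trajectories(100, d_axis = 1, speed = 0,
                                    n_frames = 72, rng_seed = 31)
  dir_trj <- simulate_trajectories(100, d_axis = 1, speed = 3,
                                   n_frames = 72, rng_seed = 32)
  fd_diff <- fit_trajectories(diff_trj)$fD
  fd_dir <- fit_trajectories(dir_trj)$fD
  expect_gt(median(fd_diff, na.rm = TRUE), 0.8)
  expect_lt(median(fd_dir, na.rm = TRUE), 0.5)
  cmp <- compare_fd(data = tibble::tibble(
    fD = c(fd_diff, fd_dir),
    group = rep(c("diffusive", "directed"), each = 100)))
  expect_lt(cmp$kruskal$p_value, 0.05)
})

test_that("Kruskal-Wallis/Dunn behaviour on degenerate and shifted groups", {
  ident <- tibble::tibble(fD = rep(0.5, 20),
                          group = rep(c("a", "b"), each = 10))
  cmp <- compare_fd(ident)
  expect_equal(cmp$kruskal$statistic, 0)
  expect_equal(cmp$kruskal$p_value, 1)

  set.seed(44)
  a <- rnorm(25, 0, 1)
  b <- rnorm(35, 5, 1)   # shifted by 5 SD; group sizes as in the assay
  cmp2 <- compare_fd(tibble::tibble(fD = c(a, b),
                                    group = rep(c("a", "b"), c(25, 35))))
  expect_lt(cmp2$kruskal$p_value, 0.05)
  expect_true(all(cmp2$dunn$p_adj >= cmp2$dunn$p_raw))

  expect_error(compare_fd(tibble::tibble(fD = 1:4,
                                         group = c("a", "a", "a", "b"))),
               "n >= 3")
})

test_that("Dunn z agrees with an independent rank-statistic computation", {
  set.seed(8)
  x <- c(rnorm(10), rnorm(12, 1), rnorm(9, 2))
  g <- rep(c("g1", "g2", "g3"), c(10, 12, 9))
  dn <- tumoroidtk:::dunn_test(x, g)
  # independent computation from the Kruskal-Wallis rank machinery
  N <- length(x); r <- rank(x)
  tie <- table(r); C <- sum(tie^3 - tie) / (12 * (N - 1))
  for (j in seq_len(nrow(dn))) {
    i1 <- g == dn$group1[j]; i2 <- g == dn$group2[j]
    se <- sqrt((N * (N + 1) / 12 - C) * (1 / sum(i1) + 1 / sum(i2)))
    z <- (mean(r[i1]) - mean(r[i2])) / se
    expect_equal(dn$z[j], z, tolerance = 1e-12)
    expect_equal(dn$p_raw[j], 2 * pnorm(-abs(z)), tolerance = 1e-12)
  }
})

test_that("tidiers expose fit and test results as tibbles", {
  tau <- 1:5
  f <- fit_msd(tibble::tibble(lag_h = tau, msd_um2 = 8 * tau + tau^2))
  td <- tidy(f)
  expect_equal(td$estimate, c(2, 1))
  gl <- glance(f)
  expect_equal(gl$n_lags, 5)
  cmp <- compare_fd(tibble::tibble(fD = c(rnorm(5), rnorm(5, 3)),
                                   group = rep(c("a", "b"), each = 5)))
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(nrow(glance(cmp)), 1)
})
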