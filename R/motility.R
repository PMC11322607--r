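# MSD analysis: directed-plus-diffusive model fit and diffusive fraction.
#
# Model: msd(t_lag) = 4 D t_lag + v^2 t_lag^2, fitted to the time-averaged
# 3D MSD; the diffusive fraction at a fixed lag t_D is
# f_D = 1 / (1 + v^2 t_D / (4 D)).

traj_matrix <- function(traj) {
  if (!all(c("t_h", "x_um", "y_um", "z_um") %in% names(traj))) {
    abort("trajectory needs columns t_h, x_um, y_um, z_um.")
  }
  traj <- traj[order(traj$t_h), , drop = FALSE]
  dt <- diff(traj$t_h)
  if (length(dt) && (any(dt <= 0) ||
                     max(abs(dt - dt[1])) > 1e-6 * max(dt[1], 1))) {
    abort("trajectory timestamps must be strictly increasing and uniform.")
  }
  list(xyz = cbind(traj$x_um, traj$y_um, traj$z_um),
       interval = if (length(dt)) dt[1] else NA_real_)
}

#' Time-averaged mean squared displacement of one trajectory
#'
#' For each lag `tau = k * frame_interval`, averages the squared 3D
#' Euclidean displacement over all ordered position pairs separated by `tau`
#' (overlapping windows, the standard time-averaged estimator).
#'
#' @param traj a single-cell trajectory tibble (`t_h, x_um, y_um, z_um`,
#'   uniform spacing).
#' @param max_lag_h largest lag, h (must be below the track duration).
#' @return An `msd_curve` tibble: `lag_h, msd_um2, n_pairs`.
#' @examples
#' tr <- tibble::tibble(t_h = 0:2, x_um = c(0, 1, 3), y_um = 0, z_um = 0)
#' compute_msd(tr, max_lag_h = 2)  # msd(1) = 2.5, msd(2) = 9
#' @export
compute_msd <- function(traj, max_lag_h = 25) {
  tm <- traj_matrix(traj)
  n <- nrow(tm$xyz)
  if (n < 2) abort("trajectory needs >= 2 points.")
  max_k <- floor(max_lag_h / tm$interval + 1e-9)
  if (max_k < 1 || max_k >= n) {
    abort("`max_lag_h` must be at least one frame and below track duration.")
  }
  xyz <- tm$xyz
  msd <- numeric(max_k)
  npairs <- integer(max_k)
  for (k in seq_len(max_k)) {
    disp <- xyz[(k + 1):n, , drop = FALSE] - xyz[1:(n - k), , drop = FALSE]
    msd[k] <- mean(rowSums(disp^2))
    npairs[k] <- n - k
  }
  structure(
    tibble(lag_h = seq_len(max_k) * tm$interval, msd_um2 = msd,
           n_pairs = npairs),
    class = c("msd_curve", class(tibble())))
}

#' Fit the directed-plus-diffusive MSD model
#'
#' Unweighted least-squares fit of `msd(tau) = 4 D tau + v^2 tau^2` with
#' both coefficients constrained non-negative: the unconstrained two-term
#' linear solution is used when admissible, otherwise the best of the
#' clipped one-term solutions (pure diffusion, pure drift, or zero). Optional
#' `weights = "pairs"` weights lags by their pair counts.
#'
#' @param curve an [compute_msd()] result (or any tibble with `lag_h` and
#'   `msd_um2`).
#' @param weights `"none"` (default) or `"pairs"`.
#' @return A `motility_fit` list: `D_um2_h`, `v_um_h`, `residual` (RSS),
#'   `n_lags`.
#' @export
fit_msd <- function(curve, weights = c("none", "pairs")) {
  weights <- match.arg(weights)
  tau <- curve$lag_h
  y <- curve$msd_um2
  if (length(tau) < 3) abort("need >= 3 lags to fit the MSD model.")
  w <- if (weights == "pairs" && "n_pairs" %in% names(curve)) {
    curve$n_pairs
  } else rep(1, length(tau))
  X <- cbind(tau, tau^2)
  rss <- function(coef) sum(w * (y - X %*% coef)^2)
  sw <- sqrt(w)
  full <- tryCatch(qr.solve(sw * X, sw * y), error = function(e) c(-1, -1))
  cands <- list()
  if (all(full >= -1e-12)) cands <- c(cands, list(pmax(full, 0)))
  a1 <- max(0, sum(w * tau * y) / sum(w * tau^2))
  b1 <- max(0, sum(w * tau^2 * y) / sum(w * tau^4))
  cands <- c(cands, list(c(a1, 0), c(0, b1), c(0, 0)))
  best <- unname(cands[[which.min(vapply(cands, rss, numeric(1)))]])
  structure(
    list(D_um2_h = best[1] / 4, v_um_h = sqrt(best[2]),
         residual = rss(best), n_lags = length(tau)),
    class = "motility_fit")
}

#' @export
print.motility_fit <- function(x, ...) {
  cat(sprintf("<motility_fit> D = %.4g um^2/h, v = %.4g um/h (%d lags, RSS %.3g)\n",
              x$D_um2_h, x$v_um_h, x$n_lags, x$residual))
  invisible(x)
}

#' Diffusive fraction of the MSD at a fixed lag
#'
#' `f_D = 1 / (1 + v^2 t_D / (4 D))`: the share of the MSD at lag `t_D`
#' (default 10 h) explained by the diffusive term. Near 1 for random
#' motility, near 0 for directed migration. Limits: `v = 0` gives 1,
#' `D = 0` with `v > 0` gives 0, and `D = v = 0` is undefined (`NA`).
#'
#' @param fit a `motility_fit`, or a numeric `D` (with `v` supplied).
#' @param v directed speed, um/h (when `fit` is numeric).
#' @param t_D evaluation lag, h.
#' @return The diffusive fraction in `[0, 1]`, or `NA` when undefined.
#' @export
diffusive_fraction <- function(fit, v = NULL, t_D = 10) {
  if (!is.finite(t_D) || t_D <= 0) abort("`t_D` must be > 0.")
  if (inherits(fit, "motility_fit")) {
    D <- fit$D_um2_h
    v <- fit$v_um_h
  } else {
    D <- as.numeric(fit)
    if (is.null(v)) abort("supply `v` when `fit` is a numeric D.")
  }
  if (D < 0 || v < 0) abort("`D` and `v` must be >= 0.")
  if (D == 0 && v == 0) return(NA_real_)
  if (v == 0) return(1)
  if (D == 0) return(0)
  1 / (1 + v^2 * t_D / (4 * D))
}

#' Per-cell MSD fits for a trajectory table
#'
#' Runs [compute_msd()], [fit_msd()] and [diffusive_fraction()] for every
#' cell in a trajectory tibble. The per-cell lag range is `1..max_lag_h`
#' frames, capped at half the track length to avoid the noisy high-lag tail.
#'
#' @param trajectories trajectory tibble (`cell_id, t_h, x_um, y_um, z_um`).
#' @param max_lag_h largest MSD lag, h.
#' @param t_D diffusive-fraction lag, h.
#' @param weights passed to [fit_msd()].
#' @return A tibble `cell_id, D_um2_h, v_um_h, fD, residual, n_lags`.
#' @export
fit_trajectories <- function(trajectories, max_lag_h = 25, t_D = 10,
                             weights = "none") {
  trajectories |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 7) return(tibble())   # need >= 3 lags at the half-length cap
      interval <- diff(sort(df$t_h))[1]
      cap <- floor(n / 2) * interval
      curve <- compute_msd(df, max_lag_h = min(max_lag_h, cap))
      fit <- fit_msd(curve, weights = weights)
      tibble(D_um2_h = fit$D_um2_h, v_um_h = fit$v_um_h,
             fD = diffusive_fraction(fit, t_D = t_D),
             residual = fit$residual, n_lags = fit$n_lags)
    }) |>
    dplyr::ungroup()
}

#' Population-level MSD curve
#'
#' Per lag, the mean of the per-trajectory time-averaged MSDs across the
#' population, with SD and the number of contributing trajectories (tracks
#' shorter than a lag do not contribute there).
#'
#' @param trajectories trajectory tibble.
#' @param max_lag_h largest lag, h.
#' @return A tibble `lag_h, msd_um2, sd_um2, n`.
#' @export
population_msd <- function(trajectories, max_lag_h = 30) {
  ids <- unique(trajectories$cell_id)
  if (length(ids) < 2) abort("need >= 2 trajectories.")
  curves <- purrr::map_dfr(ids, function(id) {
    df <- trajectories[trajectories$cell_id == id, , drop = FALSE]
    n <- nrow(df)
    if (n < 2) return(tibble())
    interval <- diff(sort(df$t_h))[1]
    lag_max <- min(max_lag_h, (n - 1) * interval)
    dplyr::mutate(compute_msd(df, max_lag_h = lag_max), cell_id = id)
  })
  curves |>
    dplyr::group_by(.data$lag_h) |>
    dplyr::summarise(sd_um2 = if (dplyr::n() > 1) sd(.data$msd_um2) else 0,
                     msd_um2 = mean(.data$msd_um2),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::select("lag_h", "msd_um2", "sd_um2", "n")
}

#' Median / SD population summary of motility parameters
#'
#' @param fits a [fit_trajectories()] tibble.
#' @return A tibble `parameter, median, sd, n` over `D_um2_h, v_um_h, fD`;
#'   fits with undefined `fD` are excluded from the `fD` row and their count
#'   reported in `n_excluded` (attribute and column).
#' @export
summarize_population <- function(fits) {
  if (!nrow(fits)) abort("no fits to summarise.")
  one <- function(x, name) {
    ok <- is.finite(x)
    tibble(parameter = name,
           median = median(x[ok]),
           sd = if (sum(ok) > 1) sd(x[ok]) else 0,
           n = sum(ok),
           n_excluded = sum(!ok))
  }
  dplyr::bind_rows(one(fits$D_um2_h, "D_um2_h"),
                   one(fits$v_um_h, "v_um_h"),
                   one(fits$fD, "fD"))
}

# Dunn's rank-based post-hoc z statistics with tie correction; no
# pre-installed R implementation exists, so it is computed from first
# principles and cross-checked in the test-suite.
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p_raw <- numeric(ncol(pairs))
  s2 <- N * (N + 1) / 12 - tie_corr
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(s2 * (1 / ni[[a]] + 1 / ni[[b]]))
    z[j] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p_raw[j] <- 2 * pnorm(-abs(z[j]))
  }
  tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
         p_raw = p_raw, p_adj = p.adjust(p_raw, method = p_adjust))
}

#' Compare diffusive fractions between groups
#'
#' Non-parametric Kruskal-Wallis test across groups followed by Dunn's
#' pairwise post-hoc comparisons (Bonferroni-adjusted by default).
#'
#' @param data tibble with columns `fD` and `group` (or supply two numeric
#'   vectors via `...` as `group_a =`, `group_b =` named arguments).
#' @param p_adjust p-adjustment method for Dunn's test.
#' @param ... named numeric vectors, an alternative to `data`.
#' @return A list of class `fd_comparison`: `kruskal` (tibble `statistic,
#'   df, p_value`) and `dunn` (pairwise tibble).
#' @export
compare_fd <- function(data = NULL, p_adjust = "bonferroni", ...) {
  if (is.null(data)) {
    vecs <- list(...)
    if (length(vecs) < 2) abort("need >= 2 groups.")
    data <- purrr::imap_dfr(vecs, ~ tibble(fD = .x, group = .y))
  }
  if (!all(c("fD", "group") %in% names(data))) {
    abort("`data` needs `fD` and `group` columns.")
  }
  data <- data[is.finite(data$fD), , drop = FALSE]
  counts <- table(data$group)
  if (length(counts) < 2) abort("need >= 2 groups.")
  if (min(counts) < 3) abort("need n >= 3 per group.")
  if (dplyr::n_distinct(data$fD) == 1) {
    kw <- tibble(statistic = 0, df = length(counts) - 1, p_value = 1)
  } else {
    k <- kruskal.test(data$fD, factor(data$group))
    kw <- tibble(statistic = unname(k$statistic), df = unname(k$parameter),
                 p_value = k$p.value)
  }
  structure(
    list(kruskal = kw,
         dunn = dunn_test(data$fD, data$group, p_adjust = p_adjust)),
    class = "fd_comparison")
}

#' @export
print.fd_comparison <- function(x, ...) {
  cat(sprintf("<fd_comparison> Kruskal-Wallis H = %.4g (df %d), p = %.3g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p_value))
  cat("Dunn post-hoc:\n")
  print(x$dunn)
  invisible(x)
}
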