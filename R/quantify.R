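# Killing fraction and in-tumoroid T-cell counts (per plane -> per stack).

#' Relate PI objects to nuclei (dead-cell calling)
#'
#' Assigns each PI (dead-cell dye) object to the nucleus whose footprint
#' contains the PI centroid; PI objects over background are discarded. A
#' nucleus is dead iff at least one PI object is assigned to it.
#'
#' @param pi a `plane_objects` result for the PI channel.
#' @param nuclei a `plane_objects` result for the nuclei channel of the same
#'   plane.
#' @return Integer vector of dead nucleus labels (unique, sorted).
#' @export
relate_pi <- function(pi, nuclei) {
  labels <- attr(nuclei, "labels")
  px <- attr(nuclei, "pixel_size")
  if (is.null(labels)) abort("`nuclei` must carry a label grid.")
  if (nrow(pi) == 0 || !any(labels > 0)) return(integer())
  col <- pmin(pmax(floor(pi$x_um / px) + 1L, 1L), ncol(labels))
  row <- pmin(pmax(floor(pi$y_um / px) + 1L, 1L), nrow(labels))
  parents <- labels[cbind(row, col)]
  sort(unique(parents[parents > 0L]))
}

#' Per-plane counts of nuclei, dead nuclei and in-tumoroid T-cells
#'
#' @param nuclei,pi nuclei / PI `plane_objects` for one plane.
#' @param tcells_inside the `inside` component of [mask_tcells()] for the
#'   same plane.
#' @return A one-row tibble `t, z, n_nuclei, n_dead_nuclei, n_tcells_inside`.
#' @export
plane_counts <- function(nuclei, pi, tcells_inside) {
  tz <- unique(rbind(nuclei[c("t", "z")], pi[c("t", "z")],
                     tcells_inside[c("t", "z")]))
  if (nrow(tz) > 1) abort("objects come from different (t, z) planes.")
  if (nrow(tz) == 0) {
    # empty plane: fall back to the indices recorded at segmentation time
    tz <- tibble(t = attr(nuclei, "t") %||% NA_integer_,
                 z = attr(nuclei, "z") %||% NA_integer_)
  }
  dead <- relate_pi(pi, nuclei)
  tibble(t = tz$t[1], z = tz$z[1],
         n_nuclei = nrow(nuclei),
         n_dead_nuclei = length(dead),
         n_tcells_inside = nrow(tcells_inside))
}

#' Aggregate per-plane counts into whole-tumoroid readouts
#'
#' The two assay readouts: the killing fraction is the fraction of
#' PI-positive nuclei over the entire tumoroid (all planes pooled), and the
#' T-cell recruitment count is the sum over z-sections of in-tumoroid T-cell
#' detections. Timepoints whose planes contain no nuclei get killing
#' fraction 0 with `zero_denominator = TRUE`.
#'
#' @param counts a tibble of [plane_counts()] rows (one or more timepoints).
#' @return A `tumoroid_ts` tibble: `t, killing_fraction, tcell_count,
#'   zero_denominator`.
#' @export
aggregate_stack <- function(counts) {
  if (!nrow(counts)) abort("no plane counts to aggregate.")
  out <- counts |>
    dplyr::group_by(t = .data$t) |>
    dplyr::summarise(
      killing_fraction = ifelse(sum(.data$n_nuclei) > 0,
                                sum(.data$n_dead_nuclei) / sum(.data$n_nuclei),
                                0),
      tcell_count = sum(.data$n_tcells_inside),
      zero_denominator = sum(.data$n_nuclei) == 0,
      .groups = "drop"
    )
  structure(out, class = c("tumoroid_ts", class(out)))
}

#' Normalise killing to a positive control
#'
#' Expresses killing as a percentage of the mean positive-control (e.g.
#' cisplatin) killing fraction; values may exceed 100.
#'
#' @param series a `tumoroid_ts` tibble (or any tibble with a
#'   `killing_fraction` column).
#' @param positive_control_fraction killing fraction(s) of the positive
#'   control; the mean of replicates is used.
#' @return `series` with an added `killing_normalized_pct` column.
#' @export
normalize_killing <- function(series, positive_control_fraction) {
  ctrl <- mean(positive_control_fraction)
  if (!is.finite(ctrl) || ctrl <= 0) {
    abort("positive-control killing fraction must be > 0.")
  }
  dplyr::mutate(series,
                killing_normalized_pct = 100 * .data$killing_fraction / ctrl)
}

#' Compare killing between conditions (two-way ANOVA + Bonferroni)
#'
#' Two-way analysis of variance of normalised killing on condition and
#' concentration, followed by Bonferroni-adjusted pairwise comparisons of
#' each condition against a designated reference, within each concentration
#' (via estimated marginal means). With a single concentration level a
#' one-way ANOVA is fitted.
#'
#' @param data tibble with columns `killing`, `condition` and optionally
#'   `concentration`; one row per replicate.
#' @param reference condition to compare against (default: first level).
#' @return A list of class `killing_comparison`: `anova` (tidy ANOVA table)
#'   and `contrasts` (pairwise tibble with `p_adj`).
#' @export
compare_killing <- function(data, reference = NULL) {
  if (!all(c("killing", "condition") %in% names(data))) {
    abort("`data` needs `killing` and `condition` columns.")
  }
  data$condition <- factor(data$condition)
  if (nlevels(data$condition) < 2) {
    abort("need at least two condition levels.")
  }
  if (min(table(data$condition)) < 2) {
    abort("need at least two replicates per condition.")
  }
  reference <- reference %||% levels(data$condition)[1]
  data$condition <- stats::relevel(data$condition, ref = as.character(reference))
  two_way <- "concentration" %in% names(data) &&
    dplyr::n_distinct(data$concentration) > 1
  if (two_way) {
    data$concentration <- factor(data$concentration)
    fit <- aov(killing ~ condition * concentration, data = data)
    emm <- emmeans::emmeans(fit, ~ condition | concentration)
  } else {
    fit <- aov(killing ~ condition, data = data)
    emm <- emmeans::emmeans(fit, ~ condition)
  }
  ctr <- as.data.frame(
    emmeans::contrast(emm, method = "trt.vs.ctrl", ref = 1,
                      adjust = "bonferroni"))
  names(ctr)[names(ctr) == "p.value"] <- "p_adj"
  # identical groups with zero residual variance: no evidence of difference
  degenerate <- !is.finite(ctr$p_adj) & abs(ctr$estimate) < 1e-12
  ctr$p_adj[degenerate] <- 1
  an <- as.data.frame(summary(fit)[[1]])
  an <- tibble(term = trimws(rownames(an)), df = an$Df, sumsq = an$`Sum Sq`,
               statistic = an$`F value`, p_value = an$`Pr(>F)`)
  structure(list(anova = an, contrasts = as_tibble(ctr),
                 reference = as.character(reference)),
            class = "killing_comparison")
}

#' @export
print.killing_comparison <- function(x, ...) {
  cat("<killing_comparison> reference:", x$reference, "\n\nANOVA:\n")
  print(x$anova)
  cat("\nBonferroni contrasts vs reference:\n")
  print(x$contrasts)
  invisible(x)
}
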