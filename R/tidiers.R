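# broom-style tidiers for fitted objects and test tables.

#' @method tidy motility_fit
#' @export
tidy.motility_fit <- function(x, ...) {
  tibble(term = c("D", "v"),
         estimate = c(x$D_um2_h, x$v_um_h),
         unit = c("um^2/h", "um/h"))
}

#' @method glance motility_fit
#' @export
glance.motility_fit <- function(x, ...) {
  tibble(D_um2_h = x$D_um2_h, v_um_h = x$v_um_h,
         residual = x$residual, n_lags = x$n_lags)
}

#' @method tidy killing_comparison
#' @export
tidy.killing_comparison <- function(x, ...) x$contrasts

#' @method glance killing_comparison
#' @export
glance.killing_comparison <- function(x, ...) {
  an <- x$anova[!is.na(x$anova$statistic), , drop = FALSE]
  tibble(term = an$term, statistic = an$statistic, p_value = an$p_value)
}

#' @method tidy fd_comparison
#' @export
tidy.fd_comparison <- function(x, ...) x$dunn

#' @method glance fd_comparison
#' @export
glance.fd_comparison <- function(x, ...) x$kruskal
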