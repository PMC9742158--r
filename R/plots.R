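#' Plot an angular profile
#'
#' Cohort mean with across-subject SD bars versus fibre-to-field angle,
#' optionally overlaying a ground-truth angular T1 law.
#'
#' @param x an `angular_profile`.
#' @param law optional [angular_t1_law()] to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.angular_profile <- function(x, law = NULL, ...) {
  ok <- !is.na(x$mean)
  sdo <- ifelse(is.na(x$sd[ok]), 0, x$sd[ok])   # single subject: no spread
  ylim <- range(c(x$mean[ok] - sdo, x$mean[ok] + sdo,
                  if (!is.null(law)) eval_t1_law(law, x$centers)),
                na.rm = TRUE)
  graphics::plot(x$centers[ok], x$mean[ok], type = "b", pch = 16,
                 xlab = expression(theta[FB] ~ "(degrees)"),
                 ylab = x$quantity, ylim = ylim, ...)
  bar <- sdo > 0
  if (any(bar))
    graphics::arrows(x$centers[ok][bar], (x$mean[ok] - sdo)[bar],
                     x$centers[ok][bar], (x$mean[ok] + sdo)[bar],
                     angle = 90, code = 3, length = 0.03, col = "grey40")
  if (!is.null(law))
    graphics::lines(x$centers, eval_t1_law(law, x$centers),
                    col = "red3", lty = 2)
  invisible(x)
}
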