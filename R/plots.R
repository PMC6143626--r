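# Cosmetic figure helpers (base graphics); not part of the tested surface.

#' Plot an acquisition curve with its fitted models
#'
#' @param curve An `acquisition_curve`.
#' @param comparison Optional [compare_fits()] result whose fitted lines
#'   are overlaid.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `curve`.
#' @export
plot_curve <- function(curve, comparison = NULL, ...) {
  nz <- curve$counted > 0L
  graphics::plot(curve$bin_centre[nz], curve$probability[nz],
                 cex = 0.4 + 1.6 * sqrt(curve$counted[nz] /
                                          max(curve$counted[nz])),
                 pch = 16, col = grDevices::grey(0.35, 0.6),
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "variant frequency",
                 ylab = "adoption probability", ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  if (!is.null(comparison)) {
    xx <- seq(0, 1, length.out = 201)
    co <- comparison$linear$coefficients
    graphics::lines(xx, co[["intercept"]] + co[["slope"]] * xx,
                    col = "steelblue", lwd = 2)
    if (isTRUE(comparison$sigmoid_ok)) {
      cs <- comparison$sigmoid$coefficients
      yy <- if (comparison$sigmoid$model == "logistic2") {
        stats::plogis(cs[["a"]] + cs[["b"]] * xx)
      } else {
        xx^cs[["theta"]] / (xx^cs[["theta"]] + (1 - xx)^cs[["theta"]])
      }
      graphics::lines(xx, yy, col = "firebrick", lwd = 2)
    }
    graphics::legend("topleft", bty = "n",
                     legend = c("linear", "sigmoid"),
                     col = c("steelblue", "firebrick"), lwd = 2)
  }
  invisible(curve)
}

#' Plot a window sweep
#'
#' r-squared of the linear and sigmoid fits against history-window size
#' (log axis).
#'
#' @param sweep A [window_sweep()] table.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `sweep`.
#' @export
plot_sweep <- function(sweep, ...) {
  graphics::plot(sweep$window, sweep$r2_linear, type = "l", log = "x",
                 lwd = 2, ylim = range(c(sweep$r2_linear,
                                         sweep$r2_sigmoid), na.rm = TRUE),
                 xlab = "history window size (behaviours)",
                 ylab = expression(r^2), ...)
  graphics::lines(sweep$window, sweep$r2_sigmoid, lty = 2, lwd = 2)
  cross <- crossover_window(sweep)
  if (!is.na(cross)) graphics::abline(v = cross, col = "grey60", lty = 3)
  graphics::legend("bottomleft", bty = "n", lty = c(1, 2), lwd = 2,
                   legend = c("linear", "sigmoid"))
  invisible(sweep)
}
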