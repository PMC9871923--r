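# Base-graphics figures for the two report styles the analysis produces.

#' Dose-response plot with confidence band
#'
#' Scatter of pooled median RGR against cumulative light dose with the
#' zero-intercept fit line and its 95\% confidence band (dashed).
#'
#' @param fit a \linkS4class{DoseResponseFit}.
#' @param doses,medianRgrs the fitted points.
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plotDoseResponse <- function(fit, doses, medianRgrs, ...) {
  graphics::plot(doses, medianRgrs, pch = 19,
                 xlab = "cumulative light dose (mJ/mm^2)",
                 ylab = "median RGR", xlim = c(0, max(doses) * 1.05),
                 ylim = range(0, medianRgrs), ...)
  xs <- seq(0, max(doses) * 1.05, length.out = 50)
  graphics::lines(xs, fit@slope * xs)
  graphics::lines(xs, fit@ci95[1] * xs, lty = 2)
  graphics::lines(xs, fit@ci95[2] * xs, lty = 2)
  invisible(NULL)
}

#' Cumulative distribution of peak response amplitudes
#'
#' Empirical CDFs of per-cell peak dff (negative dips), one line per
#' recording plus the pooled distribution in bold.
#'
#' @param peaksByRecording list of numeric vectors, one per recording.
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plotResponseCdf <- function(peaksByRecording, ...) {
  pooled <- sort(unlist(peaksByRecording))
  graphics::plot(pooled, seq_along(pooled) / length(pooled), type = "n",
                 xlab = "peak response amplitude (dF/F0)",
                 ylab = "cumulative fraction", ...)
  for (p in peaksByRecording) {
    p <- sort(p)
    graphics::lines(p, seq_along(p) / length(p), lty = 2,
                    col = "grey50")
  }
  graphics::lines(pooled, seq_along(pooled) / length(pooled), lwd = 2)
  invisible(NULL)
}
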