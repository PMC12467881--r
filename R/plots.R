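#' Diagnostic plots
#'
#' `plotKDistance()` draws the ascending k-th-neighbour distance curve with
#' the automatically selected elbow; `plotAccuracyCurve()` the test accuracy
#' against feature count from incremental selection; `plotSpectra()` overlays
#' class-mean spectra.
#'
#' @param curve a `kDistanceCurve` from [kDistance()], or the `curve`
#'   data.frame from [selectIncremental()] / a [RunReport-class].
#' @param ... passed to the underlying base-graphics call.
#' @name diagnostics
NULL

#' @rdname diagnostics
#' @export
plotKDistance <- function(curve, ...) {
  graphics::plot(curve$distances, type = "l",
                 xlab = "sample (ascending)", ylab = sprintf("%d-NN distance", curve$k),
                 main = "K-distance graph", ...)
  graphics::abline(h = curve$suggestedEps, lty = 2, col = "red")
  graphics::mtext(sprintf("suggested eps = %.3g", curve$suggestedEps),
                  side = 3, line = 0, cex = 0.8)
  invisible(curve)
}

#' @rdname diagnostics
#' @export
plotAccuracyCurve <- function(curve, ...) {
  if (methods::is(curve, "RunReport")) curve <- curve@accuracyCurve
  graphics::plot(curve$n_features, curve$accuracy, type = "b",
                 xlab = "number of features", ylab = "test accuracy",
                 main = "Incremental feature selection", ...)
  best <- which.max(curve$accuracy)
  graphics::points(curve$n_features[best], curve$accuracy[best],
                   pch = 19, col = "red")
  invisible(curve)
}

#' @rdname diagnostics
#' @param x a labeled [SpectraSet-class].
#' @export
plotSpectra <- function(x, ...) {
  wl <- wavelengths(x)
  lb <- spectrumLabels(x)
  if (is.null(lb)) lb <- rep("all", ncol(x))
  classes <- unique(lb)
  mat <- intensities(x)
  means <- vapply(classes, function(cl)
    rowMeans(mat[, lb == cl, drop = FALSE]), numeric(nrow(mat)))
  graphics::matplot(wl, means, type = "l", lty = 1,
                    xlab = "wavelength (nm)", ylab = "intensity",
                    main = instrumentId(x), ...)
  graphics::legend("topright", legend = classes, lty = 1,
                   col = seq_along(classes), bty = "n")
  invisible(x)
}
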