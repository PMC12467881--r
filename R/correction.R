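#' Align spectra onto a new wavelength grid by linear interpolation
#'
#' Builds, for every spectrum, the piecewise-linear function through its
#' (wavelength, intensity) samples and evaluates it at `newGrid`. No
#' extrapolation: the new grid must lie within the source support.
#'
#' @param x a [SpectraSet-class].
#' @param newGrid strictly increasing wavelengths (nm) within
#'   `range(wavelengths(x))`.
#' @return a [SpectraSet-class] on `newGrid`.
#' @export
interpAlign <- function(x, newGrid) {
  wl <- wavelengths(x)
  if (min(newGrid) < min(wl) || max(newGrid) > max(wl))
    stop(sprintf(
      "extrapolation: new grid [%.4f, %.4f] exceeds source support [%.4f, %.4f]",
      min(newGrid), max(newGrid), min(wl), max(wl)))
  mat <- intensities(x)
  out <- apply(mat, 2L, function(col)
    stats::approx(wl, col, xout = newGrid)$y)
  out <- matrix(out, nrow = length(newGrid), ncol = ncol(mat),
                dimnames = list(NULL, colnames(mat)))
  SpectraSet(newGrid, out, instrument = instrumentId(x),
             colData = SummarizedExperiment::colData(x),
             metadata = as.list(S4Vectors::metadata(x)))
}

#' Estimate an instrument response function from a standard-lamp pair
#'
#' The measured lamp spectrum is the certified reference times the
#' instrument's wavelength-dependent sensitivity, so the ratio
#' `reference(lambda) / measured(lambda)` on their overlap recovers the
#' correction factor (the reciprocal sensitivity, up to the lamp's
#' arbitrary global scale). The measured spectrum is first aligned onto the
#' reference grid by linear interpolation.
#'
#' Grid points where the measured intensity falls at or below
#' `floorFrac * max(measured)` are masked and filled by linear
#' interpolation of `log R`; more than 20% masked points is an error.
#' With `smooth = TRUE` the ratio is lightly denoised (3-point median
#' followed by a Savitzky-Golay fit over a ~1 nm window) — wide enough to
#' suppress shot noise, far narrower than the ~8 nm echelle ripple period,
#' so genuine ripple structure in the response survives.
#'
#' @param reference certified lamp spectrum (one-column [SpectraSet-class]).
#' @param measured lamp spectrum measured on the instrument.
#' @param smooth logical, denoise the ratio (default `TRUE`).
#' @param floorFrac division floor as a fraction of `max(measured)`.
#' @return a [ResponseFunction-class] valid on the overlap range.
#' @export
estimateResponse <- function(reference, measured, smooth = TRUE,
                             floorFrac = 1e-6) {
  refWl <- wavelengths(reference)
  mesWl <- wavelengths(measured)
  lo <- max(min(refWl), min(mesWl))
  hi <- min(max(refWl), max(mesWl))
  if (lo >= hi) stop("reference and measured lamp spectra do not overlap")
  sel <- which(refWl >= lo & refWl <= hi)
  wl <- refWl[sel]
  refI <- intensities(reference)[sel, 1L]
  mesI <- intensities(interpAlign(measured, wl))[, 1L]

  floorVal <- floorFrac * max(mesI)
  masked <- which(mesI <= floorVal)
  if (length(masked) > 0.2 * length(wl))
    stop("more than 20% of lamp points fall below the division floor; ",
         "the measured lamp spectrum is unusable")
  r <- rep(NA_real_, length(wl))
  ok <- setdiff(seq_along(wl), masked)
  r[ok] <- refI[ok] / mesI[ok]
  if (length(masked)) {
    warning(length(masked), " lamp point(s) below the division floor were ",
            "masked and interpolated")
    r <- exp(stats::approx(wl[ok], log(r[ok]), xout = wl, rule = 2)$y)
  }
  if (smooth && length(wl) >= 7L) {
    step <- stats::median(diff(wl))
    r <- stats::runmed(r, 3L)
    win <- max(5L, as.integer(round(1 / step)))
    if (win %% 2L == 0L) win <- win + 1L
    win <- min(win, length(wl) - (1 - length(wl) %% 2L))
    if (win > 3L) r <- signal::sgolayfilt(r, p = 2L, n = win)
    r <- pmax(r, .Machine$double.eps)
  }
  ResponseFunction(wl, r, validRange = c(lo, hi))
}

#' Evaluate a response function
#'
#' Linear interpolation within the valid range; outside it is an error.
#'
#' @param r a [ResponseFunction-class].
#' @param wl wavelengths (nm).
#' @return correction factors at `wl`.
#' @export
responseAt <- function(r, wl) {
  if (min(wl) < r@validRange[1] || max(wl) > r@validRange[2])
    stop(sprintf("response evaluated outside its valid range [%.2f, %.2f] nm",
                 r@validRange[1], r@validRange[2]))
  stats::approx(r@wavelength, r@value, xout = wl, rule = 2)$y
}

#' Build the cross-instrument transfer response
#'
#' Combines the two per-instrument responses into the correction that maps
#' high-resolution spectra onto the low-resolution instrument's intensity
#' scale: `R_transfer(lambda) = R_high(lambda) / R_low(lambda)`, restricted
#' to the intersection of both valid ranges clipped to `clipRange`
#' (350-850 nm by default, the overlap of the lamp's certified range and
#' both detection ranges). Since each R is the reciprocal sensitivity (up
#' to scale), a high-resolution measurement times this ratio equals what
#' the low-resolution instrument would have recorded from the same source,
#' up to a global scale that per-spectrum normalization removes.
#'
#' @param rl response of the (training) low-resolution instrument.
#' @param rh response of the (test) high-resolution instrument.
#' @param clipRange hard limits (nm) of the corrected range.
#' @return a [ResponseFunction-class] on the intersection range.
#' @export
buildTransfer <- function(rl, rh, clipRange = c(350, 850)) {
  lo <- max(rl@validRange[1], rh@validRange[1], clipRange[1])
  hi <- min(rl@validRange[2], rh@validRange[2], clipRange[2])
  if (lo >= hi) stop("response functions have no overlapping valid range")
  sel <- which(rl@wavelength >= lo & rl@wavelength <= hi)
  wl <- rl@wavelength[sel]
  ResponseFunction(wl, responseAt(rh, wl) / responseAt(rl, wl),
                   validRange = c(lo, hi))
}

#' Apply a response correction to spectra
#'
#' Restricts the spectra to the overlap of their support with the
#' response's valid range and multiplies each intensity by the correction
#' factor interpolated onto the spectra's own grid. Linear in intensity;
#' apply before per-spectrum normalization (normalization destroys the
#' absolute scale the correction operates on, and makes the result
#' invariant to any global scale in the response).
#'
#' @param x a [SpectraSet-class].
#' @param r a [ResponseFunction-class].
#' @return the corrected [SpectraSet-class], support restricted to the
#'   valid range.
#' @export
applyCorrection <- function(x, r) {
  wl <- wavelengths(x)
  sel <- which(wl >= r@validRange[1] & wl <= r@validRange[2])
  if (!length(sel))
    stop("spectra do not overlap the response's valid range")
  fac <- responseAt(r, wl[sel])
  out <- x[sel, ]
  SummarizedExperiment::assay(out, "intensity") <-
    SummarizedExperiment::assay(out, "intensity") * fac
  methods::new("SpectraSet", out)
}
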