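#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show slot
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SpectraSet: a collection of spectra on one wavelength grid
#'
#' An S4 container for emission spectra extending
#' [SummarizedExperiment::SummarizedExperiment]. Rows are wavelength points
#' (strictly increasing, stored in `rowData()$wavelength_nm`), columns are
#' individual spectra. The single assay `"intensity"` holds detector counts
#' (arbitrary units). Per-spectrum metadata (class label, sample id, shot
#' index, outlier flags) lives in `colData()`; instrument-level metadata in
#' `metadata()`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!("wavelength_nm" %in% colnames(rd)))
    return("rowData must contain a 'wavelength_nm' column")
  wl <- rd$wavelength_nm
  if (length(wl) < 2L)
    return("a spectrum needs at least 2 wavelength points")
  if (anyNA(wl) || any(diff(wl) <= 0))
    return("wavelengths must be strictly increasing and free of NA")
  if (!("intensity" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'intensity' is required")
  TRUE
})

#' Construct a SpectraSet
#'
#' @param wavelengths strictly increasing numeric vector of wavelengths (nm).
#' @param intensities numeric matrix, `length(wavelengths)` rows, one column
#'   per spectrum (a vector is treated as a single spectrum).
#' @param labels optional character vector of class labels, one per spectrum.
#' @param instrument instrument identifier for the whole set.
#' @param colData optional `DataFrame` of additional per-spectrum metadata.
#' @param metadata optional list of set-level metadata.
#' @return a [SpectraSet-class] object.
#' @export
SpectraSet <- function(wavelengths, intensities, labels = NULL,
                       instrument = "unknown", colData = NULL,
                       metadata = list()) {
  if (is.null(dim(intensities)))
    intensities <- matrix(intensities, ncol = 1L)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(wavelengths))
    stop("intensities must have one row per wavelength (got ",
         nrow(intensities), " rows for ", length(wavelengths),
         " wavelengths)")
  n <- ncol(intensities)
  if (is.null(colData)) {
    colData <- S4Vectors::DataFrame(row.names = .spectrumIds(n))
  } else {
    colData <- as(colData, "DataFrame")
    if (is.null(rownames(colData))) rownames(colData) <- .spectrumIds(n)
  }
  if (!is.null(labels)) {
    if (length(labels) != n)
      stop("length(labels) must equal the number of spectra")
    colData$label <- as.character(labels)
  }
  if (!identical(colnames(intensities), rownames(colData)))
    dimnames(intensities) <- list(NULL, rownames(colData))
  metadata$instrument_id <- instrument
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = colData,
    metadata = metadata)
  methods::new("SpectraSet", se)
}

.spectrumIds <- function(n) sprintf("spec_%04d", seq_len(n))

#' Construct a single Spectrum
#'
#' Convenience wrapper returning a one-column [SpectraSet-class].
#'
#' @inheritParams SpectraSet
#' @param meta optional named list of per-spectrum metadata.
#' @export
Spectrum <- function(wavelengths, intensities, instrument = "unknown",
                     meta = list()) {
  cd <- S4Vectors::DataFrame(row.names = "spec_0001")
  for (nm in names(meta)) cd[[nm]] <- meta[[nm]]
  SpectraSet(wavelengths, matrix(as.numeric(intensities), ncol = 1L),
             instrument = instrument, colData = cd)
}

#' ResponseFunction: wavelength-dependent correction factor
#'
#' Positive correction factors on an increasing wavelength grid, valid only
#' on `validRange`. Obtained as the ratio of a certified standard-lamp
#' spectrum to its measured counterpart; evaluation outside the valid range
#' is an error.
#'
#' @slot wavelength increasing numeric grid (nm).
#' @slot value positive correction factors.
#' @slot validRange numeric length 2, inclusive validity interval (nm).
#' @export
setClass("ResponseFunction",
         representation(wavelength = "numeric", value = "numeric",
                        validRange = "numeric"))

setValidity("ResponseFunction", function(object) {
  if (length(object@wavelength) != length(object@value))
    return("wavelength and value lengths differ")
  if (any(diff(object@wavelength) <= 0))
    return("wavelength grid must be strictly increasing")
  if (!all(is.finite(object@value)) || any(object@value <= 0))
    return("response values must be finite and > 0")
  if (length(object@validRange) != 2L ||
      object@validRange[1] >= object@validRange[2])
    return("validRange must be (lo, hi) with lo < hi")
  TRUE
})

#' @rdname ResponseFunction-class
#' @param wavelength,value,validRange see slots.
#' @export
ResponseFunction <- function(wavelength, value, validRange = range(wavelength)) {
  methods::new("ResponseFunction", wavelength = as.numeric(wavelength),
               value = as.numeric(value), validRange = as.numeric(validRange))
}

#' FeatureTable: per-spectrum peak/wavelength feature matrix
#'
#' Holds the matrix of feature intensities (rows = spectra, columns =
#' features) consumed by the classifier, together with per-feature
#' annotation (`wavelength_nm`, `species`, `origin`, optional `f_value`,
#' `match_rate`) and the per-row class labels.
#'
#' @slot values numeric matrix, spectra x features.
#' @slot features `DataFrame` of per-feature annotation.
#' @slot labels character class label per row (may be empty).
#' @slot instrument instrument identifier of the source spectra.
#' @export
setClass("FeatureTable",
         representation(values = "matrix", features = "DataFrame",
                        labels = "character", instrument = "character"))

setValidity("FeatureTable", function(object) {
  if (ncol(object@values) != nrow(object@features))
    return("number of feature columns must match feature annotation rows")
  if (length(object@labels) > 0L &&
      length(object@labels) != nrow(object@values))
    return("labels must be empty or one per spectrum row")
  if (anyDuplicated(object@features$wavelength_nm))
    return("feature wavelengths must be unique")
  TRUE
})

#' @rdname FeatureTable-class
#' @param values,features,labels,instrument see slots.
#' @export
FeatureTable <- function(values, features, labels = character(),
                         instrument = "unknown") {
  if (is.data.frame(features)) features <- S4Vectors::DataFrame(features)
  methods::new("FeatureTable", values = as.matrix(values), features = features,
               labels = as.character(labels), instrument = instrument)
}

#' ClassificationReport: confusion matrix and summary statistics
#'
#' @slot confusion k x k integer matrix, rows = true class, cols = predicted.
#' @slot accuracy overall proportion correct.
#' @slot precision named per-class precision (NA when a class was never
#'   predicted).
#' @slot recall named per-class recall (NA when a class has no true members).
#' @slot nEvaluated number of spectra evaluated.
#' @export
setClass("ClassificationReport",
         representation(confusion = "matrix", accuracy = "numeric",
                        precision = "numeric", recall = "numeric",
                        nEvaluated = "integer"))

setValidity("ClassificationReport", function(object) {
  if (nrow(object@confusion) != ncol(object@confusion))
    return("confusion matrix must be square")
  if (any(object@confusion < 0))
    return("confusion entries must be non-negative")
  if (sum(object@confusion) != object@nEvaluated)
    return("confusion total must equal nEvaluated")
  TRUE
})

#' RunReport: reproducible record of one pipeline protocol run
#'
#' @slot protocol protocol name.
#' @slot report the [ClassificationReport-class].
#' @slot featureWavelengths wavelengths (nm) of the features used.
#' @slot accuracyCurve data.frame (`n_features`, `accuracy`) from incremental
#'   feature selection (single-point for fixed feature sets).
#' @slot nRetained,nRemoved test spectra retained/removed by post-processing.
#' @slot testInstrument instrument the report was evaluated on.
#' @slot config configuration echo.
#' @slot version package version stamp.
#' @export
setClass("RunReport",
         representation(protocol = "character", report = "ClassificationReport",
                        featureWavelengths = "numeric",
                        accuracyCurve = "data.frame",
                        nRetained = "integer", nRemoved = "integer",
                        testInstrument = "character",
                        config = "list", version = "character"))

#' InstrumentModel: parametric model of a LIBS spectrometer
#'
#' Describes the simulator's view of one instrument: spectral range and
#' sampling grid, Gaussian instrumental broadening (FWHM), a smooth spectral
#' response curve with optional periodic (echelle-order) ripple, a wavelength
#' registration offset, and a two-term noise model (additive Gaussian sigma
#' plus signal-proportional fraction).
#'
#' @slot label instrument identifier.
#' @slot rangeNm numeric length 2, spectral range (nm).
#' @slot nPoints number of grid points.
#' @slot fwhmNm instrumental broadening FWHM (nm).
#' @slot response function of wavelength giving the smooth response (> 0).
#' @slot rippleAmp,ripplePeriod periodic response modulation (amplitude as a
#'   fraction, period in nm); amplitude 0 disables it.
#' @slot shiftNm wavelength registration offset (nm).
#' @slot noiseAdd additive Gaussian noise sigma (counts).
#' @slot noiseProp signal-proportional noise fraction.
#' @export
setClass("InstrumentModel",
         representation(label = "character", rangeNm = "numeric",
                        nPoints = "integer", fwhmNm = "numeric",
                        response = "function", rippleAmp = "numeric",
                        ripplePeriod = "numeric", shiftNm = "numeric",
                        noiseAdd = "numeric", noiseProp = "numeric"))

setValidity("InstrumentModel", function(object) {
  if (object@rangeNm[1] >= object@rangeNm[2])
    return("rangeNm must be (lo, hi) with lo < hi")
  if (object@fwhmNm <= 0) return("fwhmNm must be > 0")
  if (object@nPoints < 2L) return("nPoints must be >= 2")
  TRUE
})

# ---- show methods -----------------------------------------------------------

#' @export
setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  cat("SpectraSet with", ncol(object), "spectra on", length(wl),
      "wavelength points\n")
  cat(sprintf("  grid: %.2f-%.2f nm (step ~%.4f nm)\n", wl[1], wl[length(wl)],
              stats::median(diff(wl))))
  cat("  instrument:", instrumentId(object), "\n")
  lb <- spectrumLabels(object)
  if (!is.null(lb)) {
    tb <- table(lb)
    cat("  classes:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
        "\n")
  }
})

#' @export
setMethod("show", "ResponseFunction", function(object) {
  cat(sprintf("ResponseFunction on %.1f-%.1f nm (%d points), values %.3g-%.3g\n",
              object@validRange[1], object@validRange[2],
              length(object@wavelength), min(object@value), max(object@value)))
})

#' @export
setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@values), "spectra x",
      ncol(object@values), "features (instrument:", object@instrument, ")\n")
})

#' @export
setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport: accuracy %.2f%% on %d spectra\n",
              100 * object@accuracy, object@nEvaluated))
  print(object@confusion)
})

#' @export
setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport [%s]: accuracy %.2f%%, %d features, %d/%d test spectra retained\n",
              object@protocol, 100 * object@report@accuracy,
              length(object@featureWavelengths), object@nRetained,
              object@nRetained + object@nRemoved))
})

#' @export
setMethod("show", "InstrumentModel", function(object) {
  cat(sprintf("InstrumentModel '%s': %.0f-%.0f nm, %d points, FWHM %.3f nm, shift %+.3f nm\n",
              object@label, object@rangeNm[1], object@rangeNm[2],
              object@nPoints, object@fwhmNm, object@shiftNm))
})
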