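#' Accessors for SpectraSet and FeatureTable objects
#'
#' `wavelengths()` returns the shared wavelength grid (nm); `intensities()`
#' the wavelength x spectrum intensity matrix; `spectrumLabels()` the class
#' label per spectrum (or `NULL`); `instrumentId()` the instrument the data
#' came from; `featureMatrix()` and `featureInfo()` the spectra x features
#' value matrix and the per-feature annotation of a [FeatureTable-class].
#'
#' @param x a [SpectraSet-class] or [FeatureTable-class] object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("spectrumLabels", function(x) standardGeneric("spectrumLabels"))

#' @rdname accessors
#' @export
setGeneric("instrumentId", function(x) standardGeneric("instrumentId"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectraSet", function(x)
  SummarizedExperiment::rowData(x)$wavelength_nm)

#' @rdname accessors
#' @export
setMethod("intensities", "SpectraSet", function(x)
  SummarizedExperiment::assay(x, "intensity"))

#' @rdname accessors
#' @export
setMethod("spectrumLabels", "SpectraSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("label" %in% colnames(cd)) as.character(cd$label) else NULL
})

#' @rdname accessors
#' @export
setMethod("instrumentId", "SpectraSet", function(x) {
  id <- S4Vectors::metadata(x)$instrument_id
  if (is.null(id)) "unknown" else id
})

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("featureInfo", "FeatureTable", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("spectrumLabels", "FeatureTable", function(x)
  if (length(x@labels)) x@labels else NULL)

#' @rdname accessors
#' @export
setMethod("instrumentId", "FeatureTable", function(x) x@instrument)

#' Subset a FeatureTable
#'
#' Rows index spectra, columns index features; annotation and labels are
#' subset consistently.
#'
#' @param x a [FeatureTable-class].
#' @param i,j row (spectrum) and column (feature) indices.
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  FeatureTable(x@values[i, j, drop = FALSE], x@features[j, , drop = FALSE],
               labels = if (length(x@labels)) x@labels[i] else character(),
               instrument = x@instrument)
})

#' Confusion matrix and summary accessors for reports
#'
#' @param x a [ClassificationReport-class] or [RunReport-class].
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname report-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname report-accessors
#' @export
setMethod("confusionMatrix", "ClassificationReport", function(x) x@confusion)

#' @rdname report-accessors
#' @export
setMethod("accuracy", "ClassificationReport", function(x) x@accuracy)

#' @rdname report-accessors
#' @export
setMethod("confusionMatrix", "RunReport", function(x) x@report@confusion)

#' @rdname report-accessors
#' @export
setMethod("accuracy", "RunReport", function(x) x@report@accuracy)

#' @rdname report-accessors
#' @export
setGeneric("classificationReport", function(x)
  standardGeneric("classificationReport"))

#' @rdname report-accessors
#' @export
setMethod("classificationReport", "RunReport", function(x) x@report)
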