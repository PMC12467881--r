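#' Read spectra from a long or wide CSV file
#'
#' Two tabular layouts are supported. **Wide**: first column `wavelength_nm`,
#' one column per spectrum; class labels supplied via `labels` (a vector or
#' the path of a sidecar CSV with columns `spectrum_id,label`). **Long**:
#' columns `wavelength_nm,intensity,spectrum_id,label,instrument_id`, one row
#' per (spectrum, wavelength) pair.
#'
#' @param path CSV file path (UTF-8, '.' decimal).
#' @param fmt `"wide"` or `"long"`.
#' @param labels optional class labels for the wide layout: character vector
#'   (one per spectrum column) or path of a sidecar CSV.
#' @param instrument instrument identifier (wide layout; the long layout
#'   carries its own `instrument_id` column).
#' @return a [SpectraSet-class].
#' @export
readSpectra <- function(path, fmt = c("wide", "long"), labels = NULL,
                        instrument = "unknown") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (fmt == "wide") {
    if (colnames(df)[1] != "wavelength_nm")
      stop("wide CSV must have 'wavelength_nm' as its first column")
    wl <- df[[1]]
    .checkWavelengthColumn(wl)
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (anyNA(mat)) stop("ragged or missing intensity values in ", path)
    if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
      side <- utils::read.csv(labels)
      labels <- side$label[match(colnames(mat), side$spectrum_id)]
    }
    cd <- S4Vectors::DataFrame(row.names = colnames(mat))
    set <- SpectraSet(wl, mat, labels = labels, instrument = instrument,
                      colData = cd)
  } else {
    need <- c("wavelength_nm", "intensity", "spectrum_id")
    if (!all(need %in% colnames(df)))
      stop("long CSV must contain columns: ", paste(need, collapse = ", "))
    ids <- unique(df$spectrum_id)
    wl <- df$wavelength_nm[df$spectrum_id == ids[1]]
    .checkWavelengthColumn(wl)
    mat <- matrix(NA_real_, nrow = length(wl), ncol = length(ids),
                  dimnames = list(NULL, ids))
    for (id in ids) {
      sub <- df[df$spectrum_id == id, ]
      if (nrow(sub) != length(wl))
        stop("ragged rows: spectrum '", id, "' has ", nrow(sub),
             " wavelength points, expected ", length(wl))
      if (any(sub$wavelength_nm != wl))
        stop("spectrum '", id, "' is not on the shared wavelength grid")
      mat[, id] <- sub$intensity
    }
    labels <- if ("label" %in% colnames(df))
      as.character(df$label[match(ids, df$spectrum_id)]) else NULL
    instrument <- if ("instrument_id" %in% colnames(df))
      as.character(df$instrument_id[1]) else instrument
    set <- SpectraSet(wl, mat, labels = labels, instrument = instrument,
                      colData = S4Vectors::DataFrame(row.names = ids))
  }
  set
}

.checkWavelengthColumn <- function(wl) {
  bad <- which(!is.finite(wl))
  if (length(bad))
    stop("missing/NaN wavelength at row ", bad[1])
  if (any(diff(wl) <= 0))
    stop("wavelength column must be strictly increasing (violated near row ",
         which(diff(wl) <= 0)[1] + 1L, ")")
}

#' Write spectra to a long or wide CSV file
#'
#' Inverse of [readSpectra()]; values round-trip to full double precision.
#'
#' @param x a [SpectraSet-class].
#' @param path output CSV path.
#' @param fmt `"wide"` or `"long"`.
#' @param labelPath for the wide layout, optional path of the sidecar label
#'   CSV (written only when the set has labels).
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(x, path, fmt = c("wide", "long"), labelPath = NULL) {
  fmt <- match.arg(fmt)
  wl <- wavelengths(x)
  mat <- intensities(x)
  old <- options(digits = 17); on.exit(options(old))
  if (fmt == "wide") {
    df <- data.frame(wavelength_nm = wl, check.names = FALSE)
    df[colnames(mat)] <- as.data.frame(mat)
    utils::write.csv(df, path, row.names = FALSE)
    lb <- spectrumLabels(x)
    if (!is.null(lb) && !is.null(labelPath))
      utils::write.csv(data.frame(spectrum_id = colnames(mat), label = lb),
                       labelPath, row.names = FALSE)
  } else {
    lb <- spectrumLabels(x)
    df <- data.frame(
      wavelength_nm = rep(wl, times = ncol(mat)),
      intensity = as.vector(mat),
      spectrum_id = rep(colnames(mat), each = length(wl)),
      label = if (is.null(lb)) NA_character_ else rep(lb, each = length(wl)),
      instrument_id = instrumentId(x))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Average consecutive blocks of spectra
#'
#' Replaces each consecutive block of `block` spectra (within a
#' sample/class group, in acquisition order) by its pointwise mean,
#' shrinking the spectrum count by the block factor. Mirrors the common
#' LIBS practice of averaging repeated shots to raise signal-to-noise.
#'
#' Groups follow `colData()$sample_id` crossed with the class label when
#' present; otherwise the whole set forms one group.
#'
#' @param x a [SpectraSet-class] in acquisition order.
#' @param block positive integer block size.
#' @param remainder `"error"` (default) to fail when a group size is not
#'   divisible by `block`, or `"drop"` to discard the remainder with a
#'   warning.
#' @return a [SpectraSet-class] with `ncol(x) / block` spectra per group.
#' @export
averageBlocks <- function(x, block, remainder = c("error", "drop")) {
  remainder <- match.arg(remainder)
  block <- as.integer(block)
  if (block < 1L) stop("block must be a positive integer")
  cd <- SummarizedExperiment::colData(x)
  key <- rep("all", ncol(x))
  if ("label" %in% colnames(cd)) key <- paste0(key, "|", cd$label)
  if ("sample_id" %in% colnames(cd)) key <- paste0(key, "|", cd$sample_id)
  groups <- split(seq_len(ncol(x)), factor(key, levels = unique(key)))
  mat <- intensities(x)
  outCols <- list(); outMeta <- list()
  for (g in groups) {
    nFull <- length(g) %/% block
    if (length(g) %% block != 0L) {
      if (remainder == "error")
        stop("group size ", length(g), " not divisible by block ", block,
             " (use remainder = 'drop' to discard the remainder)")
      warning("dropping ", length(g) %% block,
              " trailing spectra not filling a block")
    }
    if (nFull == 0L) next
    for (b in seq_len(nFull)) {
      idx <- g[((b - 1L) * block + 1L):(b * block)]
      outCols[[length(outCols) + 1L]] <- rowMeans(mat[, idx, drop = FALSE])
      m <- cd[idx[1], , drop = FALSE]
      if ("outlier" %in% colnames(cd)) m$outlier <- any(cd$outlier[idx])
      outMeta[[length(outMeta) + 1L]] <- m
    }
  }
  if (!length(outCols)) stop("no complete blocks to average")
  newMat <- do.call(cbind, outCols)
  newCd <- do.call(rbind, outMeta)
  rownames(newCd) <- .spectrumIds(nrow(newCd))
  SpectraSet(wavelengths(x), newMat, instrument = instrumentId(x),
             colData = newCd, metadata = as.list(S4Vectors::metadata(x)))
}

#' Savitzky-Golay smoothing
#'
#' Fits a degree-`polyorder` polynomial in a moving window of `window`
#' points and replaces the centre point by the fitted value. At the
#' boundaries the polynomial fit is truncated to the available points (no
#' padding), so polynomials of degree at most `polyorder` are reproduced
#' exactly everywhere. Delegates to [signal::sgolayfilt()].
#'
#' In the default pipeline this is applied to the low-resolution
#' instrument's spectra only; high-resolution spectra pass through
#' unsmoothed.
#'
#' @param x a [SpectraSet-class].
#' @param window odd window length (points), greater than `polyorder`.
#' @param polyorder polynomial degree.
#' @return the smoothed [SpectraSet-class] on the same grid.
#' @export
savgolSmooth <- function(x, window = 5L, polyorder = 3L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (window > length(wavelengths(x)))
    stop("window exceeds spectrum length")
  mat <- intensities(x)
  sm <- apply(mat, 2L, signal::sgolayfilt, p = polyorder, n = window)
  out <- x
  SummarizedExperiment::assay(out, "intensity") <- sm
  out
}

#' Max-min normalization
#'
#' Rescales every spectrum independently to `(x - min x) / (max x - min x)`,
#' where the min and max are the spectrum's global extrema, so each
#' normalized spectrum attains 0 and 1 exactly once (at the argmin/argmax
#' wavelengths). Destroys absolute scale; apply response correction first
#' when absolute intensities matter.
#'
#' @param x a [SpectraSet-class].
#' @return the normalized [SpectraSet-class].
#' @export
minmaxNormalize <- function(x) {
  mat <- intensities(x)
  lo <- apply(mat, 2L, min)
  hi <- apply(mat, 2L, max)
  flat <- which(hi - lo <= 0)
  if (length(flat))
    stop("degenerate constant spectrum (max = min) in column ",
         paste(colnames(mat)[flat], collapse = ", "),
         "; cannot normalize")
  scale <- hi - lo
  chunk <- 64L
  for (start in seq(1L, ncol(mat), by = chunk)) {
    cols <- start:min(start + chunk - 1L, ncol(mat))
    mat[, cols] <- (mat[, cols, drop = FALSE] -
                      rep(lo[cols], each = nrow(mat))) /
      rep(scale[cols], each = nrow(mat))
  }
  out <- x
  SummarizedExperiment::assay(out, "intensity") <- mat
  out
}
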