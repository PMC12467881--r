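# Strict local maxima of a vector over a centred window of `2*half+1`
# points; boundary points are never maxima.
.localMaxima <- function(v, half = 2L) {
  n <- length(v)
  ok <- rep(TRUE, n)
  for (d in seq_len(half)) {
    lead <- c(v[-seq_len(d)], rep(Inf, d))
    lag <- c(rep(Inf, d), v[seq_len(n - d)])
    ok <- ok & v > lead & v > lag
  }
  ok
}

#' Detect peak features in class-mean spectra
#'
#' Computes the mean spectrum of every class, finds strict local maxima
#' over a `window`-point neighbourhood that exceed `threshold` (in
#' pre-normalization detector counts), and merges detections across classes
#' (detections within half a window of each other collapse onto the
#' strongest pixel). Peaks annotated to an excluded species (O and H by
#' default, whose lines are dominated by atmospheric entrainment) are
#' dropped.
#'
#' @param x a [SpectraSet-class] with class labels, in pre-normalization
#'   units.
#' @param threshold minimum class-mean peak intensity (counts).
#' @param window odd local-maximum window (points); the default spans
#'   roughly +-1 resolution element on a two-pixel-per-FWHM grid, so
#'   blended shoulders of a stronger neighbour are not reported as
#'   separate peaks.
#' @param lineList optional line table for species annotation (columns
#'   `species`, `wavelength_nm`); nearest line within `annotTol` is used.
#' @param excludeSpecies species labels to drop.
#' @param annotTol annotation tolerance (nm).
#' @return data.frame with columns `wavelength_nm`, `species`, `origin`
#'   (`"peak-set"`), ordered by wavelength. Empty (with a warning) when no
#'   peak clears the threshold.
#' @export
detectPeaks <- function(x, threshold = 1500, window = 7L, lineList = NULL,
                        excludeSpecies = c("O", "H"), annotTol = 0.3) {
  half <- (as.integer(window) - 1L) %/% 2L
  wl <- wavelengths(x)
  lb <- spectrumLabels(x)
  if (is.null(lb)) lb <- rep("all", ncol(x))
  mat <- intensities(x)
  classes <- unique(lb)
  means <- vapply(classes, function(cl)
    rowMeans(mat[, lb == cl, drop = FALSE]), numeric(nrow(mat)))
  maxMean <- apply(means, 1L, max)
  hits <- integer(0)
  for (ci in seq_along(classes)) {
    m <- means[, ci]
    hits <- union(hits, which(.localMaxima(m, half) & m > threshold))
  }
  if (!length(hits)) {
    warning("no peak exceeds the intensity threshold of ", threshold)
    return(data.frame(wavelength_nm = numeric(0), species = character(0),
                      origin = character(0)))
  }
  hits <- sort(hits)
  # merge cross-class detections of the same line: keep the strongest pixel
  # within each run of detections closer than half a window
  keep <- integer(0)
  grp <- cumsum(c(1L, diff(hits) > half))
  for (g in unique(grp)) {
    idx <- hits[grp == g]
    keep <- c(keep, idx[which.max(maxMean[idx])])
  }
  species <- rep(NA_character_, length(keep))
  if (!is.null(lineList)) {
    for (i in seq_along(keep)) {
      d <- abs(lineList$wavelength_nm - wl[keep[i]])
      if (min(d) <= annotTol) species[i] <- lineList$species[which.min(d)]
    }
    drop <- !is.na(species) & species %in% excludeSpecies
    keep <- keep[!drop]; species <- species[!drop]
  }
  data.frame(wavelength_nm = wl[keep], species = species,
             origin = "peak-set")
}

#' Extract feature values at fixed wavelengths
#'
#' Reads, for every spectrum, the intensity at the grid pixel nearest each
#' requested wavelength. Intended for the instrument the features were
#' defined on; use [matchPeaks()] to carry features across instruments.
#'
#' @param x a [SpectraSet-class].
#' @param features numeric wavelengths (nm) or a feature data.frame with a
#'   `wavelength_nm` column.
#' @return a [FeatureTable-class] (rows = spectra, columns = features).
#' @export
extractFeatures <- function(x, features) {
  feat <- .asFeatureFrame(features)
  wl <- wavelengths(x)
  idx <- vapply(feat$wavelength_nm, function(w) which.min(abs(wl - w)),
                integer(1L))
  if (anyDuplicated(idx))
    stop("two features map onto the same grid pixel; deduplicate first")
  vals <- t(intensities(x)[idx, , drop = FALSE])
  colnames(vals) <- sprintf("wl_%.3f", feat$wavelength_nm)
  lb <- spectrumLabels(x)
  FeatureTable(vals, feat, labels = if (is.null(lb)) character() else lb,
               instrument = instrumentId(x))
}

.asFeatureFrame <- function(features) {
  if (is.numeric(features))
    features <- data.frame(wavelength_nm = features,
                           species = NA_character_, origin = "peak-set")
  if (!"origin" %in% colnames(features)) features$origin <- "peak-set"
  if (!"species" %in% colnames(features)) features$species <- NA_character_
  as.data.frame(features)
}

#' Match reference peak features onto another instrument's spectra
#'
#' For every reference feature and every spectrum, searches the nearest
#' strict local maximum within `tolNm` of the reference wavelength
#' (tolerance widened by half a grid step to absorb sampling
#' discretization). A candidate maximum must also rise above the local
#' background, estimated per window as median plus `madFactor` scaled MADs,
#' so noise wiggles far from any emission line are never matched. The
#' feature value is the intensity at the matched pixel; unmatched spectra
#' fall back to the intensity at the pixel nearest the nominal wavelength,
#' and the per-feature match rate is reported in the annotation.
#'
#' Ties between two equally distant candidates resolve to the lower
#' wavelength.
#'
#' @param refFeatures feature data.frame (`wavelength_nm`, ...) or numeric
#'   wavelengths, defined on the reference instrument.
#' @param x the other instrument's [SpectraSet-class] (already corrected
#'   and normalized), or a lazy [normalizedView()] of it.
#' @param tolNm matching tolerance (nm).
#' @param madFactor background rejection threshold in MADs.
#' @return a [FeatureTable-class] whose feature wavelengths are the
#'   *reference* wavelengths (so columns align across instruments), with a
#'   `match_rate` annotation column.
#' @export
matchPeaks <- function(refFeatures, x, tolNm = 0.3, madFactor = 5) {
  if (tolNm <= 0) stop("tolNm must be > 0")
  feat <- .asFeatureFrame(refFeatures)
  src <- .asSpectraSource(x)
  wl <- src$wl
  step <- src$step
  n <- src$n
  p <- nrow(feat)
  vals <- matrix(NA_real_, n, p,
                 dimnames = list(NULL, sprintf("wl_%.3f", feat$wavelength_nm)))
  matchRate <- numeric(p)
  effTol <- tolNm + step / 2
  for (f in seq_len(p)) {
    ref <- feat$wavelength_nm[f]
    win <- which(wl >= ref - effTol & wl <= ref + effTol)
    nominal <- which.min(abs(wl - ref))
    if (!length(win)) {
      vals[, f] <- src$getRows(nominal)[1L, ]
      next
    }
    # extend by 2 pixels so edge-of-window maxima see their neighbours
    ext <- max(1L, min(win) - 2L):min(length(wl), max(win) + 2L)
    W <- src$getRows(ext)
    isLocal <- apply(W, 2L, .localMaxima, half = 2L)
    inWin <- ext %in% win
    med <- apply(W[inWin, , drop = FALSE], 2L, stats::median)
    madv <- apply(W[inWin, , drop = FALSE], 2L, stats::mad)
    nomRow <- match(nominal, ext)
    dist <- abs(wl[ext] - ref)
    ord <- order(dist, wl[ext])  # nearest first, lower wavelength on ties
    nm <- 0L
    for (s in seq_len(n)) {
      cand <- which(isLocal[, s] & inWin & W[, s] > med[s] + madFactor * madv[s])
      if (length(cand)) {
        best <- ord[ord %in% cand][1L]
        vals[s, f] <- W[best, s]
        nm <- nm + 1L
      } else {
        vals[s, f] <- W[nomRow, s]
      }
    }
    matchRate[f] <- nm / n
  }
  feat$match_rate <- matchRate
  FeatureTable(vals, feat,
               labels = if (is.null(src$labels)) character() else src$labels,
               instrument = src$instrument)
}

# Adapter giving matchPeaks a uniform view of its spectra source: either a
# materialized SpectraSet or a lazy window view (class "spectraSource")
# that computes corrected/normalized rows on demand.
.asSpectraSource <- function(x) {
  if (inherits(x, "spectraSource")) return(x)
  if (!methods::is(x, "SpectraSet")) stop("unsupported spectra source")
  mat <- SummarizedExperiment::assay(x, "intensity")
  wl <- wavelengths(x)
  structure(list(wl = wl, n = ncol(mat), labels = spectrumLabels(x),
                 instrument = instrumentId(x),
                 step = stats::median(diff(wl)),
                 getRows = function(idx) mat[idx, , drop = FALSE]),
            class = c("spectraSource", "list"))
}

#' Memory-lean corrected-and-normalized view of a spectra set
#'
#' Builds a lazy window view equivalent to
#' `minmaxNormalize(applyCorrection(x, response))` (or plain
#' `minmaxNormalize(x)` when `response` is `NULL`) without materializing
#' the transformed intensity matrix: per-spectrum extrema are accumulated
#' in column blocks, and [matchPeaks()] pulls individual wavelength
#' windows through the same arithmetic on demand. Values agree exactly
#' with the materialized chain; only peak-window feature extraction is
#' supported on the view. Intended for high-resolution sets whose full
#' matrix is large.
#'
#' @param x a [SpectraSet-class].
#' @param response optional [ResponseFunction-class] applied before
#'   normalization.
#' @return a `spectraSource` adapter consumable by [matchPeaks()] and
#'   [selectIncremental()].
#' @export
normalizedView <- function(x, response = NULL) {
  mat <- SummarizedExperiment::assay(x, "intensity")
  wl <- wavelengths(x)
  if (!is.null(response)) {
    sel <- which(wl >= response@validRange[1] & wl <= response@validRange[2])
    if (!length(sel))
      stop("spectra do not overlap the response's valid range")
    fac <- responseAt(response, wl[sel])
  } else {
    sel <- seq_along(wl)
    fac <- NULL
  }
  n <- ncol(mat)
  lo <- numeric(n); hi <- numeric(n)
  chunk <- 64L
  for (start in seq(1L, n, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n)
    block <- mat[sel, cols, drop = FALSE]
    if (!is.null(fac)) block <- block * fac
    lo[cols] <- apply(block, 2L, min)
    hi[cols] <- apply(block, 2L, max)
  }
  if (any(hi - lo <= 0))
    stop("degenerate constant spectrum (max = min); cannot normalize")
  wlSel <- wl[sel]
  getRows <- function(idx) {
    block <- mat[sel[idx], , drop = FALSE]
    if (!is.null(fac)) block <- block * fac[idx]
    (block - rep(lo, each = length(idx))) /
      rep(hi - lo, each = length(idx))
  }
  structure(list(wl = wlSel, n = n, labels = spectrumLabels(x),
                 instrument = instrumentId(x),
                 step = stats::median(diff(wlSel)),
                 getRows = getRows),
            class = c("spectraSource", "list"))
}

#' Candidate wavelengths for ANOVA ranking
#'
#' Grid pixels whose strongest class-mean intensity exceeds `threshold`
#' (pre-normalization counts) — the pool over which per-wavelength F-values
#' are computed.
#'
#' @param x a labeled [SpectraSet-class] in pre-normalization units.
#' @param threshold intensity threshold (counts).
#' @return numeric wavelengths (nm).
#' @export
candidateWavelengths <- function(x, threshold = 1500) {
  lb <- spectrumLabels(x)
  if (is.null(lb)) lb <- rep("all", ncol(x))
  mat <- intensities(x)
  means <- vapply(unique(lb), function(cl)
    rowMeans(mat[, lb == cl, drop = FALSE]), numeric(nrow(mat)))
  wavelengths(x)[apply(means, 1L, max) > threshold]
}

#' Rank candidate wavelengths by one-way ANOVA F-value
#'
#' For every candidate wavelength the one-way ANOVA F statistic is computed
#' over the class labels:
#' `F = (SSB / (k - 1)) / (SSW / (N - k))`,
#' with `SSB = sum_i n_i (xbar_i - xbar)^2` the between-class and
#' `SSW = sum_i sum_j (x_ij - xbar_i)^2` the within-class sum of squares.
#' Larger F means more class-discriminative. Degenerate cases: `SSW = 0`
#' with `SSB > 0` yields `Inf` (ranked first); `SSB = SSW = 0` yields 0.
#' F is invariant to any common affine transform of the intensities at a
#' wavelength, so ranking is unaffected by per-spectrum scale conventions.
#'
#' @param x a labeled [SpectraSet-class] (at least 2 classes, each with at
#'   least 2 spectra).
#' @param candidates candidate wavelengths (nm); `NULL` selects all grid
#'   pixels via [candidateWavelengths()] on `x` (appropriate only when `x`
#'   is in pre-normalization units).
#' @param threshold threshold passed to [candidateWavelengths()] when
#'   `candidates` is `NULL`.
#' @return data.frame (`wavelength_nm`, `f_value`) sorted by decreasing
#'   F-value.
#' @export
anovaRank <- function(x, candidates = NULL, threshold = 1500) {
  lb <- spectrumLabels(x)
  if (is.null(lb) || length(unique(lb)) < 2L)
    stop("ANOVA ranking needs at least 2 classes")
  if (any(table(lb) < 2L)) stop("every class needs at least 2 spectra")
  if (is.null(candidates)) candidates <- candidateWavelengths(x, threshold)
  wl <- wavelengths(x)
  idx <- vapply(candidates, function(w) which.min(abs(wl - w)), integer(1L))
  X <- t(intensities(x)[idx, , drop = FALSE])  # n x p
  g <- factor(lb)
  N <- nrow(X); k <- nlevels(g)
  ni <- as.vector(table(g))
  gm <- rowsum(X, g) / ni                       # k x p class means
  overall <- colMeans(X)
  ssb <- colSums(ni * (gm - rep(overall, each = k))^2)
  ssw <- colSums((X - gm[as.integer(g), , drop = FALSE])^2)
  f <- ifelse(ssw > 0, (ssb / (k - 1)) / (ssw / (N - k)),
              ifelse(ssb > 0, Inf, 0))
  out <- data.frame(wavelength_nm = wl[idx], f_value = f)
  out[order(-out$f_value, out$wavelength_nm), , drop = FALSE]
}

#' Incremental feature-count selection
#'
#' Starting from the base peak-feature set, adds ANOVA-ranked wavelengths
#' one at a time in descending F-value order — skipping any candidate
#' within one grid step of an already included feature (overlap
#' deduplication) — retrains the random forest on the training instrument
#' and records test accuracy after every addition. Returns the feature set
#' with maximal test accuracy (ties resolve to fewer features) together
#' with the full accuracy curve.
#'
#' @param base base feature data.frame (from [detectPeaks()]) or numeric
#'   wavelengths, on the training instrument's grid.
#' @param ranking ANOVA ranking from [anovaRank()].
#' @param trainSet training-instrument [SpectraSet-class] (normalized), with
#'   labels.
#' @param testSet test-instrument [SpectraSet-class] (corrected and
#'   normalized) or a [normalizedView()], with labels.
#' @param maxAdded maximum number of features added beyond the base set.
#' @param cfg [forestConfig()] used for every retrain.
#' @param tolNm cross-instrument matching tolerance (nm).
#' @param dedupStep deduplication radius (nm); defaults to one grid step of
#'   the training set.
#' @return list with `features` (annotation data.frame of the best set),
#'   `curve` (data.frame `n_features`, `accuracy`), `nSkipped` (ranked
#'   candidates dropped as duplicates), and the ready-made `trainBest` /
#'   `testBest` [FeatureTable-class]s for the best set.
#' @export
selectIncremental <- function(base, ranking, trainSet, testSet,
                              maxAdded = 20L, cfg = forestConfig(),
                              tolNm = 0.3, dedupStep = NULL) {
  feat <- .asFeatureFrame(base)
  if (is.null(dedupStep))
    dedupStep <- stats::median(diff(wavelengths(trainSet)))
  current <- feat$wavelength_nm
  added <- data.frame(wavelength_nm = numeric(0), f_value = numeric(0))
  nSkipped <- 0L
  for (i in seq_len(nrow(ranking))) {
    if (nrow(added) >= maxAdded) break
    w <- ranking$wavelength_nm[i]
    if (any(abs(current - w) <= dedupStep * (1 + 1e-9))) {
      nSkipped <- nSkipped + 1L
      next
    }
    added <- rbind(added, ranking[i, c("wavelength_nm", "f_value")])
    current <- c(current, w)
  }
  feat$f_value <- NA_real_
  allFeat <- feat[, c("wavelength_nm", "species", "origin", "f_value")]
  if (nrow(added))
    allFeat <- rbind(allFeat,
                     data.frame(wavelength_nm = added$wavelength_nm,
                                species = NA_character_,
                                origin = "anova-added",
                                f_value = added$f_value))
  trainAll <- extractFeatures(trainSet, allFeat)
  testAll <- matchPeaks(allFeat, testSet, tolNm = tolNm)
  nBase <- nrow(feat)
  sizes <- nBase + 0:nrow(added)
  acc <- numeric(length(sizes))
  for (s in seq_along(sizes)) {
    cols <- seq_len(sizes[s])
    fit <- fitForest(trainAll[, cols], cfg)
    pred <- predictForest(fit, testAll[, cols])
    acc[s] <- mean(pred == spectrumLabels(testAll))
  }
  best <- which.max(acc)  # first maximum = fewest features on ties
  bestCols <- seq_len(sizes[best])
  list(features = as.data.frame(featureInfo(testAll))[bestCols,
                                                      c("wavelength_nm", "species", "origin", "f_value")],
       curve = data.frame(n_features = sizes, accuracy = acc),
       nSkipped = nSkipped,
       trainBest = trainAll[, bestCols], testBest = testAll[, bestCols])
}
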