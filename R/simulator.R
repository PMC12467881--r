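# Counts*nm of line area per unit relative intensity; chosen so that every
# listed emission line clears the 1500-count peak-selection threshold in the
# low-resolution class-mean spectra while the strongest lines stay in the
# few-10^4 count range typical of CCD LIBS acquisitions.
.AREA_SCALE <- 12000

#' Emission line list of the three Akebia-type medicinal species
#'
#' The bundled static line table: 20 atomic/molecular peak features (C-N,
#' Ca I/II/III, Fe I, V I, C2, Na I, K I) flagged `peak_feature = TRUE`, plus
#' shaded line combs degrading violet-ward from the C-N band heads
#' (381-388 nm) and from Fe I 402.96 nm (flagged `FALSE`). The comb lines
#' sit ~0.25 nm apart with intensities ramping up toward each head: a
#' low-resolution spectrometer blends them into unresolved shoulders (no
#' separate peaks, but pixels above the selection threshold), while a
#' high-resolution echelle resolves each of them — the structure behind
#' "newly added" ANOVA wavelengths inside those bands. The `group` column
#' marks which class-discriminating band a line belongs to (`cn`, `fe`,
#' `k`, or `none`); `rel_intensity` is the line area in units of `12000`
#' counts nm; `width_nm` an optional intrinsic FWHM added in quadrature to
#' the instrumental broadening (0 for all bundled lines).
#'
#' @return a data.frame with columns `species`, `wavelength_nm`,
#'   `rel_intensity`, `group`, `width_nm`, `peak_feature`.
#' @export
defaultLineList <- function() {
  path <- system.file("extdata", "akebia_lines.csv", package = "libsbridge",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Instrument models for the two simulated LIBS systems
#'
#' `lowResInstrument()` emulates a broadband CCD fiber-optic spectrometer:
#' 190-1100 nm on 8192 points, 0.28 nm Gaussian FWHM, smooth response rising
#' toward the infrared. `highResInstrument()` emulates an echelle/ICCD
#' system: 200-850 nm on 86400 points, 0.018 nm FWHM, response falling from
#' the ultraviolet with a periodic (order-structure) ripple of 15% amplitude
#' and ~8 nm period. Both grids sample at roughly two pixels per FWHM, the
#' Nyquist-style sampling real spectrograph designs aim for. Each
#' instrument carries a wavelength registration
#' offset; when `shiftNm` is `NULL` it is drawn uniformly from
#' [0.05, 0.3] nm using the current RNG state, reproducing the
#' peak-position shifts observed between real spectrometer pairs.
#'
#' @param shiftNm wavelength registration offset (nm), or `NULL` to draw one.
#' @param fwhmNm instrumental broadening FWHM (nm), within the instrument's
#'   stated resolution band.
#' @param nPoints number of grid points.
#' @param rippleAmp,ripplePeriod echelle ripple amplitude (fraction) and
#'   period (nm); high-resolution model only.
#' @param noiseAdd,noiseProp additive noise sigma (counts) and
#'   signal-proportional noise fraction.
#' @param response smooth positive response function of wavelength.
#' @return an [InstrumentModel-class].
#' @export
lowResInstrument <- function(shiftNm = NULL, fwhmNm = 0.28, nPoints = 8192L,
                             noiseAdd = 60, noiseProp = 0.02,
                             response = function(wl) 0.30 + 0.65 * (wl - 190) / 910) {
  if (is.null(shiftNm)) shiftNm <- stats::runif(1L, 0.05, 0.3)
  methods::new("InstrumentModel", label = "L-R", rangeNm = c(190, 1100),
               nPoints = as.integer(nPoints), fwhmNm = fwhmNm,
               response = response, rippleAmp = 0, ripplePeriod = 8,
               shiftNm = shiftNm, noiseAdd = noiseAdd, noiseProp = noiseProp)
}

#' @rdname lowResInstrument
#' @export
highResInstrument <- function(shiftNm = NULL, fwhmNm = 0.018, nPoints = 86400L,
                              rippleAmp = 0.15, ripplePeriod = 8,
                              noiseAdd = 800, noiseProp = 0.02,
                              response = function(wl) 1.00 - 0.75 * (wl - 200) / 650) {
  if (is.null(shiftNm)) shiftNm <- stats::runif(1L, 0.05, 0.3)
  methods::new("InstrumentModel", label = "H-R", rangeNm = c(200, 850),
               nPoints = as.integer(nPoints), fwhmNm = fwhmNm,
               response = response, rippleAmp = rippleAmp,
               ripplePeriod = ripplePeriod, shiftNm = shiftNm,
               noiseAdd = noiseAdd, noiseProp = noiseProp)
}

#' Wavelength grid and total response of an instrument model
#'
#' `instrumentGrid()` returns the sampling grid; `instrumentResponse()` the
#' total wavelength-dependent sensitivity, i.e. the smooth response curve
#' times the periodic ripple term.
#'
#' @param model an [InstrumentModel-class].
#' @param wl wavelengths at which to evaluate the response.
#' @export
instrumentGrid <- function(model) {
  seq(model@rangeNm[1], model@rangeNm[2], length.out = model@nPoints)
}

#' @rdname instrumentGrid
#' @export
instrumentResponse <- function(model, wl) {
  r <- model@response(wl)
  if (model@rippleAmp > 0)
    r <- r * (1 + model@rippleAmp * sin(2 * pi * wl / model@ripplePeriod))
  r
}

#' Class emission profiles
#'
#' A class profile specifies, in log space, how strongly each
#' class-discriminating line group deviates from the shared base line list,
#' plus the biological/measurement variability: a per-sample log-normal
#' factor (sigma `sigmaSample`, drawn once per emission line per sample
#' slice) and a per-shot global energy factor (sigma `sigmaShot`).
#'
#' `defaultClassProfiles()` returns the three species profiles. Their group
#' offsets (+-0.3 in log space on the CN 381-388 nm, Fe 402-403 nm and
#' K 766-769 nm bands) concentrate the between-class differences in those
#' three regions while the remaining lines differ only through sampling
#' variability.
#'
#' @param name class name.
#' @param offsets named numeric log-offsets per line group.
#' @param sigmaSample per-sample log-normal sigma.
#' @param sigmaShot per-shot global log-normal sigma.
#' @return a `classProfile` list.
#' @export
classProfile <- function(name, offsets = c(cn = 0, fe = 0, k = 0),
                         sigmaSample = 0.15, sigmaShot = 0.05) {
  structure(list(name = name, offsets = offsets, sigmaSample = sigmaSample,
                 sigmaShot = sigmaShot), class = "classProfile")
}

#' @rdname classProfile
#' @export
defaultClassProfiles <- function() {
  list(
    classProfile("mutong", c(cn = +0.3, fe = 0.0, k = -0.3)),
    classProfile("guan",   c(cn = -0.3, fe = +0.3, k = 0.0)),
    classProfile("chuan",  c(cn = 0.0, fe = -0.3, k = +0.3)))
}

# Log-offset per line implied by a profile's group offsets.
.lineOffsets <- function(profile, lineList) {
  off <- rep(0, nrow(lineList))
  for (g in names(profile$offsets)) {
    off[lineList$group == g] <- profile$offsets[[g]]
  }
  off
}

# Pixel-integrated Gaussian line profiles on the model grid, weighted by the
# instrument's total response at each pixel. Detector pixels integrate the
# incident flux over their width, so a line's sampled shape is the
# difference of Gaussian CDFs across pixel edges divided by the step; this
# keeps line *area* (not peak height) invariant under resampling.
# Returns a list of list(idx, vals) per line; lines outside the range are
# dropped (NULL entries).
.lineProfiles <- function(model, lineList) {
  grid <- instrumentGrid(model)
  step <- (model@rangeNm[2] - model@rangeNm[1]) / (model@nPoints - 1)
  sigmaInstr <- model@fwhmNm / (2 * sqrt(2 * log(2)))
  lapply(seq_len(nrow(lineList)), function(j) {
    centre <- lineList$wavelength_nm[j] + model@shiftNm
    if (centre < model@rangeNm[1] || centre > model@rangeNm[2]) return(NULL)
    sigma <- sqrt(sigmaInstr^2 + (lineList$width_nm[j] / 2.3548)^2)
    half <- 6 * sigma + step
    idx <- which(grid >= centre - half & grid <= centre + half)
    if (!length(idx)) return(NULL)
    frac <- stats::pnorm((grid[idx] + step / 2 - centre) / sigma) -
      stats::pnorm((grid[idx] - step / 2 - centre) / sigma)
    list(idx = idx, vals = frac / step * instrumentResponse(model, grid[idx]))
  })
}

# Shared renderer: given an n x L matrix of line areas (counts*nm, response
# not yet applied), produce the m x n intensity matrix. Works in fixed-size
# column blocks so temporaries stay small next to the spectrum matrix.
# `surge` optionally adds a broad continuum per spectrum (amp as a fraction
# of that spectrum's signal maximum, centre and width in nm; NA amp = no
# surge). The additive and signal-proportional noise terms are independent
# Gaussians, so one draw with combined sigma sqrt(add^2 + (prop*I)^2) is
# distributionally identical to drawing them separately.
.renderMatrix <- function(model, lineList, areas, noise = TRUE,
                          surge = NULL, chunk = 64L) {
  profs <- .lineProfiles(model, lineList)
  keep <- which(!vapply(profs, is.null, logical(1L)))
  if (!length(keep)) stop("no emission line falls inside the instrument range")
  m <- model@nPoints
  n <- nrow(areas)
  grid <- if (is.null(surge)) NULL else instrumentGrid(model)
  resp <- if (is.null(surge)) NULL else instrumentResponse(model, grid)
  noiseOn <- noise && (model@noiseAdd > 0 || model@noiseProp > 0)
  M <- matrix(0, m, n)
  for (start in seq(1L, n, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n)
    B <- matrix(0, m, length(cols))
    for (j in keep) {
      pr <- profs[[j]]
      B[pr$idx, ] <- B[pr$idx, ] + pr$vals %o% areas[cols, j]
    }
    if (!is.null(surge)) {
      for (k in seq_along(cols)) {
        i <- cols[k]
        if (!is.na(surge$amp[i]))
          B[, k] <- B[, k] + surge$amp[i] * max(B[, k]) *
            exp(-(grid - surge$ctr[i])^2 / (2 * surge$wid[i]^2)) * resp
      }
    }
    if (noiseOn) {
      sd <- sqrt(model@noiseAdd^2 + (model@noiseProp * B)^2)
      B <- B + stats::rnorm(length(B)) * sd
    }
    M[, cols] <- B
  }
  M
}

#' Render a single synthetic LIBS spectrum
#'
#' Sums pixel-integrated Gaussian emission lines (instrumental FWHM
#' broadening convolved with any intrinsic band width), shifted by the
#' instrument's registration offset, scaled by the class profile's line
#' factors, weighted by the instrument response (including echelle ripple),
#' and overlaid with additive plus signal-proportional Gaussian noise.
#'
#' @param profile a [classProfile()].
#' @param model an [InstrumentModel-class].
#' @param seed optional integer seed (`NULL` uses the current RNG state).
#' @param lineList line table, defaults to [defaultLineList()].
#' @param noise logical; `FALSE` disables both noise terms.
#' @return a one-column [SpectraSet-class].
#' @export
renderSpectrum <- function(profile, model, seed = NULL,
                           lineList = defaultLineList(), noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  off <- .lineOffsets(profile, lineList)
  L <- nrow(lineList)
  sampleFac <- if (profile$sigmaSample > 0)
    stats::rnorm(L, 0, profile$sigmaSample) else numeric(L)
  shotFac <- if (profile$sigmaShot > 0)
    stats::rnorm(1L, 0, profile$sigmaShot) else 0
  areas <- matrix(.AREA_SCALE * lineList$rel_intensity *
                    exp(off + sampleFac + shotFac), nrow = 1L)
  M <- .renderMatrix(model, lineList, areas, noise = noise)
  Spectrum(instrumentGrid(model), M[, 1L], instrument = model@label,
           meta = list(label = profile$name))
}

#' Simulate a labeled LIBS dataset on one instrument
#'
#' Generates `nPerClass` spectra per class, organised into `nSamples`
#' sample slices per class (each slice drawing its own log-normal per-line
#' emission factors, so spectra cluster by sample as in repeated
#' measurements of physical slices). A fraction of spectra is corrupted to
#' emulate abnormal acquisitions and flagged in `colData()` for ground
#' truth: half suffer a *collapse* (global intensity times U(0.05, 0.2),
#' with lines below 450 nm suppressed by an extra square-root power of the
#' collapse factor, as a weakly coupled shot depresses the hotter UV
#' emission disproportionately), half a *baseline surge* (a broad Gaussian
#' continuum of 30-80% of the spectrum maximum at a random position).
#'
#' @param profiles list of [classProfile()]s (one class each).
#' @param model an [InstrumentModel-class].
#' @param nPerClass spectra per class (divisible by `nSamples`).
#' @param outlierFraction fraction in [0, 0.5) of spectra corrupted.
#' @param seed optional integer seed (`NULL` uses the current RNG state).
#' @param lineList line table, defaults to [defaultLineList()].
#' @param nSamples sample slices per class.
#' @return a [SpectraSet-class] with `colData` columns `label`, `sample_id`,
#'   `shot`, `outlier`, `outlier_type`.
#' @export
simulateDataset <- function(profiles, model, nPerClass,
                            outlierFraction = 0, seed = NULL,
                            lineList = defaultLineList(), nSamples = 10L) {
  if (!is.null(seed)) set.seed(seed)
  if (nPerClass < 1L) stop("nPerClass must be >= 1")
  if (outlierFraction < 0 || outlierFraction >= 0.5)
    stop("outlierFraction must be in [0, 0.5)")
  if (nPerClass %% nSamples != 0L)
    stop("nPerClass must be divisible by nSamples")
  perSample <- nPerClass %/% nSamples
  L <- nrow(lineList)
  k <- length(profiles)
  n <- k * nPerClass

  areas <- matrix(0, n, L)
  label <- character(n); sampleId <- character(n); shot <- integer(n)
  row <- 0L
  for (ci in seq_len(k)) {
    pr <- profiles[[ci]]
    off <- .lineOffsets(pr, lineList)
    for (s in seq_len(nSamples)) {
      sFac <- stats::rnorm(L, 0, pr$sigmaSample)
      shotFac <- stats::rnorm(perSample, 0, pr$sigmaShot)
      base <- .AREA_SCALE * lineList$rel_intensity * exp(off + sFac)
      idx <- row + seq_len(perSample)
      areas[idx, ] <- exp(shotFac) %o% base
      label[idx] <- pr$name
      sampleId[idx] <- sprintf("%s_s%02d", pr$name, s)
      shot[idx] <- seq_len(perSample)
      row <- row + perSample
    }
  }

  nOut <- round(outlierFraction * n)
  outIdx <- if (nOut > 0L) sort(sample.int(n, nOut)) else integer(0)
  outType <- rep("none", n)
  surge <- NULL
  if (nOut > 0L) {
    types <- rep(c("collapse", "surge"), length.out = nOut)
    types <- sample(types)
    outType[outIdx] <- types
    uv <- lineList$wavelength_nm < 450
    for (i in which(outType == "collapse")) {
      cf <- stats::runif(1L, 0.05, 0.2)
      areas[i, ] <- areas[i, ] * cf
      areas[i, uv] <- areas[i, uv] * sqrt(cf)
    }
    surge <- list(amp = rep(NA_real_, n), ctr = rep(NA_real_, n),
                  wid = rep(NA_real_, n))
    for (i in which(outType == "surge")) {
      surge$amp[i] <- stats::runif(1L, 0.3, 0.8)
      surge$ctr[i] <- stats::runif(1L, 400, 800)
      surge$wid[i] <- stats::runif(1L, 50, 150)
    }
  }

  M <- .renderMatrix(model, lineList, areas, surge = surge)
  colnames(M) <- .spectrumIds(n)

  cd <- S4Vectors::DataFrame(
    label = label, sample_id = sampleId, shot = shot,
    outlier = outType != "none", outlier_type = outType,
    row.names = .spectrumIds(n))
  SpectraSet(instrumentGrid(model), M, instrument = model@label, colData = cd,
             metadata = list(
               model = list(range_nm = model@rangeNm, n_points = model@nPoints,
                            fwhm_nm = model@fwhmNm, shift_nm = model@shiftNm,
                            ripple_amp = model@rippleAmp,
                            ripple_period = model@ripplePeriod),
               true_response = list(wavelength = instrumentGrid(model),
                                    value = instrumentResponse(model, instrumentGrid(model))),
               line_list = lineList))
}

#' Certified standard-lamp reference curve
#'
#' A smooth quasi-blackbody irradiance curve (Planck shape at the given
#' colour temperature, peak-normalized) on the lamp's certified range of
#' 350-1000 nm. Only ratios against measured lamp spectra matter, so the
#' absolute units are arbitrary.
#'
#' @param from,to,step wavelength grid specification (nm); alternatively
#'   pass an explicit `grid`.
#' @param grid optional explicit wavelength grid overriding `from/to/step`.
#' @param temperature colour temperature (K).
#' @return a one-column [SpectraSet-class].
#' @export
lampReference <- function(from = 350, to = 1000, step = 0.5, grid = NULL,
                          temperature = 3000) {
  wl <- if (is.null(grid)) seq(from, to, by = step) else grid
  c2 <- 1.4388e7  # nm K
  irr <- wl^-5 / (exp(c2 / (wl * temperature)) - 1)
  Spectrum(wl, irr / max(irr), instrument = "reference")
}

#' Simulate the measurement of the standard lamp on an instrument
#'
#' Returns `reference(lambda) * response(lambda)` (ripple included) plus a
#' small proportional noise term, sampled on the instrument grid restricted
#' to the overlap of the instrument range and the lamp's certified range.
#'
#' @param model an [InstrumentModel-class].
#' @param reference the lamp reference curve (a one-column
#'   [SpectraSet-class]), e.g. [lampReference()].
#' @param noiseProp proportional noise fraction (0 for an ideal
#'   measurement).
#' @param seed optional integer seed.
#' @return a one-column [SpectraSet-class] on the restricted grid.
#' @export
simulateLamp <- function(model, reference, noiseProp = 0.002, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  refWl <- wavelengths(reference)
  grid <- instrumentGrid(model)
  lo <- max(model@rangeNm[1], min(refWl))
  hi <- min(model@rangeNm[2], max(refWl))
  sel <- which(grid >= lo & grid <= hi)
  if (!length(sel))
    stop("no overlap between the instrument range and the lamp range")
  wl <- grid[sel]
  refI <- stats::approx(refWl, intensities(reference)[, 1L], xout = wl)$y
  meas <- refI * instrumentResponse(model, wl)
  if (noiseProp > 0)
    meas <- meas * (1 + stats::rnorm(length(meas), 0, noiseProp))
  Spectrum(wl, meas, instrument = model@label)
}

#' Simulate the full two-instrument study
#'
#' One call producing everything a cross-instrument experiment needs: the
#' two instrument models (registration shifts drawn from [0.05, 0.3] nm),
#' the low-resolution training dataset, the high-resolution test dataset
#' (with planted outliers), and the standard-lamp triple (certified
#' reference plus its measurement on each instrument).
#'
#' @param seed integer seed driving every random draw.
#' @param nPerClass spectra per class on each instrument.
#' @param outlierFraction fraction of corrupted spectra in the
#'   high-resolution (test) dataset; the training set is left clean.
#' @param nSamples sample slices per class.
#' @param lampNoise proportional noise on the measured lamp spectra.
#' @return a list with elements `lSet`, `hSet`, `lamps` (list `reference`,
#'   `measuredL`, `measuredH`), `models` (list `low`, `high`), and
#'   `profiles`.
#' @export
simulateStudy <- function(seed = 1L, nPerClass = 500L, outlierFraction = 0.1,
                          nSamples = 10L, lampNoise = 0.002) {
  set.seed(seed)
  modelL <- lowResInstrument()
  modelH <- highResInstrument()
  profiles <- defaultClassProfiles()
  reference <- lampReference()
  measuredL <- simulateLamp(modelL, reference, noiseProp = lampNoise)
  measuredH <- simulateLamp(modelH, reference, noiseProp = lampNoise)
  lSet <- simulateDataset(profiles, modelL, nPerClass, outlierFraction = 0,
                          nSamples = nSamples)
  hSet <- simulateDataset(profiles, modelH, nPerClass,
                          outlierFraction = outlierFraction,
                          nSamples = nSamples)
  gc(FALSE)
  list(lSet = lSet, hSet = hSet,
       lamps = list(reference = reference, measuredL = measuredL,
                    measuredH = measuredH),
       models = list(low = modelL, high = modelH), profiles = profiles)
}
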