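quietModel <- function(shift = 0, fwhm = 0.28, resp = function(wl) rep(1, length(wl)))
  lowResInstrument(shiftNm = shift, fwhmNm = fwhm, noiseAdd = 0,
                   noiseProp = 0, response = resp)

oneLine <- data.frame(species = "X", wavelength_nm = 500, rel_intensity = 1,
                      group = "none", width_nm = 0, peak_feature = TRUE)
flatProfile <- classProfile("p", sigmaSample = 0, sigmaShot = 0)

test_that("a rendered line peaks at its shifted centre within one grid step", {
  m <- quietModel(shift = 0.17)
  s <- renderSpectrum(flatProfile, m, lineList = oneLine, noise = FALSE)
  wl <- wavelengths(s)
  step <- wl[2] - wl[1]
  expect_lt(abs(wl[which.max(intensities(s)[, 1])] - 500.17), step)
})

test_that("line area is conserved: narrower broadening gives taller peaks", {
  sN <- renderSpectrum(flatProfile, quietModel(fwhm = 0.22),
                       lineList = oneLine, noise = FALSE)
  sW <- renderSpectrum(flatProfile, quietModel(fwhm = 0.30),
                       lineList = oneLine, noise = FALSE)
  expect_gt(max(intensities(sN)), max(intensities(sW)))
  step <- diff(wavelengths(sN))[1]
  expect_equal(sum(intensities(sN)) * step, sum(intensities(sW)) * step,
               tolerance = 1e-6)
})

test_that("rendering is linear in the response and in line intensities", {
  s1 <- renderSpectrum(flatProfile, quietModel(), lineList = oneLine,
                       noise = FALSE)
  s2 <- renderSpectrum(flatProfile,
                       quietModel(resp = function(wl) rep(2, length(wl))),
                       lineList = oneLine, noise = FALSE)
  expect_equal(intensities(s2), 2 * intensities(s1), tolerance = 1e-12)
  two <- oneLine; two$rel_intensity <- 2
  s3 <- renderSpectrum(flatProfile, quietModel(), lineList = two,
                       noise = FALSE)
  expect_equal(intensities(s3), 2 * intensities(s1), tolerance = 1e-12)
})

test_that("rendering fails when no line falls inside the range", {
  far <- oneLine; far$wavelength_nm <- 1500
  expect_error(renderSpectrum(flatProfile, quietModel(), lineList = far),
               "no emission line")
})

test_that("simulateDataset produces balanced labeled sets with flagged outliers", {
  prof <- defaultClassProfiles()
  m <- lowResInstrument(shiftNm = 0.1)
  d <- simulateDataset(prof, m, nPerClass = 20, outlierFraction = 0.1,
                       seed = 5, nSamples = 4)
  expect_equal(ncol(d), 60L)
  expect_equal(as.vector(table(spectrumLabels(d))), rep(20L, 3))
  cd <- SummarizedExperiment::colData(d)
  expect_equal(sum(cd$outlier), 6L)
  expect_setequal(unique(cd$outlier_type[cd$outlier]), c("collapse", "surge"))
  expect_error(simulateDataset(prof, m, 20, outlierFraction = 0.6, seed = 1,
                               nSamples = 4), "outlierFraction")
})

test_that("simulateDataset is deterministic under a fixed seed", {
  prof <- defaultClassProfiles()
  m <- lowResInstrument(shiftNm = 0.1)
  d1 <- simulateDataset(prof, m, 10, outlierFraction = 0.2, seed = 9,
                        nSamples = 2)
  d2 <- simulateDataset(prof, m, 10, outlierFraction = 0.2, seed = 9,
                        nSamples = 2)
  expect_identical(intensities(d1), intensities(d2))
  expect_identical(SummarizedExperiment::colData(d1),
                   SummarizedExperiment::colData(d2))
})

test_that("simulated lamp measurements reflect response, ripple and scale", {
  ref <- lampReference()
  unit <- quietModel()
  meas <- simulateLamp(unit, ref, noiseProp = 0)
  wl <- wavelengths(meas)
  refOn <- approx(wavelengths(ref), intensities(ref)[, 1], wl)$y
  expect_equal(intensities(meas)[, 1], refOn, tolerance = 1e-9)
  # scaling the reference scales the measurement
  ref2 <- SpectraSet(wavelengths(ref), 2 * intensities(ref))
  expect_equal(intensities(simulateLamp(unit, ref2, noiseProp = 0)),
               2 * intensities(meas), tolerance = 1e-12)
  # echelle ripple appears in the measured lamp but not in the reference
  h <- highResInstrument(shiftNm = 0.1, noiseAdd = 0, noiseProp = 0)
  measH <- simulateLamp(h, ref, noiseProp = 0)
  ratio <- intensities(measH)[, 1] /
    approx(wavelengths(ref), intensities(ref)[, 1], wavelengths(measH))$y
  smooth <- h@response(wavelengths(measH))
  modulation <- ratio / smooth - 1
  expect_gt(sd(modulation), 0.05)  # 15% ripple present
  expect_error(simulateLamp(quietModel(), Spectrum(c(2000, 2100), c(1, 1))),
               "overlap")
})

test_that("between-class contrast concentrates in the emphasized bands", {
  ll <- defaultLineList()
  prof <- defaultClassProfiles()
  m <- lowResInstrument(shiftNm = 0.12)
  hits <- logical(10)
  for (i in 1:10) {
    d <- simulateDataset(prof, m, nPerClass = 20, seed = 100 + i,
                         nSamples = 4)
    rk <- anovaRank(minmaxNormalize(d),
                    candidates = ll$wavelength_nm + m@shiftNm)
    grp <- ll$group[vapply(rk$wavelength_nm, function(w)
      which.min(abs(ll$wavelength_nm + m@shiftNm - w)), integer(1))]
    hits[i] <- mean(rk$f_value[grp != "none"]) > mean(rk$f_value[grp == "none"])
  }
  expect_true(all(hits))
})
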