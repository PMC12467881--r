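test_that("linear interpolation is exact on linear signals and on the same grid", {
  set.seed(2)
  wl <- sort(runif(40, 300, 900))
  s <- toySet(matrix(3 * wl + 1, ncol = 1), wl = wl)
  q <- seq(min(wl), max(wl), length.out = 37)
  out <- interpAlign(s, q)
  expect_lt(max(abs(intensities(out)[, 1] - (3 * q + 1))), 1e-10)
  same <- interpAlign(s, wl)
  expect_equal(intensities(same), intensities(s), tolerance = 1e-14)
  expect_error(interpAlign(s, c(min(wl) - 1, 500)), "extrapolation")
})

test_that("interpolation matches the two-point interval oracle on random grids", {
  set.seed(17)
  for (i in 1:50) {
    wl <- sort(runif(sample(5:30, 1), 0, 100))
    y <- rnorm(length(wl))
    q <- sort(runif(20, min(wl), max(wl)))
    got <- intensities(interpAlign(toySet(matrix(y, ncol = 1), wl = wl), q))[, 1]
    expect_equal(got, oracleInterp(wl, y, q), tolerance = 1e-12)
  }
})

test_that("estimateResponse recovers identity, ratios, and known responses", {
  wl <- seq(350, 1000, by = 0.5)
  ref <- Spectrum(wl, 1 + (wl - 350) / 650)
  expect_equal(estimateResponse(ref, ref, smooth = FALSE)@value,
               rep(1, length(wl)), tolerance = 1e-12)
  half <- Spectrum(wl, 2 * intensities(ref)[, 1])
  expect_equal(estimateResponse(ref, half, smooth = FALSE)@value,
               rep(0.5, length(wl)), tolerance = 1e-12)
  # simulator lamp with known response eta, no noise: R proportional to 1/eta
  m <- lowResInstrument(shiftNm = 0.1, noiseAdd = 0, noiseProp = 0)
  grid <- instrumentGrid(m)
  refG <- lampReference(grid = grid[grid >= 350 & grid <= 1000])
  meas <- simulateLamp(m, refG, noiseProp = 0)
  r <- estimateResponse(refG, meas, smooth = FALSE)
  prod <- r@value * instrumentResponse(m, r@wavelength)
  expect_lt(max(abs(prod / mean(prod) - 1)), 1e-6)
})

test_that("estimateResponse masks floor points and rejects hopeless lamps", {
  wl <- seq(400, 500, by = 1)
  ref <- Spectrum(wl, rep(2, length(wl)))
  bad <- rep(1, length(wl)); bad[50] <- 0
  expect_warning(r <- estimateResponse(ref, Spectrum(wl, bad), smooth = FALSE),
                 "masked")
  expect_equal(r@value[50], 2, tolerance = 1e-9)  # filled from neighbours
  hopeless <- rep(0, length(wl)); hopeless[1:40] <- 1
  expect_error(estimateResponse(ref, Spectrum(wl, hopeless), smooth = FALSE),
               "20%")
})

test_that("buildTransfer forms the high/low ratio on the clipped overlap", {
  wl <- seq(300, 900, by = 0.5)
  rl <- ResponseFunction(wl, 1 + wl / 1000)
  expect_equal(buildTransfer(rl, rl)@value,
               rep(1, sum(wl >= 350 & wl <= 850)), tolerance = 1e-12)
  ones <- ResponseFunction(wl, rep(1, length(wl)))
  rh <- ResponseFunction(wl, 2 / (1 + wl / 1000))
  tr <- buildTransfer(ones, rh)
  expect_equal(tr@value, 2 / (1 + tr@wavelength / 1000), tolerance = 1e-12)
  expect_true(tr@validRange[1] >= 350 && tr@validRange[2] <= 850)
  far <- ResponseFunction(seq(100, 200), rep(1, 101))
  expect_error(buildTransfer(rl, far), "overlap")
})

test_that("corrected high-res flat-source spectra match the low-res measurement", {
  mL <- lowResInstrument(shiftNm = 0.08, noiseAdd = 0, noiseProp = 0)
  mH <- highResInstrument(shiftNm = 0.21, noiseAdd = 0, noiseProp = 0)
  ref <- lampReference()
  rL <- estimateResponse(ref, simulateLamp(mL, ref, noiseProp = 0),
                         smooth = FALSE)
  rH <- estimateResponse(ref, simulateLamp(mH, ref, noiseProp = 0),
                         smooth = FALSE)
  tr <- buildTransfer(rL, rH)
  # a flat-spectrum source measured by each instrument is its response curve
  flat <- Spectrum(seq(350, 1000, by = 0.5), rep(1, 1301))
  measH <- simulateLamp(mH, flat, noiseProp = 0)
  measL <- simulateLamp(mL, flat, noiseProp = 0)
  corr <- applyCorrection(measH, tr)
  target <- intensities(interpAlign(measL, wavelengths(corr)))[, 1]
  got <- intensities(corr)[, 1]
  ratio <- got / target
  rms <- sqrt(mean((ratio / mean(ratio) - 1)^2))
  expect_lt(rms, 0.02)
})

test_that("applyCorrection is the identity for R == 1 and linear in R", {
  wl <- seq(300, 900, by = 0.25)
  set.seed(4)
  s <- toySet(matrix(rexp(length(wl) * 2), ncol = 2), wl = wl)
  ones <- ResponseFunction(seq(350, 850, by = 1), rep(1, 501))
  c1 <- applyCorrection(s, ones)
  keep <- wl >= 350 & wl <= 850
  expect_equal(intensities(c1), intensities(s)[keep, ], tolerance = 1e-12)
  twos <- ResponseFunction(seq(350, 850, by = 1), rep(2, 501))
  expect_equal(intensities(applyCorrection(s, twos)), 2 * intensities(c1),
               tolerance = 1e-12)
  expect_true(all(wavelengths(c1) >= 350 & wavelengths(c1) <= 850))
  off <- ResponseFunction(seq(1000, 1100), rep(1, 101), c(1000, 1100))
  expect_error(applyCorrection(s, off), "overlap")
})

test_that("per-spectrum normalization cancels any global response scale", {
  wl <- seq(360, 840, by = 0.5)
  set.seed(5)
  s <- toySet(matrix(rexp(length(wl)) + 0.1, ncol = 1), wl = wl)
  base <- ResponseFunction(wl, 1 + (wl - 360) / 480)
  scaled <- ResponseFunction(wl, 7.3 * base@value)
  n1 <- minmaxNormalize(applyCorrection(s, base))
  n2 <- minmaxNormalize(applyCorrection(s, scaled))
  expect_equal(intensities(n1), intensities(n2), tolerance = 1e-12)
})

test_that("band intensities around each line survive correction across resolutions", {
  # same emission source rendered on both instruments, no noise: after
  # correction the high-res band integrals match the low-res rendering's
  # relative band pattern (resolution-insensitive comparison)
  ll <- defaultLineList()
  prof <- classProfile("p", sigmaSample = 0, sigmaShot = 0)
  mL <- lowResInstrument(shiftNm = 0.1, noiseAdd = 0, noiseProp = 0)
  mH <- highResInstrument(shiftNm = 0.1, noiseAdd = 0, noiseProp = 0)
  sL <- renderSpectrum(prof, mL, lineList = ll, noise = FALSE)
  sH <- renderSpectrum(prof, mH, lineList = ll, noise = FALSE)
  ref <- lampReference()
  rL <- estimateResponse(ref, simulateLamp(mL, ref, noiseProp = 0), smooth = FALSE)
  rH <- estimateResponse(ref, simulateLamp(mH, ref, noiseProp = 0), smooth = FALSE)
  corrH <- applyCorrection(sH, buildTransfer(rL, rH))
  bandSum <- function(s, centre) {
    wl <- wavelengths(s)
    step <- stats::median(diff(wl))
    sum(intensities(s)[abs(wl - centre - 0.1) <= 0.5, 1]) * step
  }
  lines <- ll$wavelength_nm[ll$peak_feature & ll$wavelength_nm > 360 &
                              ll$wavelength_nm < 840]
  bL <- vapply(lines, bandSum, numeric(1), s = sL)
  bH <- vapply(lines, bandSum, numeric(1), s = corrH)
  relL <- bL / sum(bL); relH <- bH / sum(bH)
  expect_lt(max(abs(relH / relL - 1)), 0.05)
})
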