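# A flat-ish grid with one or more Gaussian peaks, for matching tests.
peakSet <- function(centres, heights, wl = seq(760, 775, by = 0.02),
                    noiseSd = 5, n = 4, fwhm = 0.05, seed = 1,
                    labels = NULL) {
  set.seed(seed)
  sigma <- fwhm / 2.3548
  base <- rowSums(vapply(seq_along(centres), function(i)
    heights[i] * exp(-(wl - centres[i])^2 / (2 * sigma^2)),
    numeric(length(wl))))
  mat <- vapply(seq_len(n), function(i) base + rnorm(length(wl), 0, noiseSd),
                numeric(length(wl)))
  toySet(mat, wl = wl, labels = labels)
}

test_that("detectPeaks finds thresholded class-mean maxima and warns when none", {
  wl <- seq(760, 775, by = 0.25)
  peak <- 3000 * exp(-(wl - 766.49)^2 / (2 * 0.12^2))
  s <- toySet(cbind(peak, peak), wl = wl, labels = c("a", "b"))
  got <- detectPeaks(s, threshold = 1500)
  expect_equal(nrow(got), 1L)
  expect_equal(got$wavelength_nm, wl[which.min(abs(wl - 766.49))])
  flat <- toySet(matrix(10, 30, 2), labels = c("a", "b"))
  expect_warning(none <- detectPeaks(flat, threshold = 1500), "no peak")
  expect_equal(nrow(none), 0L)
})

test_that("detectPeaks output shrinks as the threshold rises (set inclusion)", {
  wl <- seq(400, 420, by = 0.2)
  s <- toySet(matrix(4000 * exp(-(wl - 405)^2 / 0.05) +
                       2000 * exp(-(wl - 415)^2 / 0.05), ncol = 1),
              wl = wl, labels = "a")
  lo <- detectPeaks(s, threshold = 1500)
  hi <- detectPeaks(s, threshold = 3000)
  expect_true(all(hi$wavelength_nm %in% lo$wavelength_nm))
  expect_lt(nrow(hi), nrow(lo))
})

test_that("matchPeaks tolerates shifts within tol and reports fallbacks", {
  ref <- data.frame(wavelength_nm = 766.49, species = "K I",
                    origin = "peak-set")
  shifted <- peakSet(766.60, 3000)   # 0.11 nm shift
  ft <- matchPeaks(ref, minmaxNormalize(shifted), tolNm = 0.3)
  expect_equal(featureInfo(ft)$match_rate, 1)
  expect_true(all(featureMatrix(ft) > 0.9))  # matched at the peak
  none <- peakSet(770.0, 3000)       # nearest peak 3.5 nm away
  ft2 <- matchPeaks(ref, minmaxNormalize(none), tolNm = 0.3)
  expect_equal(featureInfo(ft2)$match_rate, 0)
  expect_true(all(featureMatrix(ft2) < 0.2))  # nominal-wavelength fallback
})

test_that("equidistant match candidates resolve to the lower wavelength", {
  wl <- seq(500, 510, by = 0.1)
  ref <- data.frame(wavelength_nm = 505, species = NA, origin = "peak-set")
  spec <- 10 + 1000 * exp(-(wl - 504.8)^2 / (2 * 0.03^2)) +
    1000 * exp(-(wl - 505.2)^2 / (2 * 0.03^2))
  s <- toySet(matrix(spec, ncol = 1), wl = wl)
  ft <- matchPeaks(ref, s, tolNm = 0.3)
  expect_equal(featureInfo(ft)$match_rate, 1)
  # both candidates have the same height; value must come from 504.8
  expect_equal(unname(featureMatrix(ft)[1, 1]), spec[wl == 504.8])
})

test_that("the one-way F statistic matches hand-worked and aov oracles", {
  g <- rep(1:3, each = 3)
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  s <- toySet(rbind(v, v), wl = c(1, 2), labels = g)
  rk <- anovaRank(s, candidates = 1)
  expect_equal(rk$f_value, 3)   # SSB = 6, SSW = 6, k = 3, N = 9
  same <- toySet(rbind(rep(1:3, 3), rep(1:3, 3)), wl = c(1, 2),
                 labels = rep(1:3, each = 3))
  # identical group means and spreads -> F = 0 would need SSB = 0:
  ident <- toySet(rbind(rep(5, 9), rep(5, 9)), wl = c(1, 2), labels = g)
  expect_equal(anovaRank(ident, candidates = 1)$f_value, 0)
  set.seed(23)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    ni <- sample(3:8, k, replace = TRUE)
    gg <- rep(seq_len(k), times = ni)
    vv <- rnorm(length(gg), mean = gg * runif(1, 0, 2))
    ss <- toySet(rbind(vv, vv), wl = c(1, 2), labels = gg)
    expect_equal(anovaRank(ss, candidates = 1)$f_value,
                 oracleAnovaF(vv, gg), tolerance = 1e-10)
  }
})

test_that("F-values are invariant to common affine transforms and rank Inf first", {
  set.seed(31)
  g <- rep(letters[1:3], each = 10)
  v <- rnorm(30, as.integer(factor(g)))
  f1 <- anovaRank(toySet(rbind(v, v), wl = 1:2, labels = g),
                  candidates = 1)$f_value
  f2 <- anovaRank(toySet(rbind(100 + 7 * v, v), wl = 1:2, labels = g),
                  candidates = 1)$f_value
  expect_equal(f1, f2, tolerance = 1e-9)
  # zero within-class variance with distinct means -> Inf, ranked first
  z <- rep(c(1, 2, 3), each = 5)
  s <- toySet(rbind(z, rnorm(15, z)), wl = c(1, 2), labels = rep(1:3, each = 5))
  rk <- anovaRank(s, candidates = c(1, 2))
  expect_equal(rk$f_value[1], Inf)
  expect_equal(rk$wavelength_nm[1], 1)
})

test_that("anovaRank validates its class structure", {
  one <- toySet(matrix(1:10, 2), labels = rep("a", 5))
  expect_error(anovaRank(one, candidates = 1), "2 classes")
  thin <- toySet(matrix(1:6, 2), labels = c("a", "b", "b"))
  expect_error(anovaRank(thin, candidates = 1), "at least 2 spectra")
})

test_that("incremental selection respects the base set, dedups, and is deterministic", {
  # separable two-instrument toy problem on a shared coarse grid
  set.seed(6)
  wl <- seq(400, 500, length.out = 200)
  mk <- function(n) {
    labs <- rep(c("a", "b", "c"), each = n)
    mat <- vapply(seq_along(labs), function(i) {
      mu <- c(a = 1, b = 2, c = 3)[[labs[i]]]
      3000 * exp(-(wl - 420)^2 / 2) * mu +
        3000 * exp(-(wl - 470)^2 / 2) / mu +
        2000 * exp(-(wl - 450)^2 / 2) +
        rnorm(length(wl), 0, 20)
    }, numeric(length(wl)))
    toySet(mat, wl = wl, labels = labs)
  }
  train <- mk(20); test <- mk(12)
  base <- detectPeaks(train, threshold = 1500)
  rk <- anovaRank(minmaxNormalize(train),
                  candidates = candidateWavelengths(train, 1500))
  cfg <- forestConfig(nTrees = 60, seed = 3)
  s0 <- selectIncremental(base, rk, minmaxNormalize(train),
                          minmaxNormalize(test), maxAdded = 0, cfg = cfg)
  expect_equal(nrow(s0$curve), 1L)
  expect_setequal(s0$features$wavelength_nm, base$wavelength_nm)
  s5 <- selectIncremental(base, rk, minmaxNormalize(train),
                          minmaxNormalize(test), maxAdded = 5, cfg = cfg)
  # base peaks are also top-ranked candidates; dedup must skip them
  expect_gt(s5$nSkipped, 0)
  expect_true(all(base$wavelength_nm %in% s5$features$wavelength_nm))
  expect_true(all(s5$curve$accuracy >= 0 & s5$curve$accuracy <= 1))
  expect_equal(diff(s5$curve$n_features), rep(1, nrow(s5$curve) - 1))
  s5b <- selectIncremental(base, rk, minmaxNormalize(train),
                           minmaxNormalize(test), maxAdded = 5, cfg = cfg)
  expect_identical(s5$curve, s5b$curve)
  expect_identical(s5$features, s5b$features)
})

test_that("the lazy normalized view reproduces the materialized chain exactly", {
  set.seed(8)
  wl <- seq(300, 900, by = 0.5)
  mat <- matrix(rexp(length(wl) * 6) + 10, ncol = 6)
  mat[300, ] <- 5000  # a shared peak
  s <- toySet(mat, wl = wl, labels = rep(c("a", "b"), 3))
  r <- ResponseFunction(seq(350, 850, 2), 1 + seq(350, 850, 2) / 1000)
  feat <- data.frame(wavelength_nm = wl[300], species = NA,
                     origin = "peak-set")
  dense <- matchPeaks(feat, minmaxNormalize(applyCorrection(s, r)))
  lazy <- matchPeaks(feat, normalizedView(s, r))
  expect_identical(featureMatrix(dense), featureMatrix(lazy))
  denseN <- matchPeaks(feat, minmaxNormalize(s))
  lazyN <- matchPeaks(feat, normalizedView(s))
  expect_identical(featureMatrix(denseN), featureMatrix(lazyN))
})
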