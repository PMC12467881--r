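# Independent oracles and small fixture builders shared across the suite.

# Two-point linear interpolation, written directly from the interval
# formula (independent of stats::approx).
oracleInterp <- function(x, y, xout) {
  vapply(xout, function(q) {
    if (q <= x[1]) return(y[1])
    i <- max(which(x <= q))
    if (x[i] == q) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (q - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# One-way ANOVA F through R's linear-model machinery.
oracleAnovaF <- function(values, groups) {
  summary(stats::aov(values ~ factor(groups)))[[1]]$`F value`[1]
}

# DBSCAN by explicit density reachability: adjacency of the eps-graph,
# cores by neighbourhood size (self included), clusters grown by
# breadth-first search over core points; border points attach to the
# first core cluster that reaches them; the rest is noise (0).
oracleDbscan <- function(X, eps, minPts) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  adj <- D <= eps
  core <- rowSums(adj) >= minPts
  labels <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (core[v]) {
        reach <- which(adj[v, ])
        for (w in reach) {
          if (labels[w] == 0L) {
            labels[w] <- cl
            if (core[w]) queue <- c(queue, w)
          }
        }
      }
    }
  }
  labels
}

# Canonical cluster labels: renumber by order of first appearance so two
# labelings of the same partition compare equal (noise 0 is kept).
canonicalLabels <- function(labels) {
  pos <- labels > 0L
  u <- unique(labels[pos])
  out <- labels
  out[pos] <- match(labels[pos], u)
  out
}

# Confusion-matrix tally by explicit double loop.
oracleConfusion <- function(true, pred) {
  lev <- sort(union(true, pred))
  M <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(true))
    M[true[i], pred[i]] <- M[true[i], pred[i]] + 1L
  M
}

# Small labeled SpectraSet straight from a matrix.
toySet <- function(mat, wl = seq_len(nrow(mat)), labels = NULL,
                   instrument = "toy", sample_id = NULL) {
  cd <- NULL
  if (!is.null(sample_id))
    cd <- S4Vectors::DataFrame(sample_id = sample_id)
  SpectraSet(wl, mat, labels = labels, instrument = instrument, colData = cd)
}

# A linearly separable two-feature toy classification set.
toyFeatureTable <- function(n = 30, seed = 42) {
  set.seed(seed)
  x1 <- c(rnorm(n, 0), rnorm(n, 5), rnorm(n, 10))
  x2 <- c(rnorm(n, 5), rnorm(n, 0), rnorm(n, 10))
  FeatureTable(cbind(x1, x2),
               data.frame(wavelength_nm = c(400, 500),
                          species = NA_character_, origin = "peak-set"),
               labels = rep(c("a", "b", "c"), each = n))
}

# Reduced-size two-instrument study, computed once and cached for the
# pipeline tests (full grids, fewer spectra).
miniStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateStudy(seed = 7, nPerClass = 60L, nSamples = 6L)
    cache
  }
})

miniConfig <- function(seed = 7L) pipelineConfig(seed = seed, maxAdded = 8L)
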