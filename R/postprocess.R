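#' DBSCAN configuration
#'
#' @param eps neighbourhood radius in feature space (Euclidean). `NULL`
#'   requests automatic selection from the K-distance elbow at run time.
#' @param minPts minimum number of points (the point itself included)
#'   within `eps` for a core point.
#' @return a `dbscanConfig` list.
#' @export
dbscanConfig <- function(eps = 2.5, minPts = 15L) {
  if (!is.null(eps) && eps <= 0) stop("eps must be > 0")
  if (minPts < 2L) stop("minPts must be >= 2")
  structure(list(eps = eps, minPts = as.integer(minPts)),
            class = "dbscanConfig")
}

#' K-distance graph for DBSCAN parameter selection
#'
#' Computes the Euclidean distance of every sample to its k-th nearest
#' neighbour and sorts the distances in ascending order. Where the local
#' density drops the curve bends upward; the distance at that elbow is a
#' suitable DBSCAN `eps`. The elbow is automated as the point of the
#' lightly smoothed curve farthest below the chord joining its endpoints
#' (a kneedle-style knee criterion), with a manual override available
#' wherever the curve is consumed.
#'
#' @param x a [FeatureTable-class] or numeric matrix (rows = samples).
#' @param k neighbour order (`k < nrow`).
#' @return a `kDistanceCurve` list: `k`, `distances` (ascending),
#'   `suggestedEps`.
#' @export
kDistance <- function(x, k) {
  X <- if (methods::is(x, "FeatureTable")) featureMatrix(x) else as.matrix(x)
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of samples")
  D <- as.matrix(stats::dist(X))
  kd <- vapply(seq_len(n), function(i) sort(D[i, -i], partial = k)[k],
               numeric(1L))
  curve <- sort(kd)
  structure(list(k = as.integer(k), distances = curve,
                 suggestedEps = .elbowEps(curve)),
            class = "kDistanceCurve")
}

# Elbow of an ascending k-distance curve: the point of maximum vertical
# distance below the chord joining the curve's endpoints (a kneedle-style
# criterion). On a flat-then-rising curve this lands where the dense bulk
# ends and the sparse tail begins, and it is robust to jaggedness inside
# the tail where a raw maximum-curvature rule tends to fire.
.elbowEps <- function(curve) {
  n <- length(curve)
  if (n < 5L) return(curve[n])
  win <- max(5L, round(n / 50))
  if (win %% 2L == 0L) win <- win + 1L
  sm <- as.numeric(stats::filter(curve, rep(1 / win, win), sides = 2))
  half <- (win - 1L) %/% 2L
  sm[seq_len(half)] <- curve[seq_len(half)]
  sm[(n - half + 1L):n] <- curve[(n - half + 1L):n]
  chord <- sm[1L] + (sm[n] - sm[1L]) * (seq_len(n) - 1L) / (n - 1L)
  elbow <- which.max(chord - sm)
  curve[elbow]
}

# Classic DBSCAN over a precomputed neighbour structure. Core points have
# >= minPts points (themselves included) within eps; clusters grow by
# density reachability from core points; border points (non-core within
# eps of a core) join that core's cluster; everything else is noise (0).
.dbscanLabels <- function(X, eps, minPts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1L)) >= minPts
  labels <- integer(n)  # 0 = noise/unvisited
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    frontier <- setdiff(nbrs[[i]], i)
    while (length(frontier)) {
      j <- frontier[1L]
      frontier <- frontier[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cluster
        if (core[j])
          frontier <- c(frontier, nbrs[[j]][labels[nbrs[[j]]] == 0L])
      }
    }
  }
  list(labels = labels, core = core)
}

#' DBSCAN-based removal of abnormal spectra
#'
#' Runs density-based clustering on the feature matrix and removes the
#' points labelled noise — those that are neither core points (at least
#' `minPts` points, themselves included, within radius `eps`) nor border
#' points of a cluster. Intended for unsupervised screening of a test set
#' before evaluation: abnormal acquisitions fall in low-density regions of
#' feature space and are excluded rather than force-classified.
#'
#' @param x a [FeatureTable-class].
#' @param cfg a [dbscanConfig()]; with `eps = NULL` the radius is taken
#'   from the K-distance elbow at `k = minPts`.
#' @return list with `retained` (the filtered [FeatureTable-class]),
#'   `outliers` (row indices removed), `clusterLabels` (integer labels, 0 =
#'   noise), `eps` (the radius used), and `countsByClass` (retained
#'   spectra per class label, when labels are present).
#' @export
dbscanFilter <- function(x, cfg = dbscanConfig()) {
  X <- featureMatrix(x)
  if (nrow(X) < cfg$minPts)
    stop("need at least minPts rows for density clustering")
  eps <- cfg$eps
  if (is.null(eps)) eps <- kDistance(x, cfg$minPts)$suggestedEps
  res <- .dbscanLabels(X, eps, cfg$minPts)
  out <- which(res$labels == 0L)
  if (length(out) == nrow(X))
    stop("all points were labelled noise; increase eps (used ",
         signif(eps, 4), ")")
  keep <- setdiff(seq_len(nrow(X)), out)
  retained <- x[keep, ]
  lb <- spectrumLabels(retained)
  list(retained = retained, outliers = out, clusterLabels = res$labels,
       eps = eps,
       countsByClass = if (!is.null(lb)) table(lb) else NULL)
}
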