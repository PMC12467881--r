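#' Random-forest configuration
#'
#' Defaults follow the tuned values for this classification task: 500
#' trees, minimum leaf size 20, and the standard `sqrt(p)` features per
#' split.
#'
#' @param nTrees number of trees.
#' @param minLeaf minimum number of observations in a leaf.
#' @param seed RNG seed applied before fitting (fits are deterministic
#'   given the seed).
#' @param mtry features tried per split; `NULL` means `floor(sqrt(p))`.
#' @param replace bootstrap with replacement (`TRUE`, the default forest);
#'   `FALSE` with full `sampsize` makes every tree see the full sample,
#'   useful for degenerate-forest diagnostics.
#' @return a `forestConfig` list.
#' @export
forestConfig <- function(nTrees = 500L, minLeaf = 20L, seed = 1L,
                         mtry = NULL, replace = TRUE) {
  if (nTrees < 1L) stop("nTrees must be >= 1")
  if (minLeaf < 1L) stop("minLeaf must be >= 1")
  structure(list(nTrees = as.integer(nTrees), minLeaf = as.integer(minLeaf),
                 seed = as.integer(seed), mtry = mtry, replace = replace),
            class = "forestConfig")
}

#' Gini impurity of a class-probability vector
#'
#' `G = sum_k p_k (1 - p_k)`: 0 for a pure node, `(k - 1) / k` for a
#' uniform k-class node. This is the split criterion the forest's trees
#' minimize.
#'
#' @param p class probabilities (must sum to 1).
#' @return the impurity.
#' @export
giniImpurity <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be a probability vector summing to 1")
  sum(p * (1 - p))
}

#' Fit a random-forest classifier on a feature table
#'
#' Grows `nTrees` Gini-split decision trees, each on a bootstrap resample
#' of the training rows with a random `mtry`-subset of features per split
#' (via [randomForest::randomForest]). Deterministic given `cfg$seed`.
#'
#' @param train a labeled [FeatureTable-class] with at least 2 classes.
#' @param cfg a [forestConfig()].
#' @return a `libsForest` model handle.
#' @export
fitForest <- function(train, cfg = forestConfig()) {
  y <- spectrumLabels(train)
  if (is.null(y)) stop("training feature table has no labels")
  lev <- sort(unique(y))
  if (length(lev) < 2L) stop("training set contains a single class")
  X <- featureMatrix(train)
  if (anyNA(X)) stop("missing feature values in the training set")
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(ncol(X)))) else cfg$mtry
  set.seed(cfg$seed)
  rf <- randomForest::randomForest(
    x = X, y = factor(y, levels = lev), ntree = cfg$nTrees,
    nodesize = cfg$minLeaf, mtry = mtry, replace = cfg$replace,
    sampsize = if (cfg$replace) nrow(X) else nrow(X))
  structure(list(model = rf, levels = lev,
                 featureWavelengths = featureInfo(train)$wavelength_nm,
                 cfg = cfg),
            class = "libsForest")
}

#' Predict class labels with a fitted forest
#'
#' Majority vote across trees; vote ties resolve deterministically to the
#' lowest class index (alphabetical class order).
#'
#' @param fit a `libsForest` from [fitForest()].
#' @param test a [FeatureTable-class] whose feature columns (wavelengths,
#'   in order) match the training table.
#' @return character vector of predicted labels.
#' @export
predictForest <- function(fit, test) {
  testWl <- featureInfo(test)$wavelength_nm
  if (length(testWl) != length(fit$featureWavelengths) ||
      any(testWl != fit$featureWavelengths)) {
    bad <- setdiff(round(testWl, 4), round(fit$featureWavelengths, 4))
    stop("test features do not match training features",
         if (length(bad)) paste0(" (offending wavelengths: ",
                                 paste(bad, collapse = ", "), ")"))
  }
  if (nrow(featureMatrix(test)) == 0L) return(character(0))
  votes <- stats::predict(fit$model, newdata = featureMatrix(test),
                          type = "vote", norm.votes = FALSE)
  fit$levels[apply(votes, 1L, which.max)]
}

#' Evaluate predictions against true labels
#'
#' @param true,pred equal-length label vectors.
#' @return a [ClassificationReport-class]: confusion matrix (rows = true,
#'   columns = predicted), overall accuracy, and per-class precision
#'   (`TP / column sum`) and recall (`TP / row sum`), reported as `NA` when
#'   the denominator is zero.
#' @export
evaluateClassification <- function(true, pred) {
  if (length(true) != length(pred))
    stop("true and pred must have equal length")
  lev <- sort(union(true, pred))
  conf <- table(factor(true, levels = lev), factor(pred, levels = lev))
  conf <- matrix(as.integer(conf), nrow = length(lev),
                 dimnames = list(true = lev, predicted = lev))
  tp <- diag(conf)
  colSum <- colSums(conf); rowSum <- rowSums(conf)
  precision <- ifelse(colSum > 0, tp / colSum, NA_real_)
  recall <- ifelse(rowSum > 0, tp / rowSum, NA_real_)
  names(precision) <- names(recall) <- lev
  methods::new("ClassificationReport", confusion = conf,
               accuracy = if (length(true)) sum(tp) / length(true) else NA_real_,
               precision = precision, recall = recall,
               nEvaluated = length(true))
}

#' Split a feature table under a study protocol
#'
#' `"single"`: within one instrument, per class, the first `trainFrac` of
#' spectra (in acquisition order, not shuffled) train and the remainder
#' test. `"cross"`: all of instrument A (`x`) trains, all of instrument B
#' (`y`) tests.
#'
#' @param x a labeled [FeatureTable-class] in acquisition order.
#' @param mode `"single"` or `"cross"`.
#' @param y the second instrument's [FeatureTable-class] (`"cross"` only).
#' @param trainFrac training fraction for `"single"`.
#' @param shuffle randomize order before the single-instrument split
#'   (off by default, matching ordered acquisition-block splitting).
#' @return list with elements `train` and `test`.
#' @export
splitProtocol <- function(x, mode = c("single", "cross"), y = NULL,
                          trainFrac = 0.7, shuffle = FALSE) {
  mode <- match.arg(mode)
  if (mode == "cross") {
    if (is.null(y)) stop("cross-instrument split needs both feature tables")
    return(list(train = x, test = y))
  }
  lb <- spectrumLabels(x)
  if (is.null(lb)) stop("single-instrument split needs labels")
  trainIdx <- integer(0); testIdx <- integer(0)
  for (cl in unique(lb)) {
    idx <- which(lb == cl)
    if (length(idx) < 10L)
      stop("class '", cl, "' has fewer than 10 spectra; cannot split ",
           trainFrac * 100, ":", (1 - trainFrac) * 100)
    if (shuffle) idx <- sample(idx)
    nTrain <- floor(trainFrac * length(idx))
    trainIdx <- c(trainIdx, idx[seq_len(nTrain)])
    testIdx <- c(testIdx, idx[(nTrain + 1L):length(idx)])
  }
  list(train = x[trainIdx, ], test = x[testIdx, ])
}
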