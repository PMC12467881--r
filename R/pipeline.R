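#' Pipeline configuration
#'
#' One configuration object drives every protocol. Defaults reproduce the
#' study conditions: Savitzky-Golay window 5 / order 3 on the
#' low-resolution data only, the 1500-count peak threshold, 0.3 nm
#' cross-instrument matching tolerance, a 500-tree forest with minimum
#' leaf size 20, correction limited to 350-850 nm, and DBSCAN with
#' `minPts = 15` and the K-distance elbow choosing `eps`.
#'
#' @param seed integer seed propagated to every stochastic stage.
#' @param sgWindow,sgOrder Savitzky-Golay parameters (window 1 disables
#'   smoothing).
#' @param block shot-averaging block size (1 = no averaging; raw
#'   acquisitions recorded shot-by-shot are typically averaged in blocks
#'   of 4 before analysis).
#' @param threshold peak/candidate intensity threshold (pre-normalization
#'   counts).
#' @param tolNm cross-instrument peak matching tolerance (nm).
#' @param maxAdded maximum ANOVA features added beyond the base peak set.
#' @param nTrees,minLeaf random-forest parameters.
#' @param dbscanMinPts,dbscanEps DBSCAN parameters (`NULL` eps = automatic
#'   elbow selection).
#' @param correctionRange wavelength limits (nm) of the response
#'   correction.
#' @param smoothResponse denoise estimated response functions.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(seed = 1L, sgWindow = 5L, sgOrder = 3L,
                           block = 1L, threshold = 1500, tolNm = 0.3,
                           maxAdded = 20L, nTrees = 500L, minLeaf = 20L,
                           dbscanMinPts = 15L, dbscanEps = NULL,
                           correctionRange = c(350, 850),
                           smoothResponse = TRUE) {
  structure(list(seed = as.integer(seed), sgWindow = as.integer(sgWindow),
                 sgOrder = as.integer(sgOrder), block = as.integer(block),
                 threshold = threshold, tolNm = tolNm,
                 maxAdded = as.integer(maxAdded),
                 nTrees = as.integer(nTrees), minLeaf = as.integer(minLeaf),
                 dbscanMinPts = as.integer(dbscanMinPts),
                 dbscanEps = dbscanEps, correctionRange = correctionRange,
                 smoothResponse = smoothResponse),
            class = "pipelineConfig")
}

.PROTOCOLS <- c("single-L", "single-H", "cross-raw", "cross-scfs",
                "cross-scfs-pp")

#' Run one or several experiment protocols
#'
#' Executes the stage chain of each requested protocol and returns a
#' [RunReport-class] per protocol:
#' * `single-L` / `single-H`: base peak features on one instrument,
#'   ordered 70:30 per-class split, forest trained and tested within the
#'   instrument.
#' * `cross-raw`: forest trained on all low-resolution spectra, tested on
#'   all (uncorrected) high-resolution spectra.
#' * `cross-scfs`: standard-lamp response correction of the test spectra,
#'   ANOVA-ranked incremental feature selection, then train/test as above.
#' * `cross-scfs-pp`: `cross-scfs` plus DBSCAN removal of abnormal test
#'   spectra before evaluation (same trained forest).
#'
#' Stages shared between requested protocols (preprocessing, correction,
#' feature selection) are computed once; results are identical to running
#' the module functions by hand with the same configuration, and
#' bit-identical across repeated calls with the same inputs and seed.
#'
#' @param lSet low-resolution (training instrument) labeled
#'   [SpectraSet-class], raw counts.
#' @param hSet high-resolution (test instrument) labeled
#'   [SpectraSet-class], raw counts.
#' @param lamps list with `reference`, `measuredL`, `measuredH` standard
#'   lamp spectra (needed by the cross protocols).
#' @param protocol character vector of protocols (see above).
#' @param cfg a [pipelineConfig()].
#' @return a named list of [RunReport-class] objects (one per protocol),
#'   or the single report when one protocol is requested.
#' @export
runProtocol <- function(lSet, hSet, lamps = NULL,
                        protocol = "cross-scfs", cfg = pipelineConfig()) {
  protocol <- match.arg(protocol, .PROTOCOLS, several.ok = TRUE)
  needCross <- any(protocol %in% c("cross-scfs", "cross-scfs-pp"))
  if (needCross && is.null(lamps))
    stop("cross-instrument correction protocols need the standard-lamp ",
         "spectra (lamps = list(reference, measuredL, measuredH))")
  set.seed(cfg$seed)
  fcfg <- forestConfig(nTrees = cfg$nTrees, minLeaf = cfg$minLeaf,
                       seed = cfg$seed)
  lineList <- S4Vectors::metadata(lSet)$line_list

  # -- shared preprocessing (low-resolution chain) ---------------------------
  if (cfg$block > 1L) lSet <- averageBlocks(lSet, cfg$block)
  sgL <- if (cfg$sgWindow > 1L)
    savgolSmooth(lSet, cfg$sgWindow, cfg$sgOrder) else lSet
  base <- detectPeaks(sgL, threshold = cfg$threshold, lineList = lineList)
  if (!nrow(base)) stop("no base peak features detected")
  normL <- minmaxNormalize(sgL)
  trainLFT <- extractFeatures(normL, base)

  gc(FALSE)
  rawHFT <- NULL
  needRawH <- any(protocol %in% c("single-H", "cross-raw"))
  if (needRawH)
    rawHFT <- matchPeaks(base, normalizedView(hSet), tolNm = cfg$tolNm)

  scfs <- NULL
  if (needCross) {
    rL <- estimateResponse(lamps$reference, lamps$measuredL,
                           smooth = cfg$smoothResponse)
    rH <- estimateResponse(lamps$reference, lamps$measuredH,
                           smooth = cfg$smoothResponse)
    transfer <- buildTransfer(rL, rH, clipRange = cfg$correctionRange)
    corrView <- normalizedView(hSet, transfer)
    ranking <- anovaRank(normL, candidateWavelengths(sgL, cfg$threshold))
    sel <- selectIncremental(base, ranking, normL, corrView,
                             maxAdded = cfg$maxAdded, cfg = fcfg,
                             tolNm = cfg$tolNm)
    fitBest <- fitForest(sel$trainBest, fcfg)
    scfs <- list(sel = sel, testBest = sel$testBest, fitBest = fitBest)
    gc(FALSE)
  }

  echo <- unclass(cfg)
  version <- as.character(utils::packageVersion("libsbridge"))
  singlePoint <- function(nFeat, acc)
    data.frame(n_features = nFeat, accuracy = acc)

  mkReport <- function(protocolName, report, featWl, curve, nRetained,
                       nRemoved, testInstr, extra = list()) {
    methods::new("RunReport", protocol = protocolName, report = report,
                 featureWavelengths = featWl, accuracyCurve = curve,
                 nRetained = as.integer(nRetained),
                 nRemoved = as.integer(nRemoved),
                 testInstrument = testInstr,
                 config = c(echo, extra), version = version)
  }

  runSingle <- function(ft, instr, name) {
    sp <- splitProtocol(ft, "single")
    fit <- fitForest(sp$train, fcfg)
    pred <- predictForest(fit, sp$test)
    rep <- evaluateClassification(spectrumLabels(sp$test), pred)
    mkReport(name, rep, featureInfo(ft)$wavelength_nm,
             singlePoint(ncol(featureMatrix(ft)), rep@accuracy),
             rep@nEvaluated, 0L, instr)
  }

  out <- list()
  for (p in protocol) {
    out[[p]] <- switch(
      p,
      "single-L" = runSingle(trainLFT, instrumentId(lSet), p),
      "single-H" = runSingle(rawHFT, instrumentId(hSet), p),
      "cross-raw" = {
        sp <- splitProtocol(trainLFT, "cross", y = rawHFT)
        fit <- fitForest(sp$train, fcfg)
        pred <- predictForest(fit, sp$test)
        rep <- evaluateClassification(spectrumLabels(sp$test), pred)
        mkReport(p, rep, featureInfo(trainLFT)$wavelength_nm,
                 singlePoint(ncol(featureMatrix(trainLFT)), rep@accuracy),
                 rep@nEvaluated, 0L, instrumentId(hSet))
      },
      "cross-scfs" = {
        pred <- predictForest(scfs$fitBest, scfs$testBest)
        rep <- evaluateClassification(spectrumLabels(scfs$testBest), pred)
        mkReport(p, rep, scfs$sel$features$wavelength_nm, scfs$sel$curve,
                 rep@nEvaluated, 0L, instrumentId(hSet))
      },
      "cross-scfs-pp" = {
        filt <- dbscanFilter(scfs$testBest,
                             dbscanConfig(eps = cfg$dbscanEps,
                                          minPts = cfg$dbscanMinPts))
        pred <- predictForest(scfs$fitBest, filt$retained)
        rep <- evaluateClassification(spectrumLabels(filt$retained), pred)
        mkReport(p, rep, scfs$sel$features$wavelength_nm, scfs$sel$curve,
                 rep@nEvaluated, length(filt$outliers), instrumentId(hSet),
                 extra = list(postprocess = list(
                   eps = filt$eps, outliers = filt$outliers,
                   countsByClass = filt$countsByClass)))
      })
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Summarize several protocol runs in one table
#'
#' @param reports list of [RunReport-class] objects evaluated on the same
#'   test instrument (at least 2).
#' @return data.frame with one row per protocol: feature count, spectra
#'   evaluated, accuracy, and per-class precision/recall.
#' @export
compareProtocols <- function(reports) {
  if (methods::is(reports, "RunReport")) reports <- list(reports)
  if (length(reports) < 2L)
    stop("need at least 2 reports to compare")
  instr <- vapply(reports, function(r) r@testInstrument, character(1L))
  if (length(unique(instr)) != 1L)
    stop("reports were evaluated on different test sources: ",
         paste(unique(instr), collapse = " vs "))
  rows <- lapply(reports, function(r) {
    cr <- r@report
    row <- data.frame(protocol = r@protocol,
                      n_features = length(r@featureWavelengths),
                      n_evaluated = cr@nEvaluated,
                      accuracy = cr@accuracy)
    for (cl in names(cr@precision)) {
      row[[paste0("precision_", cl)]] <- cr@precision[[cl]]
      row[[paste0("recall_", cl)]] <- cr@recall[[cl]]
    }
    row
  })
  do.call(rbind, rows)
}
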