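#' @include AllClasses.R preprocess.R ensembles.R downsample.R topology.R
#' @include coordinatize.R toroidal_maps.R hexatorus.R io.R
NULL

#' Run the covariate-free toroidal pipeline end to end
#'
#' Sequences the stages on a single population: square-root transform, speed
#' filter, optional ensemble clustering (largest retained ensemble is
#' analyzed), PCA whitening, two-step downsampling, persistent cohomology with
#' shuffle significance, circular coordinatization of the two longest H1 bars,
#' toroidal rate maps and hexagonal/square classification.
#'
#' @param rates raw \linkS4class{RateMatrix} at the topology resolution.
#' @param traj matching \linkS4class{TrajectorySample} (NULL to skip the speed
#'   filter; stored speed is used when available).
#' @param profile a \linkS4class{ParameterProfile}.
#' @param clusterRates optional \linkS4class{RateMatrix} at the clustering
#'   resolution; enables the ensemble-detection stage.
#' @param nShuffles shuffles for barcode significance (0 skips the null).
#' @param maxdim largest homological dimension.
#' @param seed RNG seed (shuffle null).
#' @param stages character subset of \code{c("cluster", "topology", "decode",
#'   "classify")}; later stages require earlier ones.
#' @param outputDir if non-NULL, barcode (JSON), coordinates (CSV) and a run
#'   report (JSON, including the parameter hash and seed) are written here.
#' @return List with the intermediate objects: \code{ensembles},
#'   \code{filtered}, \code{landmarks}, \code{barcode}, \code{counts},
#'   \code{coords}, \code{classification}, \code{report}.
#' @export
runPipeline <- function(rates, traj = NULL, profile = parameterProfile(),
                        clusterRates = NULL, nShuffles = 100, maxdim = 2,
                        seed = 1L,
                        stages = c("cluster", "topology", "decode", "classify"),
                        outputDir = NULL) {
  stopifnot(is(rates, "RateMatrix"), is(profile, "ParameterProfile"))
  res <- list(profile = profile, seed = seed)
  sel <- seq_len(nrow(rates))

  if ("cluster" %in% stages && !is.null(clusterRates)) {
    cc <- crossCorr(clusterRates, profile@tauMax)
    C <- inverseNormCrossCorr(cc)
    part <- clusterEnsembles(C, profile@rhoCluster)
    res$ensembles <- part
    if (!any(part@labels == 1L))
      stop("stage cluster: no ensemble of at least 19 neurons found")
    sel <- which(part@labels == 1L)
  }

  r <- rates[sel, ]
  r <- sqrtTransform(r)
  if (!is.null(traj) || !is.null(SummarizedExperiment::colData(r)$speed))
    r <- speedFilter(r, traj, vMin = profile@speedMin)
  res$filtered <- r

  if (!"topology" %in% stages) return(.finishPipeline(res, outputDir))

  topo <- .topologyFromRates(r, profile, maxdim = maxdim)
  bc <- topo$barcode
  if (nShuffles > 0) {
    th <- shuffleNull(r, profile, nShuffles = nShuffles, seed = seed,
                      maxdim = maxdim)
    bc <- setShuffleThresholds(bc, th)
    res$counts <- vapply(0:maxdim, function(d) countSignificantBars(bc, d),
                         integer(1))
    names(res$counts) <- paste0("H", 0:maxdim)
  }
  res$cloud <- topo$cloud
  res$landmarks <- topo$landmarks
  res$barcode <- bc

  if (!"decode" %in% stages) return(.finishPipeline(res, outputDir))

  rows <- longestBars(bc, 1, 2)
  if (length(rows) < 2)
    stop("stage decode: fewer than two H1 bars available")
  cc2 <- circularCoords(bc, rows, topo$landmarks)
  keep_cols <- which(keepMask(r))
  land_cols <- match(topo$landmarks@index, keep_cols)
  v <- rateValues(r)[, keep_cols, drop = FALSE]
  landmarkRates <- v[, land_cols, drop = FALSE]
  coords <- extrapolateCoords(cc2, landmarkRates, v)
  coords@t <- sampleTimes(r)[keep_cols]
  res$circular <- cc2
  res$landmarkRates <- landmarkRates
  res$coords <- coords

  if (!"classify" %in% stages) return(.finishPipeline(res, outputDir))

  landAngles <- cbind(cc2[[1]]@angle, cc2[[2]]@angle)
  maps10 <- peaks <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    maps10[[i]] <- .toroidalBinMap(landmarkRates[i, ], landAngles, 10)$values
    m16 <- .toroidalBinMap(landmarkRates[i, ], landAngles, 16)$values
    peaks[[i]] <- toroidalPeak(pmax(m16, 0))
  }
  res$unitMaps <- maps10
  res$peaks <- peaks
  res$classification <- classifyTorus(maps10, peaks)

  .finishPipeline(res, outputDir)
}

.finishPipeline <- function(res, outputDir) {
  report <- list(
    config_hash = .configHash(list(res$profile, res$seed)),
    seed = res$seed,
    n_neurons = if (!is.null(res$filtered)) nrow(res$filtered) else NA,
    n_landmarks = if (!is.null(res$landmarks)) nLandmarks(res$landmarks)
                  else NA,
    significant_bars = if (!is.null(res$counts)) as.list(res$counts) else NULL,
    classification = if (!is.null(res$classification))
      list(label = res$classification@label,
           hex_median = res$classification@hexMedian,
           sqr_median = res$classification@sqrMedian) else NULL)
  res$report <- report
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$barcode))
      writeBarcode(res$barcode, file.path(outputDir, "barcode.json"))
    if (!is.null(res$coords))
      writeCoords(res$coords, file.path(outputDir, "coords.csv"))
    jsonlite::write_json(report, file.path(outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  res
}
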