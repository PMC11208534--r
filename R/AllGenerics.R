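#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package classes: \code{rateValues} returns
#' the neurons x time matrix, \code{binWidth} the sample step, \code{transformTag}
#' the provenance of the values, \code{keepMask} the speed-filter mask,
#' \code{sampleTimes} the time base, \code{nLandmarks} the point count,
#' \code{barsOf} the bar table of a barcode and \code{coordAngles} the decoded
#' angle matrix.
#'
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rateValues", function(x) standardGeneric("rateValues"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("transformTag", function(x) standardGeneric("transformTag"))
#' @rdname accessors
#' @export
setGeneric("keepMask", function(x) standardGeneric("keepMask"))
#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setGeneric("nLandmarks", function(x) standardGeneric("nLandmarks"))
#' @rdname accessors
#' @export
setGeneric("barsOf", function(x) standardGeneric("barsOf"))
#' @rdname accessors
#' @export
setGeneric("coordAngles", function(x) standardGeneric("coordAngles"))

#' @rdname accessors
setMethod("rateValues", "RateMatrix", function(x)
  SummarizedExperiment::assay(x, "rates"))
#' @rdname accessors
setMethod("binWidth", "RateMatrix", function(x) S4Vectors::metadata(x)$dt)
#' @rdname accessors
setMethod("transformTag", "RateMatrix", function(x)
  S4Vectors::metadata(x)$transform)
#' @rdname accessors
setMethod("keepMask", "RateMatrix", function(x)
  SummarizedExperiment::colData(x)$keep)
#' @rdname accessors
setMethod("sampleTimes", "RateMatrix", function(x)
  SummarizedExperiment::colData(x)$t)
#' @rdname accessors
setMethod("nLandmarks", "PointCloud", function(x) nrow(x@points))
#' @rdname accessors
setMethod("barsOf", "Barcode", function(x) x@bars)
#' @rdname accessors
setMethod("coordAngles", "ToroidalCoordinates", function(x) x@angles)

setMethod("show", "RateMatrix", function(object) {
  cat(sprintf("RateMatrix: %d neurons x %d time bins (dt = %g s, %s)\n",
              nrow(object), ncol(object),
              binWidth(object), transformTag(object)))
  k <- keepMask(object)
  cat(sprintf("  %d / %d bins pass the speed filter\n", sum(k), length(k)))
})

setMethod("show", "TrajectorySample", function(object) {
  cat(sprintf("TrajectorySample: %d samples over %.1f s, mean speed %.1f cm/s\n",
              length(object@t), diff(range(object@t)), mean(object@speed)))
})

setMethod("show", "SpikeTrainSet", function(object) {
  cat(sprintf("SpikeTrainSet: %d neurons, %d events, span [%.1f, %.1f] s\n",
              length(object@times), sum(lengths(object@times)),
              object@span[1], object@span[2]))
})

setMethod("show", "CANConfig", function(object) {
  cat(sprintf("CANConfig: %s, %d x %d units, dt = %g s, seed %d\n",
              object@model, object@nRows, object@nCols, object@dt,
              object@seed))
})

setMethod("show", "SimOutput", function(object) {
  cat(sprintf("SimOutput (%s):\n", object@config@model))
  show(object@rates)
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points in %d dimensions\n",
              nrow(object@points), ncol(object@points)))
})

setMethod("show", "Barcode", function(object) {
  b <- object@bars
  cat(sprintf("Barcode (%s metric, Z%d, threshold %.3g):\n", object@metric,
              object@modulus, object@threshold))
  for (d in sort(unique(b$dim)))
    cat(sprintf("  H%d: %d bars, longest lifetime %.3g\n", d,
                sum(b$dim == d), max(b$lifetime[b$dim == d])))
  th <- object@shuffleThresholds
  if (length(th) && any(!is.na(th)))
    cat("  shuffle thresholds:",
        paste(sprintf("H%s=%.3g", names(th), th), collapse = ", "), "\n")
})

setMethod("show", "EnsemblePartition", function(object) {
  tab <- table(object@labels[object@labels > 0])
  cat(sprintf("EnsemblePartition: %d neurons, %d ensembles (rho = %g, min %d)\n",
              length(object@labels), length(tab), object@rho, object@minSize))
  if (length(tab))
    cat("  sizes:", paste(sort(as.integer(tab), decreasing = TRUE),
                          collapse = ", "), "\n")
})

setMethod("show", "ToroidalCoordinates", function(object) {
  cat(sprintf("ToroidalCoordinates: %d time points x %d angles (%d valid)\n",
              nrow(object@angles), ncol(object@angles), sum(object@valid)))
})

setMethod("show", "TorusTransform", function(object) {
  m <- object@matrix
  cat(sprintf("TorusTransform: [[%d, %d], [%d, %d]], offsets (%.2f, %.2f) rad\n",
              m[1, 1], m[1, 2], m[2, 1], m[2, 2],
              object@offsets[1], object@offsets[2]))
})

setMethod("show", "TorusClassification", function(object) {
  cat(sprintf(
    "TorusClassification: %s (hex median %.3f, square median %.3f, n = %d)\n",
    object@label, object@hexMedian, object@sqrMedian, length(object@hexCorr)))
})

setMethod("show", "ParameterProfile", function(object) {
  cat(sprintf(
    paste0("ParameterProfile: sigma = %g/%g s, dt = %g/%g s (topology/cluster),",
           " d = %d,\n  eps = %g, kappa = %d, m = %d, rho = %g, tauMax = %g s,",
           " speedMin = %g cm/s\n"),
    object@sigmaSmooth, object@sigmaCluster, object@dtTopology,
    object@dtCluster, object@d, object@eps, object@kappa, object@m,
    object@rhoCluster, object@tauMax, object@speedMin))
})
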