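#' @include AllClasses.R
NULL

#' Gaussian-kernel firing rates from spike trains
#'
#' Each spike is replaced by a unit-area Gaussian of width \code{sigma} and the
#' kernels are summed into a continuous rate (events/s), sampled every
#' \code{dt}. Kernels are truncated at five sigma (mass lost below 1e-6). An
#' empty spike train yields an all-zero row.
#'
#' @param spikes a \linkS4class{SpikeTrainSet}.
#' @param sigma kernel width (s).
#' @param dt sample step (s).
#' @return A \linkS4class{RateMatrix} tagged \code{"raw"}.
#' @export
ratesFromSpikes <- function(spikes, sigma, dt) {
  stopifnot(is(spikes, "SpikeTrainSet"))
  if (sigma <= 0 || dt <= 0) stop("sigma and dt must be positive")
  tt <- seq(spikes@span[1], spikes@span[2], by = dt)
  n <- length(tt)
  half <- 5 * sigma
  out <- matrix(0, length(spikes@times), n,
                dimnames = list(spikes@ids, NULL))
  for (i in seq_along(spikes@times)) {
    row <- numeric(n)
    for (s in spikes@times[[i]]) {
      lo <- max(1L, ceiling((s - half - tt[1]) / dt) + 1L)
      hi <- min(n, floor((s + half - tt[1]) / dt) + 1L)
      if (lo <= hi) {
        idx <- lo:hi
        row[idx] <- row[idx] + dnorm(tt[idx], mean = s, sd = sigma)
      }
    }
    out[i, ] <- row
  }
  RateMatrix(out, dt = dt, transform = "raw", t = tt)
}

#' Square-root transform of firing rates
#'
#' @param r a \linkS4class{RateMatrix} with raw values.
#' @return A \linkS4class{RateMatrix} tagged \code{"sqrt"}.
#' @export
sqrtTransform <- function(r) {
  stopifnot(is(r, "RateMatrix"))
  if (transformTag(r) != "raw")
    stop("sqrtTransform expects raw rates")
  v <- rateValues(r)
  if (any(v < 0)) stop("negative rates cannot be square-rooted")
  out <- r
  SummarizedExperiment::assay(out, "rates") <- sqrt(v)
  S4Vectors::metadata(out)$transform <- "sqrt"
  out
}

#' Speed-filter a rate matrix
#'
#' Marks time bins whose running speed falls below \code{vMin} as excluded in
#' the \code{keep} mask (columns are retained so time bases stay aligned).
#' Optionally also excludes population vectors with no activity, as
#' appropriate for event data.
#'
#' @param r a \linkS4class{RateMatrix}.
#' @param traj a \linkS4class{TrajectorySample} on the same time base, or NULL
#'   to use the speed stored in \code{r}.
#' @param vMin minimum speed (cm/s).
#' @param dropSilent also exclude all-zero population vectors.
#' @return The \linkS4class{RateMatrix} with an updated mask.
#' @export
speedFilter <- function(r, traj = NULL, vMin = 5, dropSilent = FALSE) {
  stopifnot(is(r, "RateMatrix"))
  if (is.null(traj)) {
    sp <- SummarizedExperiment::colData(r)$speed
    if (is.null(sp)) stop("no trajectory given and no speed stored")
  } else {
    if (length(traj@t) != ncol(r))
      stop(sprintf("trajectory has %d samples but rates have %d time bins",
                   length(traj@t), ncol(r)))
    sp <- traj@speed
  }
  keep <- sp >= vMin
  if (dropSilent) keep <- keep & colSums(rateValues(r)) > 0
  if (!any(keep))
    warning("speed filter removed every time bin")
  out <- r
  SummarizedExperiment::colData(out)$keep <- keep
  SummarizedExperiment::colData(out)$speed <- sp
  out
}

#' PCA-whitened population point cloud
#'
#' Population vectors (masked bins excluded) are z-scored per neuron, projected
#' onto the first \code{d} principal components and divided by the square roots
#' of the eigenvalues, so the retained components have identity empirical
#' covariance. Zero-variance neurons are dropped with a warning before
#' z-scoring.
#'
#' @param r a \linkS4class{RateMatrix}.
#' @param d number of components (at most the number of neurons).
#' @return A \linkS4class{PointCloud} of the kept time bins (rows) in d
#'   whitened dimensions; row indices refer to columns of \code{r}.
#' @export
pcaWhiten <- function(r, d) {
  stopifnot(is(r, "RateMatrix"))
  keep <- keepMask(r)
  v <- rateValues(r)[, keep, drop = FALSE]
  idx <- which(keep)
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance neurons before whitening",
                    sum(sds == 0)))
    v <- v[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (d > nrow(v)) stop("d must not exceed the number of (usable) neurons")
  z <- t((v - rowMeans(v)) / sds)          # time x neurons
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  T_ <- nrow(z)
  # prcomp sdev is sqrt of eigenvalue of cov (divisor T-1)
  white <- pc$x[, seq_len(d), drop = FALSE] /
    rep(pc$sdev[seq_len(d)], each = T_)
  colnames(white) <- paste0("PC", seq_len(d))
  PointCloud(white, index = idx)
}
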