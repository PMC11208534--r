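#' @include AllClasses.R preprocess.R downsample.R
NULL

#' Pairwise cosine distances
#'
#' @param P numeric matrix, rows are points.
#' @return Symmetric matrix of \code{1 - cos} similarities, values in [0, 2].
#' @export
cosineDistance <- function(P) {
  nrm <- sqrt(rowSums(P^2))
  if (any(nrm == 0)) stop("cosine distance undefined for zero vectors")
  G <- tcrossprod(P / nrm)
  G[G > 1] <- 1
  G[G < -1] <- -1
  D <- 1 - G
  diag(D) <- 0
  D
}

#' Vietoris-Rips persistent cohomology of a point cloud
#'
#' Computes the barcode of the Rips filtration on the chosen metric with
#' coefficients in the prime field Z_modulus (47 by default, unlikely to
#' divide any torsion), retaining representative 1-cocycles for circular
#' coordinatization. By default the filtration is truncated at the enclosing
#' radius, at which the complex becomes a cone, so every finite feature is
#' captured.
#'
#' @param X a \linkS4class{PointCloud}, or a precomputed distance matrix.
#' @param maxdim largest homological dimension (2 by default; higher is
#'   supported but costly).
#' @param metric \code{"cosine"} or \code{"euclidean"} (ignored when \code{X}
#'   is a distance matrix).
#' @param modulus prime coefficient field.
#' @param threshold filtration truncation; \code{NULL} uses the enclosing
#'   radius.
#' @return A \linkS4class{Barcode}. Bars are sorted within dimension by
#'   decreasing lifetime; infinite deaths are allowed.
#' @export
computePersistence <- function(X, maxdim = 2, metric = c("cosine", "euclidean"),
                               modulus = 47L, threshold = NULL) {
  metric <- match.arg(metric)
  if (is(X, "PointCloud")) {
    D <- if (metric == "cosine") cosineDistance(X@points)
         else as.matrix(dist(X@points))
  } else {
    D <- as.matrix(X)
    if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  }
  if (any(!is.finite(D))) stop("non-finite distances")
  if (maxdim < 0) stop("maxdim must be nonnegative")
  res <- .rips_cohomology(D, maxdim = as.integer(maxdim),
                          threshold = if (is.null(threshold)) -1 else threshold,
                          modulus = as.integer(modulus), do_cocycles = TRUE)
  bars <- data.frame(dim = as.integer(res$dim), birth = res$birth,
                     death = res$death)
  bars$lifetime <- bars$death - bars$birth
  cyc <- res$cocycles
  names(cyc) <- as.character(res$cocycle_bar + 1L)  # bar row (1-based)
  # sort within dimension by decreasing lifetime, keeping cocycle links
  ord <- order(bars$dim, -bars$lifetime)
  remap <- match(seq_len(nrow(bars)), ord)
  bars <- bars[ord, , drop = FALSE]
  rownames(bars) <- NULL
  if (length(cyc)) names(cyc) <- as.character(remap[as.integer(names(cyc))])
  new("Barcode", bars = bars, cocycles = cyc, metric = metric,
      modulus = as.integer(modulus), threshold = res$threshold,
      shuffleThresholds = c("0" = NA_real_, "1" = NA_real_, "2" = NA_real_))
}

# Whiten -> radial -> fuzzy -> persistence; the shared tail of the pipeline.
.topologyFromRates <- function(r, profile, maxdim = 2, modulus = 47L,
                               seedCloud = FALSE) {
  cloud <- pcaWhiten(r, profile@d)
  rad <- radialDownsample(cloud, profile@eps)
  kappa <- min(profile@kappa, nrow(rad@points) - 1L)
  m <- min(profile@m, nrow(rad@points))
  land <- fuzzyDownsample(rad, kappa, m)
  bc <- computePersistence(land, maxdim = maxdim, metric = "cosine",
                           modulus = modulus)
  list(cloud = cloud, landmarks = land, barcode = bc)
}

#' Shuffle null distribution for barcode significance
#'
#' Circularly rolls each neuron's rate series by an independent uniform offset
#' (the speed-filter mask stays fixed), reruns the topology tail of the
#' pipeline (whitening, two-step downsampling, persistence) and records the
#' maximum finite lifetime per dimension. The significance threshold is the
#' 99th percentile of these maxima. The infinite 0-dimensional bar is excluded
#' throughout.
#'
#' @param r the (transformed, speed-filtered) \linkS4class{RateMatrix} the
#'   observed barcode was computed from.
#' @param profile a \linkS4class{ParameterProfile}.
#' @param nShuffles number of shuffles (the reference analysis uses 100).
#' @param seed RNG seed.
#' @param maxdim largest dimension to threshold.
#' @param modulus coefficient field prime.
#' @return Named numeric vector of thresholds, one per dimension 0..maxdim.
#' @export
shuffleNull <- function(r, profile, nShuffles = 100, seed = 1L, maxdim = 2,
                        modulus = 47L) {
  stopifnot(is(r, "RateMatrix"), is(profile, "ParameterProfile"))
  if (nShuffles < 1) stop("nShuffles must be at least 1")
  set.seed(seed)
  v <- rateValues(r)
  T_ <- ncol(v)
  maxima <- matrix(0, nShuffles, maxdim + 1)
  for (s in seq_len(nShuffles)) {
    offs <- sample.int(T_, nrow(v), replace = TRUE) - 1L
    rolled <- v
    for (i in seq_len(nrow(v)))
      if (offs[i] > 0)
        rolled[i, ] <- c(v[i, (T_ - offs[i] + 1):T_], v[i, 1:(T_ - offs[i])])
    rr <- r
    SummarizedExperiment::assay(rr, "rates") <- rolled
    bc <- suppressWarnings(
      .topologyFromRates(rr, profile, maxdim = maxdim, modulus = modulus))$barcode
    b <- bc@bars
    for (d in 0:maxdim) {
      lt <- b$lifetime[b$dim == d & is.finite(b$death)]
      maxima[s, d + 1] <- if (length(lt)) max(lt) else 0
    }
  }
  th <- apply(maxima, 2, quantile, probs = 0.99, names = FALSE)
  names(th) <- as.character(0:maxdim)
  th
}

#' Attach shuffle thresholds to a barcode
#'
#' @param b a \linkS4class{Barcode}.
#' @param thresholds named per-dimension thresholds from
#'   \code{\link{shuffleNull}}.
#' @return The barcode with thresholds set.
#' @export
setShuffleThresholds <- function(b, thresholds) {
  stopifnot(is(b, "Barcode"))
  b@shuffleThresholds <- thresholds
  validObject(b)
  b
}

#' Count bars exceeding the shuffle threshold
#'
#' A finite bar is significant when its lifetime exceeds the dimension's
#' shuffle threshold; infinite bars (e.g. the essential connected component)
#' are always significant.
#'
#' @param b a \linkS4class{Barcode} with thresholds attached.
#' @param dim homological dimension.
#' @return Integer count.
#' @export
countSignificantBars <- function(b, dim) {
  stopifnot(is(b, "Barcode"))
  th <- b@shuffleThresholds[as.character(dim)]
  if (is.null(th) || is.na(th))
    stop(sprintf("no shuffle threshold for dimension %d", dim))
  bars <- b@bars[b@bars$dim == dim, , drop = FALSE]
  sum(!is.finite(bars$death) | bars$lifetime > th)
}

#' Rows of the n longest finite bars in a dimension
#'
#' @param b a \linkS4class{Barcode}.
#' @param dim homological dimension.
#' @param n number of bars.
#' @return Integer row indices into \code{barsOf(b)}, by decreasing lifetime.
#' @export
longestBars <- function(b, dim, n = 2) {
  rows <- which(b@bars$dim == dim & is.finite(b@bars$death))
  rows[order(b@bars$lifetime[rows], decreasing = TRUE)][seq_len(min(n, length(rows)))]
}

#' Plot a barcode
#'
#' Horizontal persistence bars grouped by dimension; bars whose lifetime
#' exceeds the attached shuffle threshold are emphasized, and infinite bars
#' are drawn to the panel edge with a cross.
#'
#' @param b a \linkS4class{Barcode}.
#' @param minLifetime hide bars shorter than this (declutters H0).
#' @return Invisibly, the bar table that was drawn.
#' @export
plotBarcode <- function(b, minLifetime = 0) {
  stopifnot(is(b, "Barcode"))
  bars <- b@bars[b@bars$lifetime >= minLifetime | !is.finite(b@bars$death), ]
  dims <- sort(unique(bars$dim))
  xmax <- max(b@threshold, bars$death[is.finite(bars$death)])
  oldpar <- graphics::par(mfrow = c(length(dims), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(oldpar))
  for (d in dims) {
    bd <- bars[bars$dim == d, ]
    bd <- bd[order(bd$birth), ]
    n <- nrow(bd)
    graphics::plot(NULL, xlim = c(0, xmax * 1.05), ylim = c(0, n + 1),
                   xlab = "", ylab = sprintf("H%d", d), yaxt = "n")
    th <- b@shuffleThresholds[as.character(d)]
    for (k in seq_len(n)) {
      dead <- is.finite(bd$death[k])
      x1 <- if (dead) bd$death[k] else xmax * 1.05
      sig <- !dead || (!is.null(th) && !is.na(th) && bd$lifetime[k] > th)
      graphics::segments(bd$birth[k], k, x1, k, lwd = if (sig) 2.5 else 1,
                         col = if (sig) "firebrick" else "grey40")
      if (!dead) graphics::points(x1, k, pch = 4)
    }
    if (!is.null(th) && !is.na(th))
      graphics::mtext(sprintf("shuffle threshold %.3g", th), side = 3,
                      adj = 1, cex = 0.7)
  }
  invisible(bars)
}
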