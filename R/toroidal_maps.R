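#' @include AllClasses.R
NULL

#' Binned 2-D rate map
#'
#' @slot values mean activity per bin after unvisited-bin fill and smoothing.
#' @slot occupancy sample count per bin.
#' @slot sigmaBins smoothing width (bins).
#' @slot binSize bin edge length (cm for spatial maps, degrees for toroidal).
#' @export
setClass("RateMap2D",
         representation(values = "matrix", occupancy = "matrix",
                        sigmaBins = "numeric", binSize = "numeric"))

#' 1-D spatial autocorrelogram
#'
#' @slot values dot products per shift 0..maxShift.
#' @slot binCm spatial bin (cm).
#' @export
setClass("Autocorr1D",
         representation(values = "numeric", binCm = "numeric"))

# truncated 2-D Gaussian smoothing; optionally with periodic wrap
.gaussSmooth2 <- function(m, sigma, wrap = FALSE) {
  if (sigma <= 0) return(m)
  half <- ceiling(3 * sigma)
  g <- dnorm(-half:half, sd = sigma)
  K <- outer(g, g)
  K <- K / sum(K)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0; wsum <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- i + di; jj <- j + dj
      if (wrap) {
        ii <- ((ii - 1) %% nr) + 1
        jj <- ((jj - 1) %% nc) + 1
      } else if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      w <- K[di + half + 1, dj + half + 1]
      acc <- acc + w * m[ii, jj]
      wsum <- wsum + w
    }
    out[i, j] <- acc / wsum
  }
  out
}

.bin2d <- function(x, y, nBins, rangeX, rangeY) {
  bx <- pmin(pmax(floor((x - rangeX[1]) / diff(rangeX) * nBins) + 1L, 1L), nBins)
  by <- pmin(pmax(floor((y - rangeY[1]) / diff(rangeY) * nBins) + 1L, 1L), nBins)
  list(bx = bx, by = by)
}

.meanPerBin <- function(activity, bx, by, nBins) {
  sums <- matrix(0, nBins, nBins)
  cnt <- matrix(0, nBins, nBins)
  for (k in seq_along(activity)) {
    sums[bx[k], by[k]] <- sums[bx[k], by[k]] + activity[k]
    cnt[bx[k], by[k]] <- cnt[bx[k], by[k]] + 1
  }
  vals <- sums
  vals[cnt > 0] <- sums[cnt > 0] / cnt[cnt > 0]
  list(values = vals, occupancy = cnt)
}

#' Spatial rate map
#'
#' Mean activity in a square grid of bins over the arena; unvisited bins are
#' assigned the mean of the visited bins before Gaussian smoothing.
#'
#' @param activity per-sample activity.
#' @param positions two-column matrix (x, y) in cm, aligned with activity.
#' @param bins grid resolution per axis.
#' @param sigmaBins smoothing width (bins).
#' @param range optional list(x =, y =) of axis ranges; defaults to the data.
#' @return A \linkS4class{RateMap2D}.
#' @export
spatialRatemap <- function(activity, positions, bins = 30, sigmaBins = 2,
                           range = NULL) {
  positions <- as.matrix(positions)
  if (!length(activity)) stop("no visited bins")
  if (length(activity) != nrow(positions)) stop("misaligned series")
  rx <- if (is.null(range)) base::range(positions[, 1]) else range$x
  ry <- if (is.null(range)) base::range(positions[, 2]) else range$y
  if (diff(rx) == 0) rx <- rx + c(-0.5, 0.5)
  if (diff(ry) == 0) ry <- ry + c(-0.5, 0.5)
  b <- .bin2d(positions[, 1], positions[, 2], bins, rx, ry)
  mp <- .meanPerBin(activity, b$bx, b$by, bins)
  if (!any(mp$occupancy > 0)) stop("no visited bins")
  fill <- mean(mp$values[mp$occupancy > 0])
  v <- mp$values
  v[mp$occupancy == 0] <- fill
  v <- .gaussSmooth2(v, sigmaBins)
  new("RateMap2D", values = v, occupancy = mp$occupancy,
      sigmaBins = sigmaBins, binSize = diff(rx) / bins)
}

#' 1-D spatial autocorrelogram
#'
#' Mean activity per spatial bin along the linearized position, dotted with a
#' zero-padded copy of itself at shifts 0..\code{maxShift} bins.
#'
#' @param activity per-sample activity.
#' @param linearPos linearized position (cm), aligned with activity.
#' @param binCm spatial bin (cm); 1 for wheel, 4 for a VR track.
#' @param maxShift largest shift (bins).
#' @return An \linkS4class{Autocorr1D}; the zero-shift value is maximal for
#'   nonnegative activity.
#' @export
autocorr1d <- function(activity, linearPos, binCm, maxShift = 300) {
  if (length(activity) != length(linearPos)) stop("misaligned series")
  nb <- floor((max(linearPos) - min(linearPos)) / binCm) + 1L
  if (nb < 1) stop("track shorter than one bin")
  bin <- pmin(floor((linearPos - min(linearPos)) / binCm) + 1L, nb)
  sums <- tapply(activity, factor(bin, levels = seq_len(nb)), sum)
  cnt <- tabulate(bin, nbins = nb)
  v <- ifelse(cnt > 0, as.numeric(sums) / pmax(cnt, 1), 0)
  v[is.na(v)] <- 0
  padded <- c(v, rep(0, maxShift))
  vals <- vapply(0:maxShift, function(s)
    sum(v * padded[(1 + s):(nb + s)]), numeric(1))
  new("Autocorr1D", values = vals, binCm = binCm)
}

# occupancy-weighted mean activity on an nBins^2 toroidal grid (no smoothing)
.toroidalBinMap <- function(activity, angles, nBins) {
  b1 <- pmin(floor(angles[, 1] / (2 * pi) * nBins) + 1L, nBins)
  b2 <- pmin(floor(angles[, 2] / (2 * pi) * nBins) + 1L, nBins)
  mp <- .meanPerBin(activity, b1, b2, nBins)
  mp
}

# fractional circular row shift by linear interpolation
.rollRow <- function(v, shift) {
  n <- length(v)
  s0 <- floor(shift)
  frac <- shift - s0
  roll <- function(x, k) x[((seq_len(n) - 1 - k) %% n) + 1]
  (1 - frac) * roll(v, s0 %% n) + frac * roll(v, (s0 + 1) %% n)
}

#' Toroidal rate map with hexagonal-shear smoothing
#'
#' Mean activity in 12-degree toroidal bins. To smooth across the 60-degree
#' axis geometry, each row is first shifted horizontally by half its vertical
#' position, the sheared map is tiled three by three (periodic boundaries),
#' smoothed with a Gaussian of width \code{sigmaBins}, and the middle tile is
#' extracted and unsheared. Unvisited bins receive the mean of visited bins
#' before smoothing.
#'
#' @param activity per-sample activity.
#' @param coords a \linkS4class{ToroidalCoordinates} (first two dimensions
#'   used) or a two-column angle matrix.
#' @param binDeg bin size in degrees.
#' @param sigmaBins smoothing width (bins).
#' @return A \linkS4class{RateMap2D} (rows index the first angle).
#' @export
toroidalRatemap <- function(activity, coords, binDeg = 12, sigmaBins = 2) {
  if (is(coords, "ToroidalCoordinates")) {
    keep <- coords@valid
    ang <- coords@angles[keep, 1:2, drop = FALSE]
    activity <- activity[keep]
  } else ang <- as.matrix(coords)[, 1:2, drop = FALSE]
  if (!nrow(ang)) stop("no valid coordinates")
  nBins <- round(360 / binDeg)
  mp <- .toroidalBinMap(activity, ang, nBins)
  v <- mp$values
  if (!any(mp$occupancy > 0)) stop("no occupied bins")
  v[mp$occupancy == 0] <- mean(v[mp$occupancy > 0])
  # shear: shift row r horizontally (along the second angle) by r/2 bins
  sheared <- v
  for (r in seq_len(nBins))
    sheared[r, ] <- .rollRow(v[r, ], -(r - 1) / 2)
  # vertical neighbors of the sheared map carry a half-period horizontal
  # offset (the hexagonal identification), so the 3 x 3 tiling rolls the
  # upper and lower blocks by +-nBins/2 columns
  rollBlock <- function(S, k) t(apply(S, 1, .rollRow, shift = k))
  vert <- rbind(rollBlock(sheared, nBins / 2), sheared,
                rollBlock(sheared, -nBins / 2))
  big <- vert[, rep(seq_len(nBins), 3)]
  big <- .gaussSmooth2(big, sigmaBins)
  mid <- big[nBins + seq_len(nBins), nBins + seq_len(nBins)]
  out <- mid
  for (r in seq_len(nBins))
    out[r, ] <- .rollRow(mid[r, ], (r - 1) / 2)
  new("RateMap2D", values = out, occupancy = mp$occupancy,
      sigmaBins = sigmaBins, binSize = binDeg)
}

#' Peak toroidal phase of a neuron
#'
#' Circular mass center of the activity distribution on the torus (16^2 bins
#' by default): per axis,
#' \eqn{T_{peak} = \mathrm{arctan2}(\sum_i \sin\phi_i s_i / \sum_i s_i,
#' \sum_i \cos\phi_i s_i / \sum_i s_i)}.
#'
#' @param map a \linkS4class{RateMap2D} or a plain bin matrix (rows index the
#'   first angle) of nonnegative activity.
#' @return Numeric (theta1, theta2) in [0, 2*pi) with attribute
#'   \code{degenerate}: TRUE per axis when the resultant vanishes (e.g.
#'   antipodally balanced activity).
#' @export
toroidalPeak <- function(map) {
  m <- if (is(map, "RateMap2D")) map@values else as.matrix(map)
  if (any(m < 0)) stop("activity must be nonnegative")
  tot <- sum(m)
  if (tot == 0) stop("activity must not be all zero")
  nb <- nrow(m)
  phi <- (seq_len(nb) - 0.5) / nb * 2 * pi
  w1 <- rowSums(m) / tot
  w2 <- colSums(m) / tot
  res <- function(w) {
    s <- sum(sin(phi) * w); c_ <- sum(cos(phi) * w)
    list(theta = atan2(s, c_) %% (2 * pi), r = sqrt(s^2 + c_^2))
  }
  r1 <- res(w1); r2 <- res(w2)
  structure(c(r1$theta, r2$theta),
            degenerate = c(r1$r < 1e-9, r2$r < 1e-9))
}

#' Angular (head-direction) tuning curve
#'
#' @param activity per-sample activity.
#' @param hd angles (radians), aligned with activity.
#' @param bins number of angular bins.
#' @return Max-normalized mean activity per bin (empty bins 0).
#' @export
angularTuning <- function(activity, hd, bins = 60) {
  if (!length(activity)) stop("empty input")
  b <- pmin(floor((hd %% (2 * pi)) / (2 * pi) * bins) + 1L, bins)
  sums <- tapply(activity, factor(b, levels = seq_len(bins)), sum)
  cnt <- tabulate(b, nbins = bins)
  v <- ifelse(cnt > 0, as.numeric(sums) / pmax(cnt, 1), 0)
  v[is.na(v)] <- 0
  if (max(v) > 0) v <- v / max(v)
  v
}

#' Sparse 3-D toroidal tuning
#'
#' Radial downsampling of the 3-angle coordinates yields spherical bin
#' centers; each center is valued by the mean activity of the samples nearest
#' to it.
#'
#' @param activity per-sample activity.
#' @param coords3 three-column angle matrix.
#' @param eps radial downsampling radius.
#' @return data.frame with the center coordinates and mean value per center.
#' @export
toroidal3dTuning <- function(activity, coords3, eps = 0.5) {
  coords3 <- as.matrix(coords3)
  if (!nrow(coords3)) stop("empty coordinates")
  centers <- radialDownsample(PointCloud(coords3), eps)
  ctr <- centers@points
  # nearest-center assignment
  assign <- apply(coords3, 1, function(p)
    which.min(colSums((t(ctr) - p)^2)))
  val <- vapply(seq_len(nrow(ctr)), function(k) {
    sel <- assign == k
    if (any(sel)) mean(activity[sel]) else NA_real_
  }, numeric(1))
  data.frame(theta1 = ctr[, 1], theta2 = ctr[, 2], theta3 = ctr[, 3],
             value = val)
}
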