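#' @include AllClasses.R topology.R
NULL

# connected components by BFS on an adjacency list
.components <- function(n, edges) {
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    head_ <- 1L
    comp[s] <- cur
    while (head_ <= length(queue)) {
      v <- queue[head_]
      head_ <- head_ + 1L
      nb <- adj[[as.character(v)]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      if (length(new)) queue <- c(queue, new)
    }
  }
  comp
}

# Gaussian smoothing of a circular signal via its unit-vector embedding
.smoothAngles <- function(theta, sigmaBins) {
  if (sigmaBins <= 0) return(theta)
  half <- ceiling(4 * sigmaBins)
  k <- dnorm(-half:half, sd = sigmaBins)
  k <- k / sum(k)
  pad <- function(v) c(rep(v[1], half), v, rep(v[length(v)], half))
  sm <- function(v) as.numeric(stats::filter(pad(v), k, sides = 2))[
    (half + 1):(half + length(v))]
  atan2(sm(sin(theta)), sm(cos(theta))) %% (2 * pi)
}

#' Circle-valued coordinates from persistent 1-cocycles
#'
#' For each selected H1 bar, the stored Z_p representative cocycle is lifted to
#' integers (coefficients mapped to the balanced range), harmonically smoothed
#' by unweighted least squares over the 1-skeleton of the Rips complex at
#' \eqn{\tau = b + 0.99 (d - b)}, and integrated into an angle per landmark.
#' The resulting map winds once around the circular feature the bar describes;
#' orientation and origin are gauge freedoms.
#'
#' @param b a \linkS4class{Barcode} with cocycles (dimension 1).
#' @param barIds rows of \code{barsOf(b)} to coordinatize (H1 bars).
#' @param X the \linkS4class{PointCloud} the barcode was computed from.
#' @param tau optional filtration scale; defaults to birth + 0.99 * (death -
#'   birth) per bar. Must lie in [birth, death).
#' @return List of \linkS4class{CircularCoordinate}, one per bar.
#' @export
circularCoords <- function(b, barIds, X, tau = NULL) {
  stopifnot(is(b, "Barcode"), is(X, "PointCloud"))
  D <- if (b@metric == "cosine") cosineDistance(X@points)
       else as.matrix(dist(X@points))
  n <- nrow(D)
  p <- b@modulus
  half_p <- (p - 1) / 2
  out <- vector("list", length(barIds))
  for (q in seq_along(barIds)) {
    row <- barIds[q]
    bar <- b@bars[row, ]
    if (bar$dim != 1) stop("circular coordinates require H1 bars")
    cyc <- b@cocycles[[as.character(row)]]
    if (is.null(cyc)) stop(sprintf("no stored cocycle for bar %d", row))
    tq <- if (is.null(tau)) bar$birth + 0.99 * (bar$death - bar$birth)
          else tau
    if (tq < bar$birth || tq >= bar$death)
      stop("tau must lie within [birth, death) of the bar")
    # 1-skeleton at scale tau
    eidx <- which(D <= tq & upper.tri(D), arr.ind = TRUE)  # col > row
    edges <- cbind(eidx[, "row"], eidx[, "col"])           # a < b
    # integer lift of the cocycle on ascending-ordered edges
    alpha <- numeric(nrow(edges))
    key <- edges[, 1] * (n + 1) + edges[, 2]
    ci <- cyc[, 2] + 1L  # smaller vertex (0-based in C++)
    cj <- cyc[, 1] + 1L  # larger vertex
    lift <- ifelse(cyc[, 3] > half_p, cyc[, 3] - p, cyc[, 3])
    # restrict the cocycle to edges present at tau: edges above tau belong to
    # no triangle of the complex at tau, so the restriction is still a cocycle
    ckey <- ci * (n + 1) + cj
    hit <- match(ckey, key)
    alpha[hit[!is.na(hit)]] <- lift[!is.na(hit)]
    # least squares delta0 f = alpha via the graph Laplacian
    L <- matrix(0, n, n)
    L[edges] <- -1
    L[edges[, 2:1, drop = FALSE]] <- -1
    diag(L) <- tabulate(edges, nbins = n)
    rhs <- numeric(n)
    agg <- rowsum(c(-alpha, alpha), group = c(edges[, 1], edges[, 2]))
    rhs[as.integer(rownames(agg))] <- agg[, 1]
    comp <- .components(n, edges)
    pin <- match(unique(comp), comp)  # one vertex per component
    free <- setdiff(seq_len(n), pin)
    f <- numeric(n)
    if (length(free))
      f[free] <- solve(L[free, free, drop = FALSE], rhs[free])
    theta <- ((-f) %% 1) * 2 * pi
    out[[q]] <- new("CircularCoordinate", angle = theta,
                    barId = as.integer(row), tau = tq)
  }
  out
}

# circular activity distribution per neuron over angle bins
.neuronDistributions <- function(angles, landmarkRates, nBins, smoothBins = 1) {
  bin <- pmin(floor(angles / (2 * pi) * nBins) + 1L, nBins)
  agg <- matrix(0, nrow(landmarkRates), nBins)
  for (k in seq_len(nBins)) {
    sel <- bin == k
    if (any(sel))
      agg[, k] <- rowSums(landmarkRates[, sel, drop = FALSE])
  }
  if (smoothBins > 0) {
    half <- nBins %/% 2
    kern <- dnorm(seq(-half, half), sd = smoothBins)
    kern <- kern / sum(kern)
    for (i in seq_len(nrow(agg))) {
      v <- agg[i, ]
      sm <- numeric(nBins)
      for (s in seq_along(kern)) {
        shift <- s - half - 1
        sm <- sm + kern[s] * v[((seq_len(nBins) - 1 + shift) %% nBins) + 1]
      }
      agg[i, ] <- sm
    }
  }
  agg
}

#' Extrapolate landmark coordinates to all time points
#'
#' Per neuron and torus dimension, landmark angles weighted by the neuron's
#' activity at each landmark give a circular activity distribution (16-bin
#' histogram with one-bin Gaussian circular smoothing). At each target time
#' point the neuron distributions are summed weighted by instantaneous
#' activity, and the decoded coordinate is the circular mass center of the
#' summed distribution. Because the distributions are per neuron, the same
#' torus can decode a held-out session of the same cells.
#'
#' @param cc list of \linkS4class{CircularCoordinate} from
#'   \code{\link{circularCoords}}.
#' @param landmarkRates neurons x landmarks activity (columns ordered as the
#'   landmark cloud).
#' @param targetRates neurons x time activity to decode (a matrix or a
#'   \linkS4class{RateMatrix}).
#' @param nBins histogram resolution.
#' @return A \linkS4class{ToroidalCoordinates}; time points with zero total
#'   weight are masked invalid.
#' @export
extrapolateCoords <- function(cc, landmarkRates, targetRates, nBins = 16L) {
  landmarkRates <- as.matrix(landmarkRates)
  if (is(targetRates, "RateMatrix")) {
    tvec <- sampleTimes(targetRates)
    tr <- rateValues(targetRates)
  } else {
    tr <- as.matrix(targetRates)
    tvec <- seq_len(ncol(tr))
  }
  if (nrow(tr) != nrow(landmarkRates))
    stop("landmark and target activity must share the neuron set")
  ndim <- length(cc)
  T_ <- ncol(tr)
  angles <- matrix(0, T_, ndim)
  valid <- rep(TRUE, T_)
  dists <- vector("list", ndim)
  centers <- (seq_len(nBins) - 0.5) / nBins * 2 * pi
  for (q in seq_len(ndim)) {
    dist_q <- .neuronDistributions(cc[[q]]@angle, landmarkRates, nBins)
    dists[[q]] <- dist_q
    w <- crossprod(dist_q, tr)          # bins x time
    sw <- colSums(w)
    s <- as.numeric(crossprod(w, sin(centers)))
    c_ <- as.numeric(crossprod(w, cos(centers)))
    ok <- sw > 0 & (s^2 + c_^2) > 0
    angles[ok, q] <- atan2(s[ok], c_[ok]) %% (2 * pi)
    valid <- valid & ok
  }
  new("ToroidalCoordinates", angles = angles, t = as.numeric(tvec),
      valid = valid, distributions = dists, nBins = as.integer(nBins))
}

#' Align angles to a reference by flip and offset
#'
#' Tests clockwise and anti-clockwise orientation and fixes the origin by the
#' circular mean difference to the reference, returning the candidate with the
#' smaller mean angular distance.
#'
#' @param theta angles to align (radians).
#' @param ref reference angles, same length.
#' @return Aligned angles in [0, 2*pi), with attributes \code{flip} (+1 or
#'   -1), \code{offset} and \code{error} (mean angular distance, radians).
#' @export
alignToReferenceAngle <- function(theta, ref) {
  if (length(theta) != length(ref)) stop("lengths differ")
  best <- NULL
  for (s in c(1, -1)) {
    d <- ref - s * theta
    off <- atan2(mean(sin(d)), mean(cos(d)))
    cand <- (s * theta + off) %% (2 * pi)
    err <- mean(abs(((cand - ref + pi) %% (2 * pi)) - pi))
    if (is.null(best) || err < best$error)
      best <- list(angles = cand, flip = s, offset = off, error = err)
  }
  structure(best$angles, flip = best$flip, offset = best$offset,
            error = best$error)
}

#' Circular correlation of two angle vectors
#'
#' Association measure suited to angles with uniform marginals (decoded torus
#' coordinates cover the circle): the larger resultant length of the pointwise
#' difference and sum,
#' \eqn{\max(R(a - b), R(a + b))} with \eqn{R(x) = |\mathrm{mean}(e^{ix})|}.
#' Equals 1 when \code{b} is a rotation or reflection of \code{a} and
#' approaches 0 for independent angles. (Moment-based coefficients such as
#' Fisher-Lee degenerate in the uniform-marginal case, where the mean
#' direction is arbitrary.)
#'
#' @param a,b angle vectors (radians).
#' @return Association in [0, 1].
#' @export
circularCor <- function(a, b) {
  R <- function(x) sqrt(mean(sin(x))^2 + mean(cos(x))^2)
  max(R(a - b), R(a + b))
}
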