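#' @include AllClasses.R coordinatize.R
NULL

# all 2x2 integer matrices with entries in {-1, 0, 1} and |det| = 1: the
# lattice changes-of-basis consistent with hexagonal axes 60/120 degrees
# apart, in either sign convention, together with orientation flips
.torusSymmetries <- function() {
  out <- list()
  vals <- c(-1L, 0L, 1L)
  for (a in vals) for (b in vals) for (c_ in vals) for (d in vals) {
    if (abs(a * d - b * c_) == 1L)
      out[[length(out) + 1L]] <- matrix(c(a, c_, b, d), 2, 2)
  }
  out
}

#' Apply a torus transform to coordinates
#'
#' @param transform a \linkS4class{TorusTransform}.
#' @param coords a \linkS4class{ToroidalCoordinates} or a two-column angle
#'   matrix.
#' @return Object of the input type with angles \code{(M theta + offset) mod
#'   2 pi}.
#' @export
applyTorusTransform <- function(transform, coords) {
  stopifnot(is(transform, "TorusTransform"))
  ang <- if (is(coords, "ToroidalCoordinates"))
    coords@angles[, 1:2, drop = FALSE] else as.matrix(coords)
  new_ang <- (ang %*% t(transform@matrix) +
                rep(transform@offsets, each = nrow(ang))) %% (2 * pi)
  if (is(coords, "ToroidalCoordinates")) {
    out <- coords
    out@angles <- new_ang
    out
  } else new_ang
}

#' Align two decoded tori
#'
#' Decoded toroidal coordinates are defined only up to orientation, axis
#' choice (the hexagonal torus has three axes 60 or 120 degrees apart) and
#' origin. All enumerated combinations of unimodular axis substitutions and
#' flips are tested; for each, the candidate coordinates are smoothed with a
#' 200 ms Gaussian, per-axis offsets are fitted by the circular mean
#' difference, and the transform minimizing the mean angular difference to
#' \code{coordsA} is returned.
#'
#' @param coordsA reference \linkS4class{ToroidalCoordinates}.
#' @param coordsB coordinates to align (same time base).
#' @param smoothSec temporal smoothing applied before comparison (s); set 0 to
#'   disable.
#' @return A \linkS4class{TorusTransform} with attribute \code{error} (mean
#'   angular difference, radians) such that
#'   \code{applyTorusTransform(transform, coordsB)} matches \code{coordsA}.
#' @export
alignTori <- function(coordsA, coordsB, smoothSec = 0.2) {
  stopifnot(is(coordsA, "ToroidalCoordinates"),
            is(coordsB, "ToroidalCoordinates"))
  ok <- coordsA@valid & coordsB@valid
  if (!any(ok)) stop("no overlapping valid time points")
  A <- coordsA@angles[ok, 1:2, drop = FALSE]
  B <- coordsB@angles[ok, 1:2, drop = FALSE]
  dt <- if (length(coordsA@t) > 1) median(diff(coordsA@t)) else 1
  sigmaBins <- if (smoothSec > 0) smoothSec / dt else 0
  smooth2 <- function(M) {
    if (sigmaBins <= 0) return(M)
    apply(M, 2, .smoothAngles, sigmaBins = sigmaBins)
  }
  As <- smooth2(A)
  best <- NULL
  for (M in .torusSymmetries()) {
    cand <- (B %*% t(M)) %% (2 * pi)
    cs <- smooth2(cand)
    offs <- numeric(2)
    err <- 0
    for (ax in 1:2) {
      d <- As[, ax] - cs[, ax]
      offs[ax] <- atan2(mean(sin(d)), mean(cos(d)))
      dd <- (cs[, ax] + offs[ax] - As[, ax] + pi) %% (2 * pi) - pi
      err <- err + mean(abs(dd))
    }
    err <- err / 2
    if (is.null(best) || err < best$err)
      best <- list(M = M, offs = offs, err = err)
  }
  structure(new("TorusTransform", matrix = best$M, offsets = best$offs),
            error = best$err)
}

#' Conservation of toroidal phases across sessions
#'
#' Mean toroidal phase distance (flat product metric with per-axis wrap)
#' between matched neurons' peak phases in two aligned sessions, compared with
#' a null obtained by permuting neuron identities in the second session. The
#' one-sided P value is \code{(1 + #(null <= observed)) / (nShuffles + 1)}.
#'
#' @param phasesA,phasesB two-column matrices of peak phases (radians), rows
#'   matched across sessions.
#' @param nShuffles number of identity permutations.
#' @param seed RNG seed.
#' @return list(meanDistance, P, null) with the null distribution of mean
#'   distances.
#' @export
phaseDistanceTest <- function(phasesA, phasesB, nShuffles = 1000, seed = 1L) {
  phasesA <- as.matrix(phasesA)
  phasesB <- as.matrix(phasesB)
  n <- nrow(phasesA)
  if (n < 3) stop("at least 3 matched neurons are required")
  if (nrow(phasesB) != n) stop("phase lists must be matched")
  tdist <- function(a, b) {
    d <- abs(a - b) %% (2 * pi)
    d <- pmin(d, 2 * pi - d)
    sqrt(rowSums(d^2))
  }
  obs <- mean(tdist(phasesA, phasesB))
  set.seed(seed)
  null <- vapply(seq_len(nShuffles), function(s)
    mean(tdist(phasesA, phasesB[sample.int(n), , drop = FALSE])),
    numeric(1))
  P <- (1 + sum(null <= obs)) / (nShuffles + 1)
  list(meanDistance = obs, P = P, null = null)
}

#' Unwrap a toroidal trajectory onto the plane
#'
#' After temporal smoothing, each step is continued by the candidate among the
#' four wrap combinations (crossing or not crossing each circular origin) that
#' lies closest to the previous unwrapped point. Invalid (masked) time points
#' split the path into segments, each restarting at its wrapped coordinates.
#'
#' @param coords a \linkS4class{ToroidalCoordinates} (first two dimensions).
#' @param smoothSec Gaussian smoothing before unwrapping (s); 0 disables.
#' @return data.frame(t, x, y, segment) of the unwrapped flat path at valid
#'   time points.
#' @export
unwrapTorus <- function(coords, smoothSec = 0.2) {
  stopifnot(is(coords, "ToroidalCoordinates"))
  ok <- coords@valid
  ang <- coords@angles[, 1:2, drop = FALSE]
  tvec <- coords@t
  dt <- if (length(tvec) > 1) median(diff(tvec)) else 1
  if (smoothSec > 0 && sum(ok) > 2) {
    sb <- smoothSec / dt
    ang[ok, 1] <- .smoothAngles(ang[ok, 1], sb)
    ang[ok, 2] <- .smoothAngles(ang[ok, 2], sb)
  }
  idx <- which(ok)
  if (!length(idx)) stop("no valid coordinates")
  seg <- cumsum(c(1, diff(idx) > 1))
  x <- y <- numeric(length(idx))
  for (s in unique(seg)) {
    rows <- idx[seg == s]
    px <- ang[rows[1], 1]
    py <- ang[rows[1], 2]
    pos <- which(seg == s)
    x[pos[1]] <- px
    y[pos[1]] <- py
    if (length(rows) > 1) for (k in 2:length(rows)) {
      # candidate continuations: wrap by -2pi, 0, +2pi per axis, closest wins
      cx <- ang[rows[k], 1] + 2 * pi * round((px - ang[rows[k], 1]) / (2 * pi))
      cy <- ang[rows[k], 2] + 2 * pi * round((py - ang[rows[k], 2]) / (2 * pi))
      px <- cx
      py <- cy
      x[pos[k]] <- cx
      y[pos[k]] <- cy
    }
  }
  data.frame(t = tvec[idx], x = x, y = y, segment = seg)
}

#' Per-trial toroidal path length
#'
#' Each axis of the unwrapped path is fitted linearly against time within each
#' trial; trials with Pearson r > 0.5 on both axes are kept and their length
#' is the Euclidean distance between the fitted endpoints, normalized by the
#' mean baseline length.
#'
#' @param path data.frame(t, x, y) from \code{\link{unwrapTorus}}.
#' @param trials data.frame with columns \code{start}, \code{end} (s) and
#'   optionally \code{id}.
#' @param baselineMean normalization constant (mean trial length at baseline);
#'   1 leaves lengths unnormalized.
#' @return data.frame(id, r1, r2, length, normLength, included); trials
#'   shorter than 3 samples or failing the fit criterion are excluded.
#' @export
trialPathLength <- function(path, trials, baselineMean = 1) {
  if (baselineMean <= 0) stop("baselineMean must be positive")
  n <- nrow(trials)
  id <- if ("id" %in% colnames(trials)) trials$id else seq_len(n)
  out <- data.frame(id = id, r1 = NA_real_, r2 = NA_real_,
                    length = NA_real_, normLength = NA_real_,
                    included = FALSE)
  for (i in seq_len(n)) {
    sel <- path$t >= trials$start[i] & path$t < trials$end[i]
    if (sum(sel) < 3) next
    tt <- path$t[sel]
    fx <- lm(path$x[sel] ~ tt)
    fy <- lm(path$y[sel] ~ tt)
    r1 <- suppressWarnings(cor(path$x[sel], tt))
    r2 <- suppressWarnings(cor(path$y[sel], tt))
    out$r1[i] <- r1
    out$r2[i] <- r2
    if (!is.na(r1) && !is.na(r2) && abs(r1) > 0.5 && abs(r2) > 0.5) {
      ends <- range(tt)
      dx <- diff(predict(fx, data.frame(tt = ends)))
      dy <- diff(predict(fy, data.frame(tt = ends)))
      out$length[i] <- sqrt(dx^2 + dy^2)
      out$normLength[i] <- out$length[i] / baselineMean
      out$included[i] <- TRUE
    }
  }
  out
}
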