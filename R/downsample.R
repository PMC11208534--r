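#' @include AllClasses.R
NULL

#' Radial (maximin) downsampling of a point cloud
#'
#' Greedy landmark selection: the point with the largest summed absolute
#' coordinates is the first landmark; points within \code{eps} (Euclidean) of
#' any landmark are discarded, and the surviving point with the largest minimum
#' distance to all landmarks is added next, until the cloud is exhausted. All
#' retained pairwise distances are at least \code{eps}.
#'
#' @param X a \linkS4class{PointCloud}.
#' @param eps discard radius (same units as the coordinates).
#' @return A \linkS4class{PointCloud} of landmarks in selection order.
#' @export
radialDownsample <- function(X, eps) {
  stopifnot(is(X, "PointCloud"))
  if (eps < 0) stop("eps must be nonnegative")
  P <- X@points
  n <- nrow(P)
  if (n == 0) return(PointCloud(P[0, , drop = FALSE], integer(0)))
  first <- which.max(rowSums(abs(P)))
  active <- rep(TRUE, n)
  mind <- rep(Inf, n)
  sel <- integer(0)
  cur <- first
  repeat {
    sel <- c(sel, cur)
    active[cur] <- FALSE
    d <- sqrt(colSums((t(P) - P[cur, ])^2))
    mind <- pmin(mind, d)
    active[mind < eps] <- FALSE
    if (!any(active)) break
    cand <- which(active)
    cur <- cand[which.max(mind[cand])]
  }
  PointCloud(P[sel, , drop = FALSE], X@index[sel])
}

#' Fuzzy neighborhood memberships
#'
#' For each point x a scale \eqn{\sigma_x} is solved (by bisection, relative
#' tolerance 1e-8) so that the membership sum over its \eqn{\kappa} nearest
#' neighbors equals \eqn{\log_2(\kappa)}:
#' \deqn{\mu_x(y) = \exp(-d(x, y) / \sigma_x), \quad
#'   \sum_{y \in N_x} \mu_x(y) = \log_2 \kappa.}
#' Directed memberships are supported on the neighborhood where the scale is
#' solved (\eqn{\mu_x(y) = 0} for \eqn{y \notin N_x}) and combined
#' symmetrically as
#' \eqn{\mu(x, y) = \mu_x(y) + \mu_y(x) - \mu_x(y)\mu_y(x)}; an isolated
#' point therefore carries little total membership. When duplicate points
#' make the defining equation unattainable, \eqn{\sigma_x} is set by the zero
#' limit and a message is emitted.
#'
#' @param X a \linkS4class{PointCloud}.
#' @param kappa neighborhood size, less than the number of points.
#' @return A \linkS4class{FuzzyMembership}.
#' @export
fitMemberships <- function(X, kappa) {
  stopifnot(is(X, "PointCloud"))
  n <- nrow(X@points)
  if (kappa >= n) stop("kappa must be smaller than the number of points")
  if (kappa < 1) stop("kappa must be positive")
  D <- as.matrix(dist(X@points))
  target <- log2(kappa)
  diag(D) <- Inf
  nbr <- matrix(0L, n, kappa)
  dk <- matrix(0, n, kappa)
  for (i in seq_len(n)) {
    x <- D[i, ]
    th <- sort(x, partial = kappa)[kappa]
    idx <- which(x <= th)
    idx <- idx[order(x[idx])][seq_len(kappa)]
    nbr[i, ] <- idx
    dk[i, ] <- x[idx]
  }
  diag(D) <- 0
  degenerate <- rowSums(dk == 0) >= target
  lo <- rep(1e-12, n)
  hi <- rep(max(dk) + 1, n)
  repeat {
    bad <- rowSums(exp(-dk / hi)) < target & !degenerate
    if (!any(bad)) break
    hi[bad] <- hi[bad] * 2
  }
  # vectorized bisection to the documented 1e-8 relative tolerance
  for (iter in 1:32) {
    mid <- (lo + hi) / 2
    up <- rowSums(exp(-dk / mid)) < target
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  sigma <- (lo + hi) / 2
  sigma[degenerate] <- .Machine$double.xmin
  if (any(degenerate))
    message(sprintf("%d points with degenerate (duplicate-dominated) sigma",
                    sum(degenerate)))
  # directed memberships are supported on the kappa-neighborhood where the
  # scale was solved, so isolated points carry little total membership and
  # the subsequent greedy selection steers away from outliers
  mu_dir <- matrix(0, n, n)
  for (i in seq_len(n))
    mu_dir[i, nbr[i, ]] <- exp(-dk[i, ] / sigma[i])
  mu <- mu_dir + t(mu_dir) - mu_dir * t(mu_dir)
  new("FuzzyMembership", sigma = sigma, neighbors = nbr, mu = mu,
      kappa = as.integer(kappa))
}

#' Fuzzy (density-based) downsampling
#'
#' Iteratively selects the point with the highest summed membership strength
#' over the residual cloud,
#' \eqn{F_n(x) = \sum_{y \in X} \mu(x, y) - \sum_{y \in X_n} \mu(x, y)},
#' keeping the point most likely to lie in the neighborhoods of all remaining
#' points while steering away from regions already chosen. The first selected
#' point maximizes total membership; outliers are selected late or never.
#'
#' @param X a \linkS4class{PointCloud}.
#' @param kappa neighborhood size for \code{\link{fitMemberships}}.
#' @param m number of points to select (at most the cloud size).
#' @param memberships optional precomputed \linkS4class{FuzzyMembership}.
#' @return A \linkS4class{PointCloud} of the m selected points in selection
#'   order.
#' @export
fuzzyDownsample <- function(X, kappa, m, memberships = NULL) {
  stopifnot(is(X, "PointCloud"))
  n <- nrow(X@points)
  if (m <= 0) stop("m must be positive")
  if (m > n) stop("m must not exceed the number of points")
  if (is.null(memberships)) memberships <- fitMemberships(X, kappa)
  mu <- memberships@mu
  f <- rowSums(mu)  # F_0
  selected <- logical(n)
  sel <- integer(m)
  for (k in seq_len(m)) {
    cand <- which(!selected)
    best <- cand[which.max(f[cand])]
    sel[k] <- best
    selected[best] <- TRUE
    f <- f - mu[, best]  # maintain F_n incrementally
  }
  PointCloud(X@points[sel, , drop = FALSE], X@index[sel])
}
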