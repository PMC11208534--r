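#' @include AllClasses.R
NULL

#' Time-lagged cross-correlations of a population
#'
#' @slot values n x n x (lags + 1) array; \code{values[i, j, l]} is the summed
#'   product of neuron i's rate with neuron j's rate shifted l - 1 bins ahead.
#' @slot lagStep lag resolution (s), the rate sample step.
#' @export
setClass("CrossCorrSet",
         representation(values = "array", lagStep = "numeric"))

#' Time-lagged cross-correlation of all neuron pairs
#'
#' Computes \eqn{c_{ij}^\tau = \sum_t s_i^t s_j^{t+\tau}} for lags
#' \eqn{\tau = 0, \dots, \tau_{max}} at the rate sample step, over the entire
#' recording (no speed filter). Rates are expected at the clustering
#' resolution (e.g. a 0.3 s kernel sampled every 30-100 ms).
#'
#' @param r a \linkS4class{RateMatrix}.
#' @param tauMax maximum lag (s); must be at least one sample step.
#' @return A \linkS4class{CrossCorrSet}.
#' @export
crossCorr <- function(r, tauMax) {
  stopifnot(is(r, "RateMatrix"))
  dt <- binWidth(r)
  if (tauMax < dt) stop("tauMax must be at least one lag step")
  S <- rateValues(r)
  n <- nrow(S); T_ <- ncol(S)
  L <- floor(tauMax / dt)
  if (L >= T_) stop("tauMax exceeds the recording length")
  cc <- array(0, dim = c(n, n, L + 1))
  for (l in 0:L) {
    a <- S[, seq_len(T_ - l), drop = FALSE]
    b <- S[, seq_len(T_ - l) + l, drop = FALSE]
    cc[, , l + 1] <- tcrossprod(a, b)
  }
  new("CrossCorrSet", values = cc, lagStep = dt)
}

#' Inverse, normalized cross-correlation matrix
#'
#' For each pair, the minimum of the cross-correlogram over both orderings and
#' all lags is divided by the corresponding maximum:
#' \eqn{C_{ij} = \min_\tau[c_{ij}^\tau, c_{ji}^\tau] / \max_\tau[c_{ij}^\tau,
#' c_{ji}^\tau]}, giving values in [0, 1]; strongly coupled pairs (a peaked
#' correlogram) score low. Pairs whose correlogram is identically zero are set
#' to 1 (no evidence of coupling) with a message.
#'
#' @param cc a \linkS4class{CrossCorrSet}.
#' @return Symmetric numeric matrix in [0, 1].
#' @export
inverseNormCrossCorr <- function(cc) {
  stopifnot(is(cc, "CrossCorrSet"))
  v <- cc@values
  n <- dim(v)[1]
  lo <- apply(v, c(1, 2), min)
  hi <- apply(v, c(1, 2), max)
  # joint over both orderings
  lo <- pmin(lo, t(lo))
  hi <- pmax(hi, t(hi))
  C <- matrix(1, n, n)
  nz <- hi > 0
  C[nz] <- lo[nz] / hi[nz]
  if (any(!nz))
    message(sprintf("%d all-zero correlogram pairs set to 1", sum(!nz) - 0L))
  C
}

#' Cluster neurons into ensembles
#'
#' The feature vector of neuron i is row i of the elementwise-squared
#' inverse normalized cross-correlation matrix (self entries excluded); the
#' pairwise distance is one minus the Pearson correlation of feature vectors,
#' and average-linkage agglomerative clustering is cut at height \code{rho}.
#' Ensembles smaller than \code{minSize} are disregarded (label 0). Retained
#' ensembles are labelled 1, 2, ... by decreasing size.
#'
#' @param C inverse normalized cross-correlation matrix, or a list of such
#'   matrices from multiple recordings (squared entries are averaged).
#' @param rho cut height in correlation-distance units ([0, 2]).
#' @param minSize smallest retained ensemble (default 19 neurons).
#' @return An \linkS4class{EnsemblePartition}.
#' @export
clusterEnsembles <- function(C, rho, minSize = 19L) {
  if (is.list(C)) {
    C2 <- Reduce(`+`, lapply(C, function(m) m^2)) / length(C)
  } else {
    C2 <- C^2
  }
  n <- nrow(C2)
  if (n < 2) stop("at least 2 neurons are required for clustering")
  diag(C2) <- NA  # self-correlation excluded from the feature vectors
  D <- 1 - suppressWarnings(cor(t(C2), use = "pairwise.complete.obs"))
  D[!is.finite(D)] <- 1
  diag(D) <- 0
  D <- (D + t(D)) / 2
  hc <- hclust(as.dist(D), method = "average")
  raw <- cutree(hc, h = rho)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= minSize])
  labels <- integer(n)
  if (length(keep)) {
    ord <- keep[order(sizes[as.character(keep)], decreasing = TRUE)]
    for (k in seq_along(ord)) labels[raw == ord[k]] <- k
  }
  new("EnsemblePartition", labels = labels, distance = D, rho = rho,
      minSize = as.integer(minSize))
}
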