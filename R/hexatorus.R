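#' @include AllClasses.R toroidal_maps.R
NULL

#' Heat-kernel model configuration
#'
#' @slot t diffusion time.
#' @slot range truncation of the lattice sum (k, l in -range..range).
#' @slot variant "hex" (hexagonal torus) or "sqr" (square torus).
#' @export
setClass("HeatKernelConfig",
         representation(t = "numeric", range = "integer",
                        variant = "character"))

setValidity("HeatKernelConfig", function(object) {
  if (object@t <= 0) return("diffusion time t must be positive")
  if (!object@variant %in% c("hex", "sqr")) return("variant must be hex or sqr")
  TRUE
})

#' @param t diffusion time (0.1 in the reference analysis).
#' @param range lattice truncation (1 gives the 9-term sum).
#' @param variant "hex" or "sqr".
#' @rdname HeatKernelConfig-class
#' @export
heatKernelConfig <- function(t = 0.1, range = 1L, variant = c("hex", "sqr")) {
  new("HeatKernelConfig", t = t, range = as.integer(range),
      variant = match.arg(variant))
}

#' Heat kernel on the hexagonal or square torus
#'
#' Temperature at normalized toroidal position (x, y) in [0, 1)^2 after
#' diffusion time t from a point source at the origin, as a truncated lattice
#' sum:
#' \deqn{H(x, y; t) = \frac{1}{t} \sum_{k,l} \exp\left(-\frac{\pi}{t}
#'   Q(k + x, l + y)\right)}
#' with the hexagonal quadratic form \eqn{Q = \frac{2}{\sqrt 3}(u^2 + uv +
#' v^2)} or the square form \eqn{Q = u^2 + v^2}.
#'
#' @param x,y positions (vectors recycle); values are wrapped into [0, 1).
#' @param cfg a \linkS4class{HeatKernelConfig}.
#' @return Temperatures, same length as the inputs.
#' @export
heatKernel <- function(x, y, cfg = heatKernelConfig()) {
  stopifnot(is(cfg, "HeatKernelConfig"))
  x <- x %% 1
  y <- y %% 1
  H <- numeric(max(length(x), length(y)))
  x <- rep_len(x, length(H))
  y <- rep_len(y, length(H))
  for (k in -cfg@range:cfg@range) for (l in -cfg@range:cfg@range) {
    u <- k + x
    v <- l + y
    Q <- if (cfg@variant == "hex") (2 / sqrt(3)) * (u^2 + u * v + v^2)
         else u^2 + v^2
    H <- H + exp(-pi * Q / cfg@t)
  }
  H / cfg@t
}

#' Idealized heat-kernel rate map
#'
#' The torus is sampled on an even grid, the origin is shifted to the unit's
#' peak phase, and the mean temperature is taken in \code{bins}^2 square bins.
#' Setting \code{reverse} mirrors the second sampled coordinate, testing the
#' opposite axis orientation of the hexagonal torus.
#'
#' @param peak (theta1, theta2) peak phase in radians.
#' @param cfg a \linkS4class{HeatKernelConfig}.
#' @param bins output resolution.
#' @param sampleRes sampling grid per axis.
#' @param reverse mirror the second coordinate before evaluating.
#' @return A \linkS4class{RateMap2D} (rows index the first coordinate).
#' @export
modelRatemap <- function(peak, cfg = heatKernelConfig(), bins = 10,
                         sampleRes = 40, reverse = FALSE) {
  if (any(attr(peak, "degenerate") %||% FALSE)) stop("degenerate peak phase")
  p <- as.numeric(peak) / (2 * pi)
  u <- (seq_len(sampleRes) - 0.5) / sampleRes
  grid <- expand.grid(u = u, v = u)
  # reversal acts relative to the peak so the field stays centered on it
  dv <- if (reverse) p[2] - grid$v else grid$v - p[2]
  temp <- heatKernel(grid$u - p[1], dv, cfg)
  bu <- pmin(floor(grid$u * bins) + 1L, bins)
  bv <- pmin(floor(grid$v * bins) + 1L, bins)
  mp <- .meanPerBin(temp, bu, bv, bins)
  new("RateMap2D", values = mp$values, occupancy = mp$occupancy,
      sigmaBins = 0, binSize = 360 / bins)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify an ensemble's torus as hexagonal or square
#'
#' For each unit, the observed toroidal rate map (from pre-extrapolation
#' landmark coordinates, 10^2 bins) is correlated with heat-kernel model maps
#' centered on the unit's peak phase: hexagonal kernel in both axis
#' orientations (the maximum is kept) and the square kernel. The ensemble is
#' hexagonal when the median hexagonal correlation exceeds 0.6 and the square
#' median; square when the square median exceeds 0.6 and the hexagonal median.
#'
#' @param unitMaps list of observed maps (\linkS4class{RateMap2D} or
#'   matrices), one per unit.
#' @param peaks list of per-unit peak phases (radians) as returned by
#'   \code{\link{toroidalPeak}}.
#' @param cfg heat-kernel configuration (diffusion time; lattice range).
#' @param sampleRes sampling grid for the model maps.
#' @return A \linkS4class{TorusClassification}.
#' @export
classifyTorus <- function(unitMaps, peaks, cfg = heatKernelConfig(),
                          sampleRes = 40) {
  if (length(unitMaps) < 2) stop("at least 2 units are required")
  if (length(unitMaps) != length(peaks)) stop("one peak per unit map required")
  hexCfg <- heatKernelConfig(t = cfg@t, range = cfg@range, variant = "hex")
  sqrCfg <- heatKernelConfig(t = cfg@t, range = cfg@range, variant = "sqr")
  getv <- function(m) if (is(m, "RateMap2D")) m@values else as.matrix(m)
  nb <- nrow(getv(unitMaps[[1]]))
  hexCorr <- sqrCorr <- numeric(length(unitMaps))
  for (i in seq_along(unitMaps)) {
    obs <- as.numeric(getv(unitMaps[[i]]))
    pk <- peaks[[i]]
    h1 <- as.numeric(modelRatemap(pk, hexCfg, bins = nb,
                                  sampleRes = sampleRes)@values)
    h2 <- as.numeric(modelRatemap(pk, hexCfg, bins = nb,
                                  sampleRes = sampleRes, reverse = TRUE)@values)
    sq <- as.numeric(modelRatemap(pk, sqrCfg, bins = nb,
                                  sampleRes = sampleRes)@values)
    hexCorr[i] <- max(cor(obs, h1), cor(obs, h2))
    sqrCorr[i] <- cor(obs, sq)
  }
  hm <- median(hexCorr)
  sm <- median(sqrCorr)
  label <- if (hm > 0.6 && hm > sm) "hexagonal"
           else if (sm > 0.6 && sm > hm) "square" else "unclassified"
  new("TorusClassification", hexCorr = hexCorr, sqrCorr = sqrCorr,
      hexMedian = hm, sqrMedian = sm, label = label)
}

#' Time-varying heat-kernel model rates
#'
#' Replaces the sampled toroidal coordinates with decoded positions: each
#' unit's idealized rate is the hexagonal heat kernel evaluated at the decoded
#' position relative to the unit's peak phase. Invalid (masked) times
#' propagate as NA.
#'
#' @param coords a \linkS4class{ToroidalCoordinates} (first two dimensions).
#' @param peaks list of per-unit peak phases (radians).
#' @param cfg heat-kernel configuration.
#' @return units x time matrix of model rates.
#' @export
heatModelRates <- function(coords, peaks, cfg = heatKernelConfig()) {
  stopifnot(is(coords, "ToroidalCoordinates"))
  ang <- coords@angles[, 1:2, drop = FALSE] / (2 * pi)
  out <- matrix(NA_real_, length(peaks), nrow(ang))
  ok <- coords@valid
  for (i in seq_along(peaks)) {
    p <- as.numeric(peaks[[i]]) / (2 * pi)
    out[i, ok] <- heatKernel(ang[ok, 1] - p[1], ang[ok, 2] - p[2], cfg)
  }
  out
}
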