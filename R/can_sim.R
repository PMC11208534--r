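#' @include AllClasses.R trajectory.R
NULL

# Sheet coordinates (unit spacing) and 2x2-blocked preferred directions
# (E, N, W, S) for the inhibitory-sheet network.
.sheetLayout <- function(nRows, nCols) {
  ix <- rep(seq_len(nCols) - 1L, each = nRows)
  iy <- rep(seq_len(nRows) - 1L, times = nCols)
  block <- 2L * (iy %% 2L) + (ix %% 2L)
  phibar <- c(0, pi / 2, pi, 3 * pi / 2)[block + 1L]
  list(x = ix, y = iy, phibar = phibar)
}

# Inhibitory connectivity: W[j, i] = W0 when the periodic sheet distance from
# unit i to unit j's location shifted by l along j's preferred direction is
# at most R, else 0.
.sheetWeights <- function(cfg) {
  lay <- .sheetLayout(cfg@nRows, cfg@nCols)
  sx <- lay$x + cfg@dirOffset * cos(lay$phibar)
  sy <- lay$y + cfg@dirOffset * sin(lay$phibar)
  dx <- abs(outer(sx, lay$x, "-")) %% cfg@nCols
  dx <- pmin(dx, cfg@nCols - dx)
  dy <- abs(outer(sy, lay$y, "-")) %% cfg@nRows
  dy <- pmin(dy, cfg@nRows - dy)
  W <- matrix(0, length(lay$x), length(lay$x))
  W[dx^2 + dy^2 <= cfg@connRadius^2] <- cfg@inhibW
  list(W = W, layout = lay)
}

.checkRates <- function(rates, model) {
  if (any(!is.finite(rates)))
    stop(sprintf(
      "%s simulation produced non-finite rates: unstable parameters", model))
}

#' Simulate an inhibitory-sheet grid cell network
#'
#' Euler updates of the rectified rate dynamics
#' \deqn{f_{t+1} = f_t + (1/\rho)\,(-f_t + [J + f_t W + \gamma s \cos(\phi -
#' \bar\phi)]_+)}
#' on a periodic sheet with purely inhibitory, direction-shifted connectivity.
#' The state is initialized at random, stabilized at zero velocity, then driven
#' by the trajectory interpolated at the integration step; output rates are
#' resampled at 10 ms and rates below \code{rateFloor} are zeroed.
#'
#' @param config a \linkS4class{CANConfig} with \code{model =
#'   "inhibitory_sheet"}.
#' @param traj the driving \linkS4class{TrajectorySample}.
#' @return A \linkS4class{SimOutput}; \code{bumpPhase} tracks the population
#'   bump on the sheet (two angles, one per sheet axis).
#' @export
simulateInhibitorySheet <- function(config, traj) {
  stopifnot(is(config, "CANConfig"), is(traj, "TrajectorySample"))
  if (config@model != "inhibitory_sheet")
    stop("config@model must be 'inhibitory_sheet'")
  ws <- .sheetWeights(config)
  N <- length(ws$layout$x)
  tr <- resampleTrajectory(traj, config@dt)
  set.seed(config@seed)
  f0 <- runif(N)
  keep_every <- max(1L, round(0.01 / config@dt))
  sim <- .sheet_dynamics(ws$W, f0, ws$layout$phibar, tr@speed, tr@heading,
                         config@drive, config@velocityGain, config@relax,
                         config@rateFloor, config@stabilizationSteps,
                         keep_every)
  .checkRates(sim$rates, "inhibitory_sheet")
  n_keep <- ncol(sim$rates)
  dt_out <- config@dt * keep_every
  kept_idx <- seq_len(n_keep) * keep_every
  traj_out <- TrajectorySample(t = tr@t[kept_idx], x = tr@x[kept_idx],
                               y = tr@y[kept_idx])
  phases <- cbind(2 * pi * ws$layout$x / config@nCols,
                  2 * pi * ws$layout$y / config@nRows)
  # the sheet carries a lattice of bumps, so the pattern phase lives at the
  # lattice frequency: track the two dominant non-collinear Fourier modes of
  # the mean pattern
  bump <- .sheetPatternPhase(sim$rates, ws$layout, config@nRows, config@nCols)
  new("SimOutput",
      rates = RateMatrix(sim$rates, dt = dt_out, transform = "raw",
                         t = traj_out@t, speed = traj_out@speed),
      unitPhases = phases, trajectory = traj_out, bumpPhase = bump,
      config = config)
}

.bumpPhaseFromRates <- function(rates, phases) {
  cs1 <- crossprod(rates, cbind(cos(phases[, 1]), sin(phases[, 1])))
  cs2 <- crossprod(rates, cbind(cos(phases[, 2]), sin(phases[, 2])))
  cbind(atan2(cs1[, 2], cs1[, 1]) %% (2 * pi),
        atan2(cs2[, 2], cs2[, 1]) %% (2 * pi))
}

# phases of the two strongest non-collinear spatial Fourier modes of the
# mean sheet pattern, evaluated per frame
.sheetPatternPhase <- function(rates, layout, nRows, nCols) {
  pat <- matrix(rowMeans(rates), nRows, nCols)
  F <- fft(pat)
  amp <- Mod(F)
  amp[1, 1] <- 0  # DC
  ord <- order(amp, decreasing = TRUE)
  idx2freq <- function(k) {
    r <- (k - 1) %% nRows
    c_ <- (k - 1) %/% nRows
    c(ifelse(r > nRows / 2, r - nRows, r), ifelse(c_ > nCols / 2, c_ - nCols, c_))
  }
  k1 <- idx2freq(ord[1])
  k2 <- NULL
  for (k in ord[-1]) {
    f2 <- idx2freq(k)
    if (abs(f2[1] * k1[2] - f2[2] * k1[1]) > 1e-9) { k2 <- f2; break }
  }
  if (is.null(k2)) k2 <- c(k1[2], -k1[1])
  wave <- function(kk)
    exp(-2i * pi * (kk[1] * layout$y / nRows + kk[2] * layout$x / nCols))
  z1 <- as.vector(rbind(wave(k1)) %*% rates)
  z2 <- as.vector(rbind(wave(k2)) %*% rates)
  cbind(Arg(z1) %% (2 * pi), Arg(z2) %% (2 * pi))
}

.torusSim <- function(config, traj, twisted) {
  stopifnot(is(config, "CANConfig"), is(traj, "TrajectorySample"))
  ex <- modifyList(list(intensity = 0.3, sigma = 0.24, tshift = 0.05,
                        tau = 0.8, arenaNorm = 100, nRef = 90,
                        frameRef = 0.01), config@extra)
  tr <- resampleTrajectory(traj, config@dt)
  n <- length(tr@t)
  # velocity input: gain times speed in arena-normalized units per second,
  # expressed per reference frame so the spatial grid scale is independent of
  # the integration step
  sbox <- tr@speed / ex$arenaNorm * (config@dt / ex$frameRef)
  vel <- cbind(config@gridGain * sbox * cos(tr@heading),
               config@gridGain * sbox * sin(tr@heading))
  ly <- if (twisted) sqrt(3) / 2 else 1
  cx <- rep((seq_len(config@nCols) - 1) / config@nCols,
            each = config@nRows)
  cy <- rep((seq_len(config@nRows) - 1) / config@nRows * ly,
            times = config@nCols)
  cells <- cbind(cx, cy)
  set.seed(config@seed)
  a0 <- runif(nrow(cells))
  sim <- .torus_dynamics(cells, vel, a0, ex$intensity, ex$sigma, ex$tshift,
                         ex$tau, twisted, config@stabilizationSteps,
                         norm = ex$nRef / nrow(cells))
  .checkRates(sim$rates, if (twisted) "twisted_torus" else "square_torus")
  # unit phases in the dual-lattice circle coordinates (single-valued on the
  # twisted torus; plain (x, y) on the square torus)
  phases <- if (twisted)
    cbind(2 * pi * (cells[, 1] - cells[, 2] / sqrt(3)),
          2 * pi * 2 * cells[, 2] / sqrt(3)) %% (2 * pi)
  else cbind(2 * pi * cells[, 1], 2 * pi * cells[, 2])
  new("SimOutput",
      rates = RateMatrix(sim$rates, dt = config@dt, transform = "raw",
                         t = tr@t, speed = tr@speed),
      unitPhases = phases, trajectory = tr, bumpPhase = sim$bump,
      config = config)
}

#' Simulate a twisted-torus grid cell network
#'
#' Divisive-normalization attractor dynamics on a sheet whose distance is the
#' minimum over the seven periodic copies of the twisted torus (offsets (0,0),
#' (+-1,0), (+-1/2, +-sqrt(3)/2)), producing hexagonally periodic firing. The
#' velocity input is \code{gridGain} times the running speed in
#' arena-normalized units, so a foraging walk drags the activity bump around
#' the torus several times.
#'
#' @param config a \linkS4class{CANConfig} with \code{model = "twisted_torus"}.
#' @param traj the driving \linkS4class{TrajectorySample}.
#' @return A \linkS4class{SimOutput}; \code{bumpPhase} holds the ground-truth
#'   bump phase per frame, against which decoded coordinates can be scored.
#' @export
simulateTwistedTorus <- function(config, traj) {
  if (config@model != "twisted_torus")
    stop("config@model must be 'twisted_torus'")
  .torusSim(config, traj, twisted = TRUE)
}

#' Simulate a square-torus grid cell network
#'
#' The untwisted variant of \code{\link{simulateTwistedTorus}}: ordinary
#' unit-torus distance (nine periodic copies), yielding square lattice
#' periodicity. Serves as the negative control for hexagonal-torus
#' classification.
#'
#' @param config a \linkS4class{CANConfig} with \code{model = "square_torus"}.
#' @param traj the driving \linkS4class{TrajectorySample}.
#' @return A \linkS4class{SimOutput}.
#' @export
simulateSquareTorus <- function(config, traj) {
  if (config@model != "square_torus")
    stop("config@model must be 'square_torus'")
  .torusSim(config, traj, twisted = FALSE)
}
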