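#' @include AllClasses.R
NULL

#' Simulated random-walk foraging trajectory
#'
#' Generates a smooth 2-D random walk confined to a square arena: running speed
#' follows a clipped AR(1) process and heading diffuses, with the heading
#' reflected at the walls so the speed distribution is unaffected by the
#' boundary.
#'
#' @param duration length of the walk (s).
#' @param arena side of the square arena (cm); the walk starts at its center.
#' @param speedParams list with \code{mean} and \code{sd} of the running speed
#'   (cm/s) and the AR(1) memory \code{ar} in [0, 1).
#' @param dt sample step (s).
#' @param turnSd heading diffusion (rad per sqrt(s)).
#' @param seed RNG seed; the walk is reproducible given the seed.
#' @return A \linkS4class{TrajectorySample} with kinematics derived from the
#'   generated positions.
#' @export
randomWalkTrajectory <- function(duration, arena, speedParams = list(),
                                 dt = 0.02, turnSd = 2.5, seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  if (arena <= 0) stop("arena must be positive")
  sp <- modifyList(list(mean = 15, sd = 5, ar = 0.98), speedParams)
  set.seed(seed)
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  x <- y <- numeric(n)
  x[1] <- y[1] <- arena / 2
  heading <- runif(1, 0, 2 * pi)
  # AR(1) speed about its mean, clipped at zero
  s <- numeric(n)
  s[1] <- max(0, sp$mean + rnorm(1, 0, sp$sd))
  innov_sd <- sp$sd * sqrt(1 - sp$ar^2)
  turns <- rnorm(n, 0, turnSd * sqrt(dt))
  for (i in seq_len(n - 1)) {
    heading <- (heading + turns[i]) %% (2 * pi)
    step <- s[i] * dt
    nx <- x[i] + step * cos(heading)
    ny <- y[i] + step * sin(heading)
    # reflect the heading at the walls, clamping position inside
    if (nx < 0 || nx > arena) {
      heading <- (pi - heading) %% (2 * pi)
      nx <- min(max(nx, 0), arena)
    }
    if (ny < 0 || ny > arena) {
      heading <- (-heading) %% (2 * pi)
      ny <- min(max(ny, 0), arena)
    }
    x[i + 1] <- nx
    y[i + 1] <- ny
    s[i + 1] <- max(0, sp$mean + sp$ar * (s[i] - sp$mean) +
                      rnorm(1, 0, innov_sd))
  }
  TrajectorySample(t = t, x = x, y = y)
}

#' Head-fixed wheel-running trajectory
#'
#' A 1-D analogue of the foraging walk: distance accumulates along x at an
#' AR(1) speed (no walls), y stays at zero. Used to drive the torus simulators
#' in wheel/VR-like conditions; an optional gain rescales the integrated
#' distance, mimicking an optical-flow gain manipulation.
#'
#' @param duration length (s).
#' @param speedParams as in \code{\link{randomWalkTrajectory}}.
#' @param dt sample step (s).
#' @param gain multiplies the integrated distance.
#' @param seed RNG seed.
#' @return A \linkS4class{TrajectorySample}.
#' @export
wheelTrajectory <- function(duration, speedParams = list(), dt = 0.02,
                            gain = 1, seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  sp <- modifyList(list(mean = 15, sd = 5, ar = 0.98), speedParams)
  set.seed(seed)
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  s <- numeric(n)
  s[1] <- max(0, sp$mean + rnorm(1, 0, sp$sd))
  innov_sd <- sp$sd * sqrt(1 - sp$ar^2)
  for (i in seq_len(n - 1))
    s[i + 1] <- max(0, sp$mean + sp$ar * (s[i] - sp$mean) +
                      rnorm(1, 0, innov_sd))
  x <- cumsum(c(0, s[-n] * dt)) * gain
  TrajectorySample(t = t, x = x, y = rep(0, n))
}

#' Resample a trajectory at a new time step
#'
#' Linear interpolation of position at an even grid of step \code{dt};
#' kinematics are recomputed from the interpolated positions.
#'
#' @param traj a \linkS4class{TrajectorySample}.
#' @param dt new sample step (s).
#' @return A \linkS4class{TrajectorySample}.
#' @export
resampleTrajectory <- function(traj, dt) {
  tt <- seq(traj@t[1], traj@t[length(traj@t)], by = dt)
  x <- approx(traj@t, traj@x, xout = tt)$y
  y <- approx(traj@t, traj@y, xout = tt)$y
  TrajectorySample(t = tt, x = x, y = y)
}
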