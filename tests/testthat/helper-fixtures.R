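# Shared simulation fixtures, computed once per test run. The twisted-torus
# run mirrors the reference simulation conditions (20 x 20 network,
# grid_gain = 0.06, 5000-frame random walk); the analysis profile for
# simulated modules uses d = 6 whitened dimensions and a two-step
# downsampling to a few hundred landmarks.
.fixtureCache <- new.env(parent = emptyenv())

simProfile <- function() {
  parameterProfile(d = 6L, eps = 0.4, kappa = 300L, m = 450L, speedMin = 5)
}

twistedSim <- function() {
  if (is.null(.fixtureCache$twSim)) {
    traj <- randomWalkTrajectory(50, 100, dt = 0.01, seed = 11)
    .fixtureCache$twSim <- simulateTwistedTorus(
      canConfig("twisted_torus", seed = 7), traj)
  }
  .fixtureCache$twSim
}

twistedPipeline <- function() {
  if (is.null(.fixtureCache$twRes)) {
    sim <- twistedSim()
    .fixtureCache$twRes <- runPipeline(sim@rates, sim@trajectory,
                                       simProfile(), nShuffles = 20, seed = 5)
  }
  .fixtureCache$twRes
}

squarePipeline <- function() {
  if (is.null(.fixtureCache$sqRes)) {
    traj <- randomWalkTrajectory(50, 100, dt = 0.01, seed = 11)
    sim <- simulateSquareTorus(canConfig("square_torus", seed = 7), traj)
    .fixtureCache$sqSim <- sim
    .fixtureCache$sqRes <- runPipeline(sim@rates, sim@trajectory,
                                       simProfile(), nShuffles = 0, seed = 5,
                                       stages = c("topology", "decode",
                                                  "classify"))
  }
  .fixtureCache$sqRes
}

# best per-axis circular correlation between decoded angles and the true bump
# phase over the enumerated torus symmetries (gauge alignment)
gaugeAlignedCircCor <- function(angles, bump) {
  best <- c(0, 0)
  for (M in gridtorus:::.torusSymmetries()) {
    tb <- (bump %*% t(M)) %% (2 * pi)
    c1 <- circularCor(angles[, 1], tb[, 1])
    c2 <- circularCor(angles[, 2], tb[, 2])
    if (min(c1, c2) > min(best)) best <- c(c1, c2)
  }
  best
}
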