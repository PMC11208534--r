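.mkCoords <- function(ang, t = NULL) {
  ang <- ang %% (2 * pi)
  new("ToroidalCoordinates", angles = ang,
      t = if (is.null(t)) seq_len(nrow(ang)) * 0.02 else t,
      valid = rep(TRUE, nrow(ang)), distributions = list(), nBins = 16L)
}

test_that("torus alignment recovers planted transforms exactly", {
  set.seed(20)
  n <- 800
  A <- cbind(cumsum(rnorm(n, 0, 0.1)), cumsum(rnorm(n, 0, 0.1)))
  ca <- .mkCoords(A)
  # identity
  tr0 <- alignTori(ca, ca, smoothSec = 0)
  expect_equal(tr0@matrix, diag(2L))
  expect_lt(attr(tr0, "error"), 1e-9)
  # planted flip + offset
  B <- cbind(-A[, 1] + 1.3, A[, 2] + 2.1)
  trF <- alignTori(ca, .mkCoords(B), smoothSec = 0)
  aligned <- applyTorusTransform(trF, .mkCoords(B))
  expect_lt(mean(abs(((coordAngles(aligned) - coordAngles(ca) + pi) %%
                        (2 * pi)) - pi)), 1e-6)
  # planted hexagonal axis substitution (theta1, theta1 + theta2)
  H <- cbind(A[, 1], A[, 1] + A[, 2] + 0.7)
  trH <- alignTori(ca, .mkCoords(H), smoothSec = 0)
  alignedH <- applyTorusTransform(trH, .mkCoords(H))
  expect_lt(mean(abs(((coordAngles(alignedH) - coordAngles(ca) + pi) %%
                        (2 * pi)) - pi)), 1e-6)
})

test_that("alignment recovers every enumerated group element", {
  set.seed(21)
  n <- 500
  A <- cbind(cumsum(rnorm(n, 0, 0.15)), cumsum(rnorm(n, 0, 0.15)))
  ca <- .mkCoords(A)
  syms <- gridtorus:::.torusSymmetries()
  for (k in seq(1, length(syms), by = 5)) {
    M <- syms[[k]]
    B <- (A %*% t(M) + rep(c(0.4, 5.0), each = n))
    tr <- alignTori(ca, .mkCoords(B), smoothSec = 0)
    aligned <- applyTorusTransform(tr, .mkCoords(B))
    expect_lt(mean(abs(((coordAngles(aligned) - coordAngles(ca) + pi) %%
                          (2 * pi)) - pi)), 1e-6)
  }
})

test_that("phase-distance test gives minimal P for identical phases", {
  set.seed(22)
  ph <- matrix(runif(40, 0, 2 * pi), ncol = 2)
  res <- phaseDistanceTest(ph, ph, nShuffles = 200, seed = 3)
  expect_equal(res$meanDistance, 0)
  expect_equal(res$P, 1 / 201)
  # deterministic under a fixed seed
  res2 <- phaseDistanceTest(ph, ph, nShuffles = 200, seed = 3)
  expect_identical(res$null, res2$null)
  expect_error(phaseDistanceTest(ph[1:2, ], ph[1:2, ]), "at least 3")
})

test_that("phase-distance P is roughly uniform for random phases", {
  set.seed(23)
  ps <- replicate(60, {
    a <- matrix(runif(30, 0, 2 * pi), ncol = 2)
    b <- matrix(runif(30, 0, 2 * pi), ncol = 2)
    phaseDistanceTest(a, b, nShuffles = 99,
                      seed = sample.int(1e6, 1))$P
  })
  expect_gt(mean(ps < 0.5), 0.25)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("unwrapping continues through wraps and preserves modular identity", {
  # constant angular velocity through many wraps
  n <- 400
  th1 <- (0.1 * seq_len(n)) %% (2 * pi)
  th2 <- (0.07 * seq_len(n)) %% (2 * pi)
  co <- .mkCoords(cbind(th1, th2))
  up <- unwrapTorus(co, smoothSec = 0)
  expect_equal(diff(up$x), rep(0.1, n - 1), tolerance = 1e-9)
  expect_equal(up$x %% (2 * pi), th1, tolerance = 1e-9)
  # planted 2-D winding (5, 3): net displacement (10 pi, 6 pi)
  t_ <- seq(0, 1, length.out = 2000)
  co2 <- .mkCoords(cbind(2 * pi * 5 * t_, 2 * pi * 3 * t_))
  up2 <- unwrapTorus(co2, smoothSec = 0)
  expect_equal(up2$x[nrow(up2)] - up2$x[1], 10 * pi, tolerance = 1e-6)
  expect_equal(up2$y[nrow(up2)] - up2$y[1], 6 * pi, tolerance = 1e-6)
  # masked gaps split segments
  co3 <- .mkCoords(cbind(th1, th2))
  co3@valid[100:110] <- FALSE
  up3 <- unwrapTorus(co3, smoothSec = 0)
  expect_equal(length(unique(up3$segment)), 2L)
})

test_that("trial path lengths follow the fitted-endpoint arithmetic", {
  t_ <- seq(0, 10, by = 0.02)
  path <- data.frame(t = t_, x = 4 * pi * t_ / 10, y = 2 * pi * t_ / 10)
  trials <- data.frame(start = 0, end = 10.1)
  out <- trialPathLength(path, trials)
  expect_true(out$included)
  expect_equal(out$length, sqrt(20) * pi, tolerance = 1e-6)
  # doubling the angular velocity doubles the normalized length
  path2 <- data.frame(t = t_, x = 8 * pi * t_ / 10, y = 4 * pi * t_ / 10)
  out2 <- trialPathLength(path2, trials, baselineMean = out$length)
  expect_equal(out2$normLength, 2, tolerance = 1e-6)
  # pure noise paths are excluded by the fit criterion
  set.seed(24)
  noise <- data.frame(t = t_, x = rnorm(length(t_)), y = rnorm(length(t_)))
  expect_false(trialPathLength(noise, trials)$included)
  # trials shorter than 3 samples are excluded
  tiny <- trialPathLength(path, data.frame(start = 0, end = 0.03))
  expect_false(tiny$included)
})

test_that("gain manipulation scales toroidal path length inversely", {
  # wheel-like runs through the twisted-torus model at gains 1 and 0.5:
  # halving the gain halves the decoded path length per distance run
  lens <- numeric(2)
  gains <- c(1, 0.5)
  for (g in seq_along(gains)) {
    traj <- wheelTrajectory(40, speedParams = list(mean = 20, sd = 2),
                            dt = 0.01, seed = 30)
    cfg <- canConfig("twisted_torus", gridGain = 0.06 * gains[g], seed = 8,
                     stabilizationSteps = 300L)
    sim <- simulateTwistedTorus(cfg, traj)
    co <- new("ToroidalCoordinates", angles = sim@bumpPhase,
              t = sim@trajectory@t, valid = rep(TRUE, nrow(sim@bumpPhase)),
              distributions = list(), nBins = 16L)
    up <- unwrapTorus(co, smoothSec = 0.2)
    out <- trialPathLength(up, data.frame(start = 0, end = max(up$t) + 1))
    lens[g] <- out$length
  }
  expect_equal(lens[1] / lens[2], 2, tolerance = 0.1)
})
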