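test_that("heat kernels match the direct 9-term summation", {
  # square kernel at the origin, t = 0.1: 10 (1 + 4 e^{-10 pi} + 4 e^{-20 pi})
  sqr <- heatKernelConfig(t = 0.1, variant = "sqr")
  expect_equal(heatKernel(0, 0, sqr),
               10 * (1 + 4 * exp(-10 * pi) + 4 * exp(-20 * pi)),
               tolerance = 1e-12)
  hex <- heatKernelConfig(t = 0.1, variant = "hex")
  set.seed(16)
  xs <- runif(25); ys <- runif(25)
  for (v in c("hex", "sqr")) {
    cfg <- heatKernelConfig(t = 0.1, variant = v)
    got <- heatKernel(xs, ys, cfg)
    want <- mapply(function(x, y) bruteForceHeatKernel(x, y, 0.1, v), xs, ys)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(heatKernelConfig(t = -1), "positive")
})

test_that("heat kernels are periodic, symmetric, positive, peaked at origin", {
  hex <- heatKernelConfig(variant = "hex")
  x <- runif(20); y <- runif(20)
  expect_equal(heatKernel(x, y, hex), heatKernel(x + 1, y, hex))
  expect_equal(heatKernel(x, y, hex), heatKernel(y, x, hex))
  g <- expand.grid(x = (0:39) / 40, y = (0:39) / 40)
  H <- heatKernel(g$x, g$y, hex)
  expect_true(all(H > 0))
  expect_equal(which.max(H), 1L)  # (0, 0) first grid point
  # total mass over the torus decreases with diffusion time
  masses <- vapply(c(0.05, 0.1, 0.2, 0.4), function(t_)
    mean(heatKernel(g$x, g$y, heatKernelConfig(t = t_, variant = "hex"))),
    numeric(1))
  expect_true(all(diff(masses) < 0))
})

test_that("model rate maps are centered on the peak and shift-equivariant", {
  hex <- heatKernelConfig(variant = "hex")
  m0 <- modelRatemap(c(0, 0), hex, bins = 10, sampleRes = 40)
  # hottest bins straddle the origin (wrap makes bins 1 and 10 symmetric)
  pk0 <- which(m0@values == max(m0@values), arr.ind = TRUE)
  expect_true(all(pk0 %in% c(1L, 10L)))
  ctr <- toroidalPeak(m0@values)
  expect_lt(abs(((ctr[1] + pi) %% (2 * pi)) - pi), 2 * pi / 10)
  expect_lt(abs(((ctr[2] + pi) %% (2 * pi)) - pi), 2 * pi / 10)
  # shifting the peak by whole bins shifts the map
  shift <- c(3, 2) * 2 * pi / 10
  m1 <- modelRatemap(shift, hex, bins = 10, sampleRes = 40)
  rolled <- m0@values[((0:9 - 3) %% 10) + 1, ((0:9 - 2) %% 10) + 1]
  expect_equal(m1@values, rolled, tolerance = 1e-9)
  # matches brute-force dense evaluation within binning error
  dense <- matrix(0, 10, 10)
  cnt <- matrix(0, 10, 10)
  for (u in (1:80 - 0.5) / 80) for (v in (1:80 - 0.5) / 80) {
    bu <- floor(u * 10) + 1; bv <- floor(v * 10) + 1
    dense[bu, bv] <- dense[bu, bv] + bruteForceHeatKernel(u, v, 0.1, "hex")
    cnt[bu, bv] <- cnt[bu, bv] + 1
  }
  m2 <- modelRatemap(c(0, 0), hex, bins = 10, sampleRes = 80)
  expect_equal(m2@values, dense / cnt, tolerance = 1e-9)
})

test_that("classification separates hexagonal from square model maps", {
  set.seed(17)
  peaks <- lapply(1:30, function(i) runif(2, 0, 2 * pi))
  mk <- function(variant, reverse = FALSE) lapply(peaks, function(p)
    modelRatemap(p, heatKernelConfig(variant = variant), reverse = reverse))
  clHex <- classifyTorus(mk("hex"), peaks)
  expect_identical(clHex@label, "hexagonal")
  expect_equal(clHex@hexMedian, 1, tolerance = 1e-9)
  clRev <- classifyTorus(mk("hex", reverse = TRUE), peaks)
  expect_identical(clRev@label, "hexagonal")
  clSqr <- classifyTorus(mk("sqr"), peaks)
  expect_identical(clSqr@label, "square")
  expect_gt(clSqr@sqrMedian, clSqr@hexMedian)
  expect_error(classifyTorus(mk("hex")[1], peaks[1]), "at least 2")
})

test_that("classification round-trips through measured peaks", {
  # peaks re-estimated from the maps themselves, as the pipeline does
  set.seed(18)
  truth <- lapply(1:20, function(i) runif(2, 0, 2 * pi))
  maps <- lapply(truth, function(p)
    modelRatemap(p, heatKernelConfig(variant = "hex"), bins = 10,
                 sampleRes = 40))
  measured <- lapply(maps, function(m) toroidalPeak(m@values))
  cl <- classifyTorus(maps, measured)
  expect_identical(cl@label, "hexagonal")
  expect_gt(cl@hexMedian, 0.95)
})

test_that("classification is invariant to a global toroidal rotation", {
  set.seed(19)
  peaks <- lapply(1:15, function(i) runif(2, 0, 2 * pi))
  maps <- lapply(peaks, function(p)
    modelRatemap(p, heatKernelConfig(variant = "hex")))
  rot <- c(1.1, 2.3)
  peaks2 <- lapply(peaks, function(p) (p + rot) %% (2 * pi))
  maps2 <- lapply(peaks2, function(p)
    modelRatemap(p, heatKernelConfig(variant = "hex")))
  c1 <- classifyTorus(maps, peaks)
  c2 <- classifyTorus(maps2, peaks2)
  expect_equal(c1@hexMedian, c2@hexMedian, tolerance = 0.02)
  expect_identical(c1@label, c2@label)
})

test_that("heat-model rates evaluate the kernel at decoded positions", {
  peaks <- list(c(1, 2), c(4, 0.5))
  ang <- rbind(c(1, 2), c(1.6, 2.6), c(4, 0.5))
  coords <- new("ToroidalCoordinates", angles = ang, t = 0:2,
                valid = c(TRUE, TRUE, TRUE),
                distributions = list(), nBins = 16L)
  hm <- heatModelRates(coords, peaks)
  hex <- heatKernelConfig(variant = "hex")
  # constant coordinates at a unit's peak give the maximal (origin) rate
  expect_equal(hm[1, 1], heatKernel(0, 0, hex))
  expect_equal(hm[2, 3], heatKernel(0, 0, hex))
  expect_true(all(hm[1, 2:3] < hm[1, 1]))
  # masked times propagate
  coords@valid <- c(TRUE, FALSE, TRUE)
  hm2 <- heatModelRates(coords, peaks)
  expect_true(all(is.na(hm2[, 2])))
  # zero-length coordinates give an empty result
  empty <- new("ToroidalCoordinates", angles = matrix(0, 0, 2), t = numeric(0),
               valid = logical(0), distributions = list(), nBins = 16L)
  expect_equal(ncol(heatModelRates(empty, peaks)), 0L)
})
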