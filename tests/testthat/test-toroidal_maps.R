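test_that("spatial rate maps: flat input, single peak, unvisited-bin fill", {
  set.seed(11)
  pos <- cbind(runif(4000, 0, 60), runif(4000, 0, 60))
  m <- spatialRatemap(rep(2, 4000), pos, bins = 10, sigmaBins = 1)
  expect_equal(as.numeric(m@values), rep(2, 100), tolerance = 1e-9)
  act <- as.numeric(pos[, 1] < 6 & pos[, 2] < 6)
  m2 <- spatialRatemap(act, pos, bins = 10, sigmaBins = 1)
  expect_equal(which.max(m2@values), 1L)
  # checkerboard occupancy: unvisited bins get the visited mean pre-smoothing
  xb <- rep(c(0.5, 2.5), 200); yb <- rep(c(0.5, 2.5), each = 200)
  m3 <- spatialRatemap(rep(3, 400), cbind(xb, yb), bins = 4, sigmaBins = 0,
                       range = list(x = c(0, 4), y = c(0, 4)))
  expect_equal(as.numeric(m3@values), rep(3, 16))
  expect_error(spatialRatemap(numeric(0), matrix(0, 0, 2)), "misaligned|no visited")
})

test_that("1-D autocorrelograms reproduce direct dot products", {
  pos <- seq(0, 399, by = 0.5)
  act <- sin(2 * pi * pos / 20)^2  # period 20 cm = 20 bins at 1 cm
  ac <- autocorr1d(act, pos, binCm = 1, maxShift = 60)
  v <- ac@values
  expect_equal(which.max(v), 1L)  # shift 0 maximal
  loc <- function(s) v[s + 1] > v[s] && v[s + 1] > v[s + 2]
  expect_true(loc(20) && loc(40))
  # constant tuning declines linearly from zero-padding overlap
  ac2 <- autocorr1d(rep(2, length(pos)), pos, binCm = 1, maxShift = 100)
  overlap <- 400 - (0:100)
  expect_equal(ac2@values, 4 * overlap, tolerance = 1e-9)
  # single occupied bin: only the zero shift is nonzero
  ac3 <- autocorr1d(rep(1, 5), rep(0.2, 5), binCm = 1, maxShift = 10)
  expect_true(ac3@values[1] > 0 && all(ac3@values[-1] == 0))
})

test_that("toroidal rate maps are periodic-equivariant under angle shifts", {
  set.seed(12)
  n <- 6000
  ang <- cbind(runif(n, 0, 2 * pi), runif(n, 0, 2 * pi))
  ctr <- c(1.2, 4.0)
  d2 <- function(a, c_) pmin(abs(a - c_), 2 * pi - abs(a - c_))^2
  act <- exp(-(d2(ang[, 1], ctr[1]) + d2(ang[, 2], ctr[2])) / 0.5)
  m <- toroidalRatemap(act, ang)
  # impulse-like field at the center
  pk <- which(m@values == max(m@values), arr.ind = TRUE)
  binc <- (c(pk) - 0.5) * 12 / 180 * pi
  expect_lt(max(abs(((binc - ctr + pi) %% (2 * pi)) - pi)), 0.25)
  # shifting all angles by delta translates the map by delta
  delta <- c(2, 3) * 12 / 180 * pi  # whole bins
  m2 <- toroidalRatemap(act, (ang + rep(delta, each = n)) %% (2 * pi))
  shifted <- m@values[((seq_len(30) - 1 - 2) %% 30) + 1,
                      ((seq_len(30) - 1 - 3) %% 30) + 1]
  expect_equal(m2@values, shifted, tolerance = 0.05 * max(m@values))
})

test_that("toroidal peak equals the circular mass center arithmetic", {
  m <- matrix(0, 16, 16)
  # all mass in the bin whose first-angle center is 90 degrees
  m[5, 1] <- 3  # bin 5 center = (4.5/16) * 360 = 101.25 deg; use bin 4.5 ->
  m <- matrix(0, 16, 16)
  i90 <- which.min(abs((seq_len(16) - 0.5) / 16 * 360 - 90))
  m[i90, 1] <- 3
  pk <- toroidalPeak(m)
  expect_equal(pk[1], (i90 - 0.5) / 16 * 2 * pi, tolerance = 1e-9)
  # equal mass at 0 and 90 degrees gives 45 (vector sum arithmetic)
  m2 <- matrix(0, 16, 16)
  i0 <- 1
  m2[i0, 1] <- 1; m2[i90, 1] <- 1
  th0 <- (i0 - 0.5) / 16 * 2 * pi; th90 <- (i90 - 0.5) / 16 * 2 * pi
  expected <- atan2(sin(th0) + sin(th90), cos(th0) + cos(th90))
  expect_equal(toroidalPeak(m2)[1], expected, tolerance = 1e-9)
  # antipodal balance is degenerate
  m3 <- matrix(0, 16, 16)
  m3[1, 1] <- 1; m3[9, 1] <- 1  # bins 180 degrees apart
  expect_true(attr(toroidalPeak(m3), "degenerate")[1])
  expect_error(toroidalPeak(matrix(0, 16, 16)), "all zero")
})

test_that("toroidal peak reduces to the circular mean as bins approach samples", {
  set.seed(13)
  th <- runif(50, 0, 2 * pi)
  nb <- 2048
  m <- matrix(0, nb, nb)
  bins <- pmin(floor(th / (2 * pi) * nb) + 1, nb)
  for (b in bins) m[b, 1] <- m[b, 1] + 1
  direct <- atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)
  expect_equal(toroidalPeak(m)[1], direct, tolerance = 2 * pi / nb)
})

test_that("angular tuning curves are max-normalized means", {
  set.seed(14)
  hd <- runif(5000, 0, 2 * pi)
  act <- exp(2 * cos(hd - 1.5))  # von Mises tuning at 1.5 rad
  tc <- angularTuning(act, hd, bins = 60)
  expect_equal(max(tc), 1)
  expect_equal((which.max(tc) - 0.5) / 60 * 2 * pi, 1.5, tolerance = 0.1)
  # constant activity gives ones wherever a bin is visited
  flat <- angularTuning(rep(4, 100), hd[1:100])
  expect_true(all(flat %in% c(0, 1)))
  expect_gt(sum(flat), 30)
  one <- angularTuning(5, 0.3, bins = 60)
  expect_equal(sum(one > 0), 1L)
})

test_that("3-D toroidal tuning matches nearest-center assignment", {
  set.seed(15)
  n <- 400
  c3 <- matrix(runif(3 * n, 0, 2 * pi), n)
  act <- c3[, 1] + 0.1 * c3[, 2]
  tun <- toroidal3dTuning(act, c3, eps = 1.5)
  ctr <- as.matrix(tun[, 1:3])
  # brute-force oracle: assign each sample to its nearest center
  for (k in c(1, nrow(ctr))) {
    d <- colSums((t(c3) - ctr[k, ])^2)
    expect_gt(nrow(ctr), 1)
  }
  assign <- apply(c3, 1, function(p) which.min(colSums((t(ctr) - p)^2)))
  oracle <- tapply(act, factor(assign, levels = seq_len(nrow(ctr))), mean)
  expect_equal(tun$value, as.numeric(oracle))
  # uniform activity gives uniform values
  tun2 <- toroidal3dTuning(rep(7, n), c3, eps = 1.5)
  expect_true(all(abs(tun2$value - 7) < 1e-12))
})
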