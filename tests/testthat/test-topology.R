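test_that("canonical clouds yield their known barcodes", {
  # 20 evenly spaced circle points: exactly one long H1 bar, empty H2
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  bc <- computePersistence(PointCloud(cbind(cos(th), sin(th))),
                           maxdim = 2, metric = "euclidean")
  b <- barsOf(bc)
  h1 <- b[b$dim == 1, ]
  expect_equal(nrow(h1), 1L)
  expect_gt(h1$lifetime, 1)
  expect_equal(sum(b$dim == 2), 0L)
  # single point: one infinite H0 bar only
  b1 <- barsOf(computePersistence(PointCloud(matrix(0, 1, 2)), maxdim = 1,
                                  metric = "euclidean"))
  expect_equal(nrow(b1), 1L)
  expect_identical(b1$dim, 0L)
  expect_identical(b1$death, Inf)
})

test_that("a flat-torus lattice has the (1, 2, 1) longest-bar signature", {
  n <- 8
  u <- (seq_len(n) - 1) / n * 2 * pi
  g <- expand.grid(a = u, b = u)
  P <- cbind(cos(g$a), sin(g$a), cos(g$b), sin(g$b))
  bc <- computePersistence(PointCloud(P), maxdim = 2, metric = "euclidean")
  b <- barsOf(bc)
  lt <- function(d) sort(b$lifetime[b$dim == d & is.finite(b$death)],
                         decreasing = TRUE)
  # two dominant H1 bars, clearly separated from the rest
  h1 <- lt(1)
  expect_gt(h1[2], 3 * h1[3])
  # one dominant H2 bar
  h2 <- lt(2)
  expect_gt(h2[1], 3 * h2[2])
  # one infinite H0 component
  expect_equal(sum(b$dim == 0 & !is.finite(b$death)), 1L)
})

test_that("barcodes agree with brute-force boundary reduction", {
  set.seed(25)
  clouds <- list(
    cbind(cos(seq(0, 2 * pi, length.out = 13)[-13]),
          sin(seq(0, 2 * pi, length.out = 13)[-13])),
    matrix(rnorm(60), 20),
    matrix(runif(72), 18))
  for (P in clouds) {
    D <- as.matrix(dist(P))
    oracle <- bruteForcePersistence(D, maxdim = 2)
    got <- barsOf(computePersistence(D, maxdim = 2))
    got <- got[got$lifetime > 0, c("dim", "birth", "death")]
    got <- got[order(got$dim, got$birth, got$death), ]
    rownames(oracle) <- rownames(got) <- NULL
    expect_equal(got$dim, oracle$dim)
    expect_equal(got$birth, oracle$birth, tolerance = 1e-5)
    expect_equal(got$death, oracle$death, tolerance = 1e-5)
  }
})

test_that("field choice does not alter torsion-free barcodes", {
  n <- 6
  u <- (seq_len(n) - 1) / n * 2 * pi
  g <- expand.grid(a = u, b = u)
  P <- cbind(cos(g$a), sin(g$a), cos(g$b), sin(g$b))
  b47 <- barsOf(computePersistence(PointCloud(P), maxdim = 2,
                                   metric = "euclidean", modulus = 47L))
  b2 <- barsOf(computePersistence(PointCloud(P), maxdim = 2,
                                  metric = "euclidean", modulus = 2L))
  expect_equal(b47$dim, b2$dim)
  expect_equal(b47$birth, b2$birth, tolerance = 1e-6)
  expect_equal(b47$death, b2$death, tolerance = 1e-6)
})

test_that("cosine distances are a valid dissimilarity and permutation-stable", {
  set.seed(26)
  P <- matrix(rnorm(120), 30)
  D <- cosineDistance(P)
  expect_true(all(D >= 0 & D <= 2 + 1e-12))
  expect_equal(D, t(D))
  perm <- sample(30)
  b1 <- barsOf(computePersistence(PointCloud(P), maxdim = 1))
  b2 <- barsOf(computePersistence(PointCloud(P[perm, ]), maxdim = 1))
  o1 <- b1[order(b1$dim, b1$birth, b1$death), ]
  o2 <- b2[order(b2$dim, b2$birth, b2$death), ]
  expect_equal(o1$birth, o2$birth, tolerance = 1e-6)
  expect_equal(o1$death, o2$death, tolerance = 1e-6)
})

test_that("shuffle null is deterministic and bounded by construction", {
  set.seed(27)
  v <- matrix(rexp(30 * 400), 30)
  r <- RateMatrix(sqrt(v), dt = 0.02, transform = "sqrt")
  prof <- parameterProfile(d = 4L, eps = 0.3, kappa = 40L, m = 100L)
  th1 <- shuffleNull(r, prof, nShuffles = 2, seed = 9, maxdim = 1)
  th2 <- shuffleNull(r, prof, nShuffles = 2, seed = 9, maxdim = 1)
  expect_identical(th1, th2)
  expect_true(all(th1 >= 0))
  # a single shuffle's threshold equals that shuffle's maximum lifetime
  th3 <- shuffleNull(r, prof, nShuffles = 1, seed = 11, maxdim = 1)
  expect_equal(length(th3), 2L)
  expect_error(shuffleNull(r, prof, nShuffles = 0), "at least 1")
})

test_that("significant-bar counting needs thresholds and sorts by construction", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  bc <- computePersistence(PointCloud(cbind(cos(th), sin(th))), maxdim = 1,
                           metric = "euclidean")
  expect_error(countSignificantBars(bc, 1), "threshold")
  bc <- setShuffleThresholds(bc, c("0" = 0.5, "1" = 0.5))
  expect_equal(countSignificantBars(bc, 1), 1L)
  expect_equal(countSignificantBars(bc, 0), 1L)  # the infinite component
  # empty dimension counts zero
  bc2 <- setShuffleThresholds(bc, c("0" = 0.5, "1" = 0.5, "2" = 0.1))
  expect_equal(countSignificantBars(bc2, 2), 0L)
})
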