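# Independent oracles used to freeze expected values. These deliberately use
# naive, direct formulations (full boundary-matrix reduction, quadratic-time
# greedy selection, explicit lattice sums) so they share no code with the
# package implementations they check.

# Brute-force persistent homology over Z2 by full boundary-matrix reduction.
bruteForcePersistence <- function(D, maxdim = 1, threshold = NULL) {
  n <- nrow(D)
  if (is.null(threshold)) threshold <- min(apply(D, 1, max))
  simplices <- list()
  for (d in 0:(maxdim + 1)) {
    combs <- utils::combn(n, d + 1)
    for (c_ in seq_len(ncol(combs))) {
      vs <- combs[, c_]
      diam <- if (d == 0) 0 else max(D[vs, vs][upper.tri(diag(d + 1))])
      if (diam <= threshold)
        simplices[[length(simplices) + 1]] <-
          list(vs = vs, dim = d, diam = diam)
    }
  }
  keys <- vapply(simplices, function(s) s$diam, numeric(1))
  dims <- vapply(simplices, function(s) s$dim, numeric(1))
  lex <- vapply(simplices, function(s)
    paste(sprintf("%03d", s$vs), collapse = ""), character(1))
  ord <- order(keys, dims, lex)
  simplices <- simplices[ord]
  ns <- length(simplices)
  skey <- vapply(simplices, function(s)
    paste(s$dim, paste(s$vs, collapse = ","), sep = ":"), character(1))
  pos <- seq_len(ns)
  names(pos) <- skey
  cols <- vector("list", ns)
  for (i in seq_len(ns)) {
    s <- simplices[[i]]
    if (s$dim == 0) {
      cols[[i]] <- integer(0)
      next
    }
    faces <- vapply(seq_along(s$vs), function(k)
      paste(s$dim - 1, paste(s$vs[-k], collapse = ","), sep = ":"),
      character(1))
    cols[[i]] <- sort(unname(pos[faces]))
  }
  low_of <- integer(ns)
  pairs <- list()
  for (j in seq_len(ns)) {
    col <- cols[[j]]
    while (length(col)) {
      low <- col[length(col)]
      if (low_of[low] == 0) break
      other <- cols[[low_of[low]]]
      col <- sort(c(setdiff(col, other), setdiff(other, col)))
    }
    cols[[j]] <- col
    if (length(col)) {
      low_of[col[length(col)]] <- j
      pairs[[length(pairs) + 1]] <- c(col[length(col)], j)
    }
  }
  bars <- data.frame(dim = integer(0), birth = numeric(0), death = numeric(0))
  births <- vapply(pairs, `[`, numeric(1), 1)
  deaths <- vapply(pairs, `[`, numeric(1), 2)
  for (k in seq_along(pairs)) {
    b <- simplices[[births[k]]]
    d_ <- simplices[[deaths[k]]]
    if (d_$diam > b$diam)
      bars <- rbind(bars,
                    data.frame(dim = b$dim, birth = b$diam, death = d_$diam))
  }
  for (i in setdiff(seq_len(ns), c(births, deaths))) {
    s <- simplices[[i]]
    if (s$dim <= maxdim)
      bars <- rbind(bars,
                    data.frame(dim = s$dim, birth = s$diam, death = Inf))
  }
  bars[order(bars$dim, bars$birth, bars$death), ]
}

# Direct greedy implementation of the fuzzy downsampling equations: explicit
# sigma solve by dense uniroot, full membership matrix, quadratic re-summation
# of F_n at every iteration.
bruteForceFuzzySelect <- function(P, kappa, m) {
  n <- nrow(P)
  D <- as.matrix(dist(P))
  target <- log2(kappa)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    dk <- sort(D[i, -i])[seq_len(kappa)]
    f <- function(s) sum(exp(-dk / s)) - target
    sigma[i] <- uniroot(f, c(1e-10, 1e6), tol = 1e-12)$root
  }
  mu_dir <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbrs <- order(D[i, ] + ifelse(seq_len(n) == i, Inf, 0))[seq_len(kappa)]
    mu_dir[i, nbrs] <- exp(-D[i, nbrs] / sigma[i])
  }
  mu <- mu_dir + t(mu_dir) - mu_dir * t(mu_dir)
  chosen <- integer(0)
  for (k in seq_len(m)) {
    resid <- setdiff(seq_len(n), chosen)
    fn <- vapply(resid, function(x)
      sum(mu[x, ]) - sum(mu[x, chosen]), numeric(1))
    chosen <- c(chosen, resid[which.max(fn)])
  }
  list(order = chosen, sigma = sigma, mu = mu)
}

# Hand-rolled greedy radial downsampling (order of selected indices).
bruteForceRadialSelect <- function(P, eps) {
  n <- nrow(P)
  D <- as.matrix(dist(P))
  sel <- which.max(rowSums(abs(P)))
  alive <- setdiff(which(apply(D[, sel, drop = FALSE], 1, min) >= eps), sel)
  while (length(alive)) {
    mind <- apply(D[alive, sel, drop = FALSE], 1, min)
    nxt <- alive[which.max(mind)]
    sel <- c(sel, nxt)
    alive <- alive[D[alive, nxt] >= eps & alive != nxt]
  }
  sel
}

# Explicit 9-term lattice sums of the torus heat kernels.
bruteForceHeatKernel <- function(x, y, t, variant) {
  s <- 0
  for (k in -1:1) for (l in -1:1) {
    u <- k + x
    v <- l + y
    Q <- if (variant == "hex") (2 / sqrt(3)) * (u^2 + u * v + v^2)
         else u^2 + v^2
    s <- s + exp(-pi * Q / t)
  }
  s / t
}

# Standard rotational-autocorrelation scores: Pearson correlation of the
# spatial autocorrelogram with itself rotated on an annulus.
#   grid score   = min(corr at 60, 120) - max(corr at 30, 90, 150)
#   square score = corr at 90 - max(corr at 45, 135)
.rotationalCorrelations <- function(ratemap, degs) {
  m <- ratemap - mean(ratemap)
  n <- nrow(m)
  ac <- matrix(0, 2 * n - 1, 2 * n - 1)
  for (dx in -(n - 1):(n - 1)) for (dy in -(n - 1):(n - 1)) {
    xs <- max(1, 1 + dx):min(n, n + dx)
    ys <- max(1, 1 + dy):min(n, n + dy)
    if (length(xs) < 2 || length(ys) < 2) next
    a <- m[xs, ys]
    b <- m[xs - dx, ys - dy]
    ac[dx + n, dy + n] <- sum(a * b) / (length(a))
  }
  ctr <- n
  rmax <- n - 1
  rot_cor <- function(deg) {
    th <- deg * pi / 180
    xs <- rep(-(rmax):rmax, times = 2 * rmax + 1)
    ys <- rep(-(rmax):rmax, each = 2 * rmax + 1)
    r <- sqrt(xs^2 + ys^2)
    keep <- r > rmax * 0.15 & r < rmax * 0.95
    xr <- xs * cos(th) - ys * sin(th)
    yr <- xs * sin(th) + ys * cos(th)
    xi <- round(xr) + ctr
    yi <- round(yr) + ctr
    ok <- keep & xi >= 1 & xi <= 2 * n - 1 & yi >= 1 & yi <= 2 * n - 1
    a <- ac[cbind(xs[ok] + ctr, ys[ok] + ctr)]
    b <- ac[cbind(xi[ok], yi[ok])]
    suppressWarnings(cor(a, b))
  }
  vapply(degs, rot_cor, numeric(1))
}

gridScore <- function(ratemap) {
  rc <- .rotationalCorrelations(ratemap, c(30, 60, 90, 120, 150))
  min(rc[2], rc[4]) - max(rc[1], rc[3], rc[5])
}

squareScore <- function(ratemap) {
  rc <- .rotationalCorrelations(ratemap, c(45, 90, 135))
  rc[2] - max(rc[1], rc[3])
}
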