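# Independent oracles and fixture generators used across the suite.
# These deliberately use naive loops / direct formulas, not the package's
# code paths.

# Random single-component blobby 2D mask: a base disc with satellite
# discs merged on, largest component kept, holes filled.
makeBlobbyMask <- function(seed, n = 90) {
  set.seed(seed)
  ctr <- c(n, n) / 2
  r0 <- runif(1, n * 0.22, n * 0.33)
  X <- row(matrix(0, n, n))
  Y <- col(matrix(0, n, n))
  m <- (X - ctr[1])^2 + (Y - ctr[2])^2 <= r0^2
  for (i in seq_len(sample(3:6, 1))) {
    ang <- runif(1, 0, 2 * pi)
    off <- ctr + runif(1, 0.5, 1) * r0 * c(cos(ang), sin(ang))
    rr <- runif(1, n * 0.08, n * 0.2)
    m <- m | ((X - off[1])^2 + (Y - off[2])^2 <= rr^2)
  }
  lab <- EBImage::bwlabel(m * 1)
  m <- lab == which.max(tabulate(lab[lab > 0]))
  EBImage::fillHull(m * 1) > 0
}

# Brute-force per-label pixel counts via an explicit loop.
oracleShellCounts <- function(labels, nShells) {
  counts <- numeric(nShells)
  for (v in as.integer(labels)) if (v > 0) counts[v] <- counts[v] + 1
  counts
}

# Brute-force per-label intensity sums via an explicit loop.
oracleShellSums <- function(channel, labels, nShells) {
  sums <- numeric(nShells)
  lab <- as.integer(labels)
  ch <- as.numeric(channel)
  for (i in seq_along(lab)) if (lab[i] > 0)
    sums[lab[i]] <- sums[lab[i]] + ch[i]
  sums
}

# Exhaustive minimum distance (micron) from `point` to the centre of any
# boundary element of `mask`: every foreground element is tested for a
# background face-neighbour (array edges count as background) one by one.
oracleEdgeDistance <- function(point, mask, spacing) {
  d <- dim(mask)
  nd <- length(d)
  fg <- which(mask)
  pos <- arrayInd(fg, d)
  best <- Inf
  for (r in seq_len(nrow(pos))) {
    p <- pos[r, ]
    isBoundary <- FALSE
    for (ax in seq_len(nd)) {
      for (s in c(-1L, 1L)) {
        q <- p
        q[ax] <- q[ax] + s
        if (q[ax] < 1L || q[ax] > d[ax] ||
            !mask[matrix(q, 1)]) { isBoundary <- TRUE; break }
      }
      if (isBoundary) break
    }
    if (isBoundary) {
      dist <- sqrt(sum(((p - 0.5) * spacing - point)^2))
      if (dist < best) best <- dist
    }
  }
  best
}

# Random digitized ellipsoid mask with anisotropic spacing.
makeEllipsoidMask <- function(seed, spacing = c(0.2, 0.2, 0.4)) {
  set.seed(seed)
  axes <- runif(3, 1.5, 3)
  d <- ceiling(2 * (axes + 0.5) / spacing)
  ctr <- d * spacing / 2
  xs <- (seq_len(d[1]) - 0.5) * spacing[1]
  ys <- (seq_len(d[2]) - 0.5) * spacing[2]
  zs <- (seq_len(d[3]) - 0.5) * spacing[3]
  m <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    zq <- ((zs[k] - ctr[3]) / axes[3])^2
    m[, , k] <- outer(((xs - ctr[1]) / axes[1])^2,
                      ((ys - ctr[2]) / axes[2])^2, `+`) + zq <= 1
  }
  list(mask = m, spacing = spacing, centre = ctr, axes = axes)
}

# Two-sided permutation p-value for the difference between two samples,
# using a hand-computed Welch statistic (independent of stats::t.test).
manualWelchT <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- (colSums(xa^2) - na * ma^2) / (na - 1)
  vb <- (colSums(xb^2) - nb * mb^2) / (nb - 1)
  (ma - mb) / sqrt(va / na + vb / nb)
}

permutationWelchP <- function(a, b, B, seed = 1) {
  set.seed(seed)
  na <- length(a)
  pool <- c(a, b)
  tobs <- manualWelchT(matrix(a), matrix(b))
  perm <- replicate(B, sample(pool))
  tperm <- manualWelchT(perm[seq_len(na), , drop = FALSE],
                        perm[-seq_len(na), , drop = FALSE])
  mean(abs(tperm) >= abs(tobs) - 1e-12)
}

# Streaming (Welford) mean and SEM, one value at a time.
streamingMeanSEM <- function(x) {
  n <- 0; mean <- 0; m2 <- 0
  for (v in x) {
    n <- n + 1
    delta <- v - mean
    mean <- mean + delta / n
    m2 <- m2 + delta * (v - mean)
  }
  c(mean = mean, sem = sqrt(m2 / (n - 1)) / sqrt(n))
}

# Radial fraction of a point realized on an emitted mask: distance from
# the mask centroid towards the point, divided by the boundary distance
# found by marching along the same ray in quarter-pixel steps.
realizedRadialFraction <- function(point, mask, spacing) {
  d <- dim(mask)
  pos <- arrayInd(which(mask), d)
  ctr <- (colMeans(pos) - 0.5) * spacing
  v <- point - ctr
  len <- sqrt(sum(v^2))
  dir <- v / len
  step <- min(spacing) / 4
  t <- 0
  repeat {
    q <- ctr + (t + step) * dir
    idx <- pmin(pmax(ceiling(q / spacing), 1L), d)
    if (!mask[matrix(idx, 1)]) break
    t <- t + step
  }
  len / t
}
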