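# Shared fixtures (built once per test run) and independent brute-force
# oracles used to cross-check the optimized implementations.

.fixtures <- new.env(parent = emptyenv())

# Coarse (2 mm) phantom spec: fast enough for unit tests.
coarseSpec <- function(seed = 1L)
  phantomSpec(spacing = c(2, 2, 2), gridShape = c(80L, 104L, 86L),
              rngSeed = as.integer(seed))

coarsePhantom <- function() {
  if (is.null(.fixtures$ph)) .fixtures$ph <- generatePhantom(coarseSpec())
  .fixtures$ph
}

coarseSegmentation <- function() {
  if (is.null(.fixtures$seg))
    .fixtures$seg <- segmentAll(coarsePhantom()$ct)
  .fixtures$seg
}

# Full-resolution 70-case database index, shared by the retrieval and
# end-to-end acceptance checks.
dbIndex70 <- function() {
  if (is.null(.fixtures$idx70))
    .fixtures$idx70 <- generateDatabaseIndex(phantomSpec(), 70)
  .fixtures$idx70
}

# Small solid-cube mask centered in a grid.
cubeMask <- function(side, shape = rep(side + 4L, 3), spacing = c(1, 1, 1),
                     corner = rep(3L, 3)) {
  a <- array(FALSE, shape)
  a[corner[1]:(corner[1] + side - 1), corner[2]:(corner[2] + side - 1),
    corner[3]:(corner[3] + side - 1)] <- TRUE
  binaryMask(a, spacing)
}

# Rasterized sphere mask.
sphereMask <- function(r, spacing = 1, pad = 3) {
  n <- 2 * ceiling(r / spacing) + 2 * pad + 1
  xs <- (seq_len(n) - (n + 1) / 2) * spacing
  a <- array(FALSE, c(n, n, n))
  for (k in seq_len(n))
    a[, , k] <- outer(xs^2, xs^2, "+") + xs[k]^2 <= r^2
  binaryMask(a, rep(spacing, 3))
}

# Random blob mask with <= maxBoundary boundary voxels (seeded).
randomBlobMask <- function(seed, shape = c(14L, 14L, 14L)) {
  withr::with_seed(seed, {
    a <- array(FALSE, shape)
    ctr <- runif(3, 5, shape - 4)
    r <- runif(1, 2, 4.5)
    idx <- which(array(TRUE, shape), arr.ind = TRUE)
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 +
      (idx[, 3] - ctr[3])^2
    a[d2 <= r^2] <- TRUE
    extra <- sample(which(!a & d2 <= (r + 1.5)^2),
                    size = min(20, sum(!a & d2 <= (r + 1.5)^2)))
    a[extra] <- TRUE
    binaryMask(a, c(1, 1, 1))
  })
}

# ---- independent O(n^2) oracles (plain R, no package kernels) ----

# All pairwise distances between two point matrices.
bfPairwise <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    out[i, ] <- sqrt((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2 +
                       (a[i, 3] - b[, 3])^2)
  out
}

# Boundary voxel centers by direct 6-neighbour scan in R.
bfBoundaryPoints <- function(m) {
  d <- dim(m@mask)
  idx <- which(m@mask, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    outside <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
      nb[, 3] < 1 | nb[, 3] > d[3]
    keep[r] <- any(outside) ||
      any(!m@mask[nb[!outside, , drop = FALSE]])
  }
  pts <- idx[keep, , drop = FALSE]
  sweep(sweep(pts - 1, 2, m@spacing, "*"), 2, m@origin, "+")
}

# Brute-force surface distances (symmetrized mean + Hausdorff).
bfSurfaceDistances <- function(a, b) {
  pa <- bfBoundaryPoints(a)
  pb <- bfBoundaryPoints(b)
  dm <- bfPairwise(pa, pb)
  dab <- apply(dm, 1, min)
  dba <- apply(dm, 2, min)
  list(mean_mm = mean(c(dab, dba)), hausdorff_mm = max(dab, dba))
}

bfDice <- function(a, b) {
  2 * sum(a@mask & b@mask) / (sum(a@mask) + sum(b@mask))
}

# Sparse planar grid cloud where nearest neighbours stay in
# correspondence under small shifts (spacing >> shift).
gridCloud <- function(gridSpacing = 10, extent = 90) {
  g <- as.matrix(expand.grid(x = seq(0, extent, gridSpacing),
                             y = seq(0, extent, gridSpacing), z = 0))
  surfaceCloud(g)
}
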