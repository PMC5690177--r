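test_that("mask surfaces are boundary voxel centers with decimation", {
  cube <- cubeMask(3)
  s <- maskToSurface(cube)
  expect_equal(nrow(cloudPoints(s)), 26)
  # sphere: all surface points close to the nominal radius
  sph <- sphereMask(10, spacing = 1)
  pts <- cloudPoints(maskToSurface(sph, maxPoints = 10000L))
  r <- sqrt(rowSums(pts^2))
  expect_true(all(r >= 9 - 1e-9 & r <= 11 + 1e-9))
  # decimation: exact count, deterministic under the seed
  d1 <- maskToSurface(sph, maxPoints = 10L, seed = 7L)
  d2 <- maskToSurface(sph, maxPoints = 10L, seed = 7L)
  expect_equal(nrow(cloudPoints(d1)), 10)
  expect_identical(cloudPoints(d1), cloudPoints(d2))
  empty <- binaryMask(array(FALSE, c(5, 5, 5)), c(1, 1, 1))
  expect_error(maskToSurface(empty), "empty")
})

test_that("the crop plane keeps the brain-eye region", {
  ph <- coarsePhantom()
  # plane pushed far along its normal (superior-posterior): nothing
  # is on the discard side, so the full surfaces come back
  far <- cropPlane(c(0, -400, 400), tiltDeg = 15)
  full <- cropForMatching(ph$masks, plane = far,
                          maxPoints = c(brain = 1e6, eye = 1e6))
  nBrainFull <- sum(full@label == "brain")
  expect_equal(nBrainFull,
               sum(maskArray(boundaryMask(ph$masks$brain))))
  # plane through the brain centroid: strictly fewer brain points
  mid <- cropPlane(maskCentroid(ph$masks$brain), tiltDeg = 0)
  crop <- cropForMatching(ph$masks, plane = mid,
                          maxPoints = c(brain = 1e6, eye = 1e6))
  expect_lt(sum(crop@label == "brain"), nBrainFull)
  # every retained brain point satisfies the plane inequality
  kept <- cloudPoints(crop)[crop@label == "brain", ]
  side <- sweep(kept, 2, mid@point) %*% mid@normal
  expect_true(all(side <= 1e-9))
  # eye surfaces are always kept in full (up to decimation)
  expect_gt(sum(crop@label == "eye_L"), 100)
  # a plane discarding everything errors
  below <- cropPlane(c(0, 400, -400), tiltDeg = 15)
  expect_error(cropForMatching(ph$masks, plane = below), "discards")
})

test_that("default crop plane passes the superior pole of the eyes", {
  ph <- coarsePhantom()
  cloud <- cropForMatching(ph$masks)
  zTop <- max(cloudPoints(cloud)[cloud@label %in% c("eye_L", "eye_R"), 3])
  kept <- cloudPoints(cloud)[cloud@label == "brain", ]
  # no retained brain point lies above the eye pole by more than the
  # tilt allows at its y position
  pl <- cropPlane(c(0, maskCentroid(ph$masks$eye_L)[2], zTop), 15)
  expect_true(all(sweep(kept, 2, pl@point) %*% pl@normal <= 1e-6))
})

test_that("translations-only ICP recovers synthetic offsets", {
  ph <- coarsePhantom()
  cloud <- cropForMatching(ph$masks)
  # identity
  expect_equal(as.numeric(icpAlign(cloud, cloud)), c(0, 0, 0),
               tolerance = 1e-9)
  withr::with_seed(31, {
    for (i in 1:10) {
      tr <- runif(3, -30, 30)
      moved <- surfaceCloud(sweep(cloudPoints(cloud), 2, tr, "+"))
      rec <- icpAlign(moved, cloud)
      expect_lt(max(abs(as.numeric(rec) + tr)), 0.5)
    }
  })
  # two points each: exact centroid-difference solution in one iteration
  a <- surfaceCloud(rbind(c(0, 0, 0), c(10, 0, 0)))
  b <- surfaceCloud(rbind(c(3, 4, 5), c(13, 4, 5)))
  tr <- icpAlign(a, b)
  expect_equal(as.numeric(tr), c(3, 4, 5))
  expect_lte(attr(tr, "iterations"), 2L)
  expect_error(icpAlign(surfaceCloud(matrix(numeric(0), 0, 3)), b),
               "nonempty")
})

test_that("the match score is direction-selective and RMS-weighted", {
  g <- gridCloud()
  # self match
  expect_equal(as.numeric(matchScore(g, g)), 0)
  # pure x-offset between plates with normal x: ignored entirely
  pl <- surfaceCloud(as.matrix(expand.grid(x = 0, y = seq(0, 50, 5),
                                           z = seq(0, 50, 5))))
  plx <- surfaceCloud(sweep(cloudPoints(pl), 2, c(25, 0, 0), "+"))
  expect_equal(as.numeric(matchScore(plx, pl, align = FALSE)), 0)
  expect_equal(as.numeric(matchScore(plx, pl, align = TRUE)), 0)
  # uniform 2 mm vs localized 7 mm: RMS ranks them opposite to the mean
  base <- cloudPoints(g)
  unif <- surfaceCloud(base + cbind(0, 0, rep(2, nrow(base))))
  dz <- rep(1, nrow(base)); dz[seq_len(nrow(base) / 10)] <- 7
  loc <- surfaceCloud(base + cbind(0, 0, dz))
  sUnif <- as.numeric(matchScore(unif, g, align = FALSE))
  sLoc <- as.numeric(matchScore(loc, g, align = FALSE))
  expect_equal(sUnif, 2)
  expect_equal(sLoc, sqrt(0.1 * 49 + 0.9 * 1))
  expect_gt(sLoc, sUnif)
  # a plain mean-distance metric would rank them the other way
  expect_lt(0.1 * 7 + 0.9 * 1, 2)
  expect_error(matchScore(surfaceCloud(matrix(numeric(0), 0, 3)), g),
               "nonempty")
})

test_that("squared penalty makes the score increase with variance", {
  g <- gridCloud()
  base <- cloudPoints(g)
  n <- nrow(base)
  # same mean |z| residual (2 mm), increasing variance
  mk <- function(hi, frac) {
    lo <- (2 - frac * hi) / (1 - frac)
    dz <- rep(lo, n)
    dz[seq_len(round(frac * n))] <- hi
    surfaceCloud(base + cbind(0, 0, dz))
  }
  s1 <- as.numeric(matchScore(mk(2, 0.1), g, align = FALSE))   # uniform
  s2 <- as.numeric(matchScore(mk(4, 0.1), g, align = FALSE))
  s3 <- as.numeric(matchScore(mk(6, 0.1), g, align = FALSE))
  expect_lt(s1, s2)
  expect_lt(s2, s3)
})

test_that("nearest-neighbour lookup equals brute force", {
  withr::with_seed(17, {
    q <- matrix(runif(300, -40, 40), ncol = 3)
    r <- matrix(runif(450, -40, 40), ncol = 3)
  })
  idx <- wbrt:::cpp_nn_index(q, r)
  dm <- bfPairwise(q, r)
  expect_equal(idx, apply(dm, 1, which.min))
})

test_that("database ranking: planted query, ties, monotonicity", {
  spec <- coarseSpec()
  idx <- generateDatabaseIndex(spec, 6)
  q <- cropForMatching(databaseCase(spec, 4)$masks)
  rk <- rankDatabase(q, idx)
  expect_equal(rk$case_id[1], "case_004")
  expect_equal(rk$score[1], 0)
  expect_equal(nrow(rk), 6)
  expect_true(!is.unsorted(rk$score))
  # retrieved plan is the planted case's plan
  expect_equal(attr(rk, "bestPlan")@patientID, "DB004")
  # ties broken by case id: duplicate one cloud under two ids
  dup <- list(cases = list(
    list(id = "case_b", cloud = q, plan = idx$cases[[1]]$plan),
    list(id = "case_a", cloud = q, plan = idx$cases[[1]]$plan)),
    params = idx$params)
  rk2 <- rankDatabase(q, dup)
  expect_equal(rk2$case_id, c("case_a", "case_b"))
  # supersets never worsen the best score
  best <- vapply(c(2, 4, 6), function(n)
    min(rankDatabase(q, list(cases = idx$cases[1:n],
                             params = idx$params))$score), 0)
  expect_true(all(diff(best) <= 1e-12))
  expect_error(rankDatabase(q, list(cases = list(), params = idx$params)),
               "empty")
})

test_that("the index survives the manifest round trip", {
  spec <- coarseSpec()
  idx <- generateDatabaseIndex(spec, 2)
  dir <- withr::local_tempdir()
  # manifests reference plan files
  for (i in 1:2) {
    writePlan(idx$cases[[i]]$plan, file.path(dir, paste0("p", i, ".json")))
    idx$cases[[i]]$planPath <- file.path(dir, paste0("p", i, ".json"))
  }
  mp <- file.path(dir, "manifest.json")
  writeDatabaseIndex(idx, mp)
  idx2 <- readDatabaseIndex(mp)
  expect_equal(length(idx2$cases), 2)
  expect_equal(cloudPoints(idx2$cases[[1]]$cloud),
               cloudPoints(idx$cases[[1]]$cloud), ignore_attr = TRUE)
  q <- cropForMatching(databaseCase(spec, 1)$masks)
  rk <- rankDatabase(q, idx2)
  expect_equal(rk$case_id[1], "case_001")
  expect_equal(rk$score[1], 0)
})
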