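test_that("soft-tissue windowing is exact", {
  ph <- coarsePhantom()
  spec <- coarseSpec()
  soft <- softTissueMask(ph$ct)
  hu <- voxels(ph$ct)
  expect_identical(maskArray(soft), hu >= -200 & hu <= 200)
  # excludes skull and air by construction
  expect_false(any(maskArray(soft) & hu == spec@huValues[["skull"]]))
  expect_false(any(maskArray(soft) & hu == spec@huValues[["air"]]))
  # uniform soft volume: all-true mask
  expect_true(all(maskArray(softTissueMask(ctVolume(array(0, c(6, 6, 6)))))))
  # degenerate input
  expect_error(softTissueMask(ctVolume(array(-1000, c(6, 6, 6)))),
               "degenerate")
})

test_that("soft-tissue voxel count matches the analytic anatomy", {
  ph <- coarsePhantom()
  spec <- coarseSpec()
  soft <- maskVolume(softTissueMask(ph$ct))
  vol <- function(semi) 4 / 3 * pi * prod(semi)
  orbit <- 2 * (4 / 3 * pi) * ((spec@eyeRadius + spec@orbitThickness)^3 -
                                 spec@eyeRadius^3)
  analytic <- vol(spec@headSemiaxes) -
    (vol(spec@brainSemiaxes + spec@skullThickness) -
       vol(spec@brainSemiaxes)) - orbit
  expect_lt(abs(soft - analytic) / analytic, 0.03)
})

test_that("largest-component rule picks the bigger of two blobs", {
  v <- array(-1000, c(40, 20, 20))
  v[3:12, 3:12, 3:12] <- 30    # 1000 voxels
  v[25:29, 8:12, 8:12] <- 30   # 125 voxels
  ct <- ctVolume(v, c(1, 1, 1))
  brain <- segmentBrain(ct, segmentationParams(edgeStrategy = "none",
                                               erosionRadius = 1,
                                               closingRadius = 1))
  got <- which(maskArray(brain), arr.ind = TRUE)
  expect_true(all(got[, 1] <= 13))
  expect_gte(sum(maskArray(brain)), 729)  # the large blob (opened)
})

test_that("brain segmentation excludes eyes by severing muscle bridges", {
  ph <- coarsePhantom()
  seg <- coarseSegmentation()
  brain <- segStructures(seg, "brain")
  expect_false(any(maskArray(brain) & maskArray(ph$masks$eye_L)))
  expect_false(any(maskArray(brain) & maskArray(ph$masks$eye_R)))
  expect_gte(dice(brain, ph$masks$brain), 0.95)
  # single connected component
  expect_equal(max(labelComponents(brain)), 1L)
})

test_that("eyes are recovered as the two roundest components", {
  ph <- coarsePhantom()
  seg <- coarseSegmentation()
  expect_gte(dice(segStructures(seg, "eye_L"), ph$masks$eye_L), 0.85)
  expect_gte(dice(segStructures(seg, "eye_R"), ph$masks$eye_R), 0.85)
  # left/right assignment by x: +x is patient left
  expect_gt(maskCentroid(segStructures(seg, "eye_L"))[1],
            maskCentroid(segStructures(seg, "eye_R"))[1])
})

test_that("lens segmentation finds the bright patch in each eye", {
  ph <- coarsePhantom()
  seg <- coarseSegmentation()
  expect_gte(dice(segStructures(seg, "lens_L"), ph$masks$lens_L), 0.6)
  expect_gte(dice(segStructures(seg, "lens_R"), ph$masks$lens_R), 0.6)
})

test_that("roundness ranks shapes correctly and has closed forms", {
  sphere <- sphereMask(10, spacing = 1)
  slabArr <- array(FALSE, c(20, 20, 20))
  slabArr[, , 3] <- TRUE  # 1-voxel-thick slab
  slab <- binaryMask(slabArr, c(1, 1, 1))
  # equal-ish volume thin slab ranks far below the sphere
  expect_gt(roundness(sphere), roundness(slab))
  expect_lt(roundness(slab, "face"), 0.5)
  # single voxel under face counting: closed form for a cube
  one <- binaryMask(array(TRUE, c(1, 1, 1)), c(1, 1, 1))
  expect_equal(roundness(one, "face"), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-9)
  # well-resolved sphere approaches 1 under the gradient estimator
  expect_gte(roundness(sphereMask(12, spacing = 0.5)), 0.9)
  expect_error(roundness(binaryMask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))),
               "empty")
})

test_that("a missing eye is reported, not silently mis-segmented", {
  ph <- coarsePhantom()
  spec <- coarseSpec()
  v <- voxels(ph$ct)
  v[maskArray(ph$masks$eye_R)] <- spec@huValues[["skull"]]
  ct <- ctVolume(v, gridSpacing(ph$ct), gridOrigin(ph$ct))
  brain <- segmentBrain(ct)
  expect_error(segmentEyes(ct, brain), "fewer than two")
})

test_that("an eye without a lens yields an empty mask plus warning", {
  ph <- coarsePhantom()
  spec <- coarseSpec()
  v <- voxels(ph$ct)
  v[maskArray(ph$masks$lens_L)] <- spec@huValues[["eye"]]
  v[maskArray(ph$masks$lens_R)] <- spec@huValues[["eye"]]
  ct <- ctVolume(v, gridSpacing(ph$ct), gridOrigin(ph$ct))
  eyes <- list(eye_L = ph$masks$eye_L, eye_R = ph$masks$eye_R)
  w <- capture_warnings(lenses <- segmentLenses(ct, eyes))
  expect_length(w, 2)
  expect_match(w, "no lens-bright", all = TRUE)
  expect_equal(sum(maskArray(lenses$lens_L)), 0)
  expect_equal(sum(maskArray(lenses$lens_R)), 0)
})

test_that("the larger of two bright patches is kept as the lens", {
  # synthetic eye VOI: uniform vitreous with two bright patches
  v <- array(-1000, c(30, 30, 30))
  v[4:27, 4:27, 4:27] <- 25
  v[8:12, 8:12, 8:12] <- 110   # 125 voxels
  v[20:21, 20:21, 20:22] <- 110  # 12 voxels
  ct <- ctVolume(v, c(1, 1, 1))
  eye <- binaryMask(v > -1000, c(1, 1, 1), gridOrigin(ct))
  lenses <- segmentLenses(ct, list(eye_L = eye, eye_R = eye))
  got <- which(maskArray(lenses$lens_L), arr.ind = TRUE)
  expect_true(all(got[, 1] <= 13))
  expect_gte(sum(maskArray(lenses$lens_L)), 100)
})

test_that("the full segmentation is deterministic and complete", {
  ph <- coarsePhantom()
  seg1 <- coarseSegmentation()
  seg2 <- segmentAll(ph$ct)
  for (nm in names(segStructures(seg1))) {
    expect_gt(sum(maskArray(segStructures(seg1, nm))), 0)
    expect_identical(maskArray(segStructures(seg1, nm)),
                     maskArray(segStructures(seg2, nm)))
  }
  expect_named(seg1@diagnostics, c("brain", "eyes"))
})

test_that("erosion/dilation pairing barely moves the brain Dice", {
  # without bridges, the opening in the brain chain is near-identity
  spec <- coarseSpec()
  spec@bridgeRadius <- 0
  ph <- generatePhantom(spec)
  d1 <- dice(segmentBrain(ph$ct, segmentationParams(erosionRadius = 2)),
             ph$masks$brain)
  d2 <- dice(segmentBrain(ph$ct, segmentationParams(erosionRadius = 4)),
             ph$masks$brain)
  expect_lt(abs(d1 - d2), 0.02)
})

test_that("brain recovery is accurate on the clean phantom", {
  ph <- coarsePhantom()
  seg <- coarseSegmentation()
  sd <- surfaceDistances(segStructures(seg, "brain"), ph$masks$brain)
  expect_lt(sd$hausdorff_mm, 10)
})
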