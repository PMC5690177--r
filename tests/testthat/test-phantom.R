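test_that("ground-truth masks match analytic solid volumes", {
  ph <- coarsePhantom()
  spec <- coarseSpec()
  eyeAnalytic <- 4 / 3 * pi * spec@eyeRadius^3
  expect_lt(abs(maskVolume(ph$masks$eye_L) - eyeAnalytic) / eyeAnalytic, 0.03)
  expect_lt(abs(maskVolume(ph$masks$eye_R) - eyeAnalytic) / eyeAnalytic, 0.03)
  brainAnalytic <- 4 / 3 * pi * prod(spec@brainSemiaxes)
  expect_lt(abs(maskVolume(ph$masks$brain) - brainAnalytic) / brainAnalytic,
            0.03)
  lensAnalytic <- 4 / 3 * pi * prod(spec@lensSemiaxes)
  # small structure: voxelization error scales with surface/volume
  expect_lt(abs(maskVolume(ph$masks$lens_L) - lensAnalytic) / lensAnalytic,
            0.35)
})

test_that("phantom generation is deterministic", {
  spec <- coarseSpec(seed = 11L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(voxels(a$ct), voxels(b$ct))
  expect_identical(maskArray(a$masks$brain), maskArray(b$masks$brain))
  # and with noise enabled, still deterministic under the spec seed
  specN <- phantomSpec(spacing = c(2, 2, 2), gridShape = c(80L, 104L, 86L),
                       noiseSd = 10, rngSeed = 11L)
  expect_identical(voxels(generatePhantom(specN)$ct),
                   voxels(generatePhantom(specN)$ct))
})

test_that("lens is the brightest tissue inside the eye", {
  ph <- coarsePhantom()
  spec <- coarseSpec()
  huInEye <- voxels(ph$ct)[maskArray(ph$masks$eye_L)]
  expect_equal(max(huInEye), spec@huValues[["lens"]])
  huLens <- voxels(ph$ct)[maskArray(ph$masks$lens_L)]
  expect_true(all(huLens == spec@huValues[["lens"]]))
})

test_that("structural containment invariants hold", {
  ph <- coarsePhantom()
  m <- ph$masks
  expect_false(any(maskArray(m$eye_L) & maskArray(m$brain)))
  expect_false(any(maskArray(m$eye_R) & maskArray(m$brain)))
  expect_true(all(!maskArray(m$lens_L) | maskArray(m$eye_L)))
  expect_true(all(!maskArray(m$lens_R) | maskArray(m$eye_R)))
  expect_true(all(!maskArray(m$eye_L) | maskArray(m$external)))
  expect_true(all(!maskArray(m$brain) | maskArray(m$external)))
  expect_false(any(maskArray(m$eye_L) & maskArray(m$eye_R)))
})

test_that("illegal specs are rejected", {
  # eye pushed into the brain
  bad <- coarseSpec()
  bad@eyeCenterOffsets <- rbind(c(10, 20, 0), c(-10, 20, 0))
  expect_error(generatePhantom(bad), "overlaps the brain")
  # grid too small for the head
  expect_error(phantomSpec(gridShape = c(40L, 40L, 40L)),
               "grid too small")
  # HU conventions enforced
  expect_error(phantomSpec(huValues = c(air = -1000, scalp = 40,
                                        skull = 100, brain = 35, eye = 25,
                                        lens = 110, muscle = 50)),
               "skull")
  expect_error(phantomSpec(huValues = c(air = -1000, scalp = 40,
                                        skull = 700, brain = 35, eye = 120,
                                        lens = 110, muscle = 50)),
               "lens")
})

test_that("zero jitter yields identical database anatomies", {
  spec <- coarseSpec()
  spec@jitter[] <- 0
  db <- generateDatabase(spec, 3)
  expect_length(db, 3L)
  expect_identical(voxels(db[[1]]$ct), voxels(db[[2]]$ct))
  expect_identical(voxels(db[[2]]$ct), voxels(db[[3]]$ct))
  expect_identical(maskArray(db[[1]]$masks$eye_L),
                   maskArray(db[[3]]$masks$eye_L))
  # metadata still unique per case
  expect_false(db[[1]]$plan@patientID == db[[2]]$plan@patientID)
})

test_that("jittered cases differ within the stated bounds", {
  spec <- coarseSpec()
  db <- generateDatabase(spec, 2)
  c1 <- maskCentroid(db[[1]]$masks$eye_L)
  c2 <- maskCentroid(db[[2]]$masks$eye_L)
  delta <- abs(c1 - c2)
  expect_gt(max(delta), 0)
  bound <- spec@jitter[["couch"]] + spec@jitter[["eye_center"]] +
    max(spec@spacing)  # half-voxel rasterization slack per side
  expect_true(all(delta <= bound))
})

test_that("degenerate database sizes are rejected", {
  expect_error(generateDatabase(coarseSpec(), 0), "nCases")
  expect_error(generateDatabaseIndex(coarseSpec(), 0), "nCases")
})

test_that("database plans carry lateral opposed beams at the isocenter", {
  cs <- databaseCase(coarseSpec(), 1)
  beams <- planBeams(cs$plan)
  expect_length(beams, 2L)
  expect_setequal(vapply(beams, `[[`, 0, "gantry_angle_deg"), c(90, 270))
  iso <- planIsocenter(cs$plan)
  ctr <- maskCentroid(cs$masks$brain)
  expect_equal(iso, ctr, tolerance = 1e-8)
})
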