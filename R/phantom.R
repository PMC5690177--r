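# Synthetic CT head phantoms with ground-truth masks and template plans.
# Anatomy is ellipsoid/sphere based: scalp/face soft tissue, an ellipsoidal
# skull shell, the brain filling the skull cavity, spherical eye globes
# sealed in bony orbit shells, ellipsoidal lenses, and optional thin
# muscle-like soft-tissue bridges connecting the eyes to the brain through
# the orbit (the connections the segmentation's erosion step must sever).

#' PhantomSpec: parameters of the synthetic head phantom
#'
#' All lengths in mm; HU values must respect the soft-tissue window
#' assumptions: air < -200, scalp/brain/eye/muscle within [-200, 200],
#' skull > 200, lens brighter than eye.
#'
#' @slot gridShape integer(3), voxels per axis.
#' @slot spacing numeric(3), voxel size mm.
#' @slot headSemiaxes numeric(3), outer head ellipsoid semiaxes.
#' @slot skullThickness numeric(1), skull shell thickness.
#' @slot brainSemiaxes numeric(3), brain ellipsoid semiaxes.
#' @slot brainCenter numeric(3), brain center relative to head center.
#' @slot eyeRadius numeric(1), eye globe radius.
#' @slot eyeCenterOffsets 2 x 3 matrix, eye centers (rows L, R) relative to
#'   head center.
#' @slot lensSemiaxes numeric(3), lens semiaxes (y = visual axis).
#' @slot orbitThickness numeric(1), bony orbit shell thickness around each
#'   eye (isolates the globe from facial soft tissue).
#' @slot bridgeRadius numeric(1), radius of the extraocular-muscle-like
#'   soft-tissue bridges between eyes and brain; 0 disables them.
#' @slot huValues named numeric: air, scalp, skull, brain, eye, lens, muscle.
#' @slot noiseSd numeric(1), additive Gaussian HU noise (0 = none).
#' @slot rngSeed integer(1).
#' @slot jitter named numeric, uniform perturbation half-widths used by
#'   [generateDatabase()]: head_semiaxes, brain_semiaxes, brain_center,
#'   eye_center, eye_radius (mm, per axis) and couch (whole-patient
#'   translation).
#' @seealso [phantomSpec()], [generatePhantom()], [generateDatabase()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
    headSemiaxes = "numeric", skullThickness = "numeric",
    brainSemiaxes = "numeric", brainCenter = "numeric",
    eyeRadius = "numeric", eyeCenterOffsets = "matrix",
    lensSemiaxes = "numeric", orbitThickness = "numeric",
    bridgeRadius = "numeric", huValues = "numeric", noiseSd = "numeric",
    rngSeed = "integer", jitter = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  hu <- object@huValues
  need <- c("air", "scalp", "skull", "brain", "eye", "lens", "muscle")
  if (!all(need %in% names(hu)))
    msg <- c(msg, paste("huValues must name", paste(need, collapse = ", ")))
  else {
    soft <- hu[c("scalp", "brain", "eye", "muscle")]
    if (any(soft < -200 | soft > 200))
      msg <- c(msg, "scalp/brain/eye/muscle HU must lie in [-200, 200]")
    if (hu["skull"] <= 200) msg <- c(msg, "skull HU must exceed 200")
    if (hu["air"] >= -200) msg <- c(msg, "air HU must be below -200")
    if (hu["lens"] <= hu["eye"])
      msg <- c(msg, "lens HU must exceed eye HU")
    if (hu["lens"] > 200 | hu["lens"] < -200)
      msg <- c(msg, "lens HU must lie in [-200, 200]")
  }
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape must be 3 values >= 8")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  if (!identical(dim(object@eyeCenterOffsets), c(2L, 3L)))
    msg <- c(msg, "eyeCenterOffsets must be a 2 x 3 matrix (rows L, R)")
  if (object@eyeRadius <= 0) msg <- c(msg, "eyeRadius must be positive")
  if (object@skullThickness <= 0)
    msg <- c(msg, "skullThickness must be positive")
  half <- (object@gridShape - 1) / 2 * object@spacing
  if (any(object@headSemiaxes >= half))
    msg <- c(msg, "grid too small to contain the head ellipsoid")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults describe an adult head at 1 mm isotropic resolution: a
#' 140 x 190 x 156 mm head ellipsoid, a 6 mm skull shell around a
#' 124 x 140 x 120 mm brain, 12 mm radius eye globes sealed in 3 mm bony
#' orbits, 9 x 5 x 9 mm lenses, and 1.5 mm radius muscle bridges from each
#' eye to the brain. HU values follow the soft-tissue window convention
#' (air -1000, scalp 40, skull 700, brain 35, eye 25, lens 110).
#'
#' @param gridShape integer(3) voxels per axis.
#' @param spacing numeric(3) voxel size mm.
#' @param headSemiaxes,skullThickness,brainSemiaxes,brainCenter head geometry.
#' @param eyeRadius,eyeCenterOffsets,lensSemiaxes eye/lens geometry.
#' @param orbitThickness,bridgeRadius orbit shell and muscle-bridge sizes.
#' @param huValues named numeric of tissue HU values.
#' @param noiseSd additive Gaussian HU noise standard deviation.
#' @param rngSeed integer seed.
#' @param jitter named numeric of database perturbation half-widths (mm).
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(spacing = c(2, 2, 2), gridShape = c(80, 104, 86))
#' ph <- generatePhantom(spec)
#' names(ph$masks)
#' @export
phantomSpec <- function(gridShape = c(156L, 206L, 170L),
                        spacing = c(1, 1, 1),
                        headSemiaxes = c(70, 95, 78),
                        skullThickness = 6,
                        brainSemiaxes = c(62, 68, 60),
                        brainCenter = c(0, -14, 8),
                        eyeRadius = 12,
                        eyeCenterOffsets = rbind(L = c(30, 62, -20),
                                                 R = c(-30, 62, -20)),
                        lensSemiaxes = c(4.5, 2.5, 4.5),
                        orbitThickness = 3,
                        bridgeRadius = 1.5,
                        huValues = c(air = -1000, scalp = 40, skull = 700,
                                     brain = 35, eye = 25, lens = 110,
                                     muscle = 50),
                        noiseSd = 0,
                        rngSeed = 1L,
                        jitter = c(head_semiaxes = 2, brain_semiaxes = 1.5,
                                   brain_center = 1.5, eye_center = 1.5,
                                   eye_radius = 0.75, couch = 15)) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), headSemiaxes = as.numeric(headSemiaxes),
      skullThickness = as.numeric(skullThickness),
      brainSemiaxes = as.numeric(brainSemiaxes),
      brainCenter = as.numeric(brainCenter),
      eyeRadius = as.numeric(eyeRadius),
      eyeCenterOffsets = eyeCenterOffsets,
      lensSemiaxes = as.numeric(lensSemiaxes),
      orbitThickness = as.numeric(orbitThickness),
      bridgeRadius = as.numeric(bridgeRadius),
      huValues = huValues, noiseSd = as.numeric(noiseSd),
      rngSeed = as.integer(rngSeed), jitter = jitter)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: grid %s @ %s mm, head (%s) mm,\n",
                     "  brain (%s) mm, eyes r=%g mm, seed %d\n"),
              paste(object@gridShape, collapse = "x"),
              paste(format(object@spacing, digits = 3), collapse = "x"),
              paste(object@headSemiaxes, collapse = ", "),
              paste(object@brainSemiaxes, collapse = ", "),
              object@eyeRadius, object@rngSeed))
})

# ---- rasterizers (voxel centers, bbox-limited) ----

subRange <- function(coords, lo, hi) {
  i <- which(coords >= lo & coords <= hi)
  if (length(i) == 0L) integer(0) else seq(min(i), max(i))
}

emptyGrid <- function(shape) array(FALSE, shape)

# Ellipsoid solid: ((p - c) / a)^2 summed <= 1, evaluated at voxel centers
# inside the bounding box only.
rasterEllipsoid <- function(coords, center, semi, shape) {
  out <- emptyGrid(shape)
  ix <- subRange(coords[[1]], center[1] - semi[1], center[1] + semi[1])
  iy <- subRange(coords[[2]], center[2] - semi[2], center[2] + semi[2])
  iz <- subRange(coords[[3]], center[3] - semi[3], center[3] + semi[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(out)
  ax <- ((coords[[1]][ix] - center[1]) / semi[1])^2
  ay <- ((coords[[2]][iy] - center[2]) / semi[2])^2
  az <- ((coords[[3]][iz] - center[3]) / semi[3])^2
  out[ix, iy, iz] <- outer(outer(ax, ay, "+"), az, "+") <= 1
  out
}

rasterSphere <- function(coords, center, r, shape)
  rasterEllipsoid(coords, center, rep(r, 3), shape)

# Solid cylinder around the segment p0-p1.
rasterCylinder <- function(coords, p0, p1, radius, shape) {
  out <- emptyGrid(shape)
  lo <- pmin(p0, p1) - radius
  hi <- pmax(p0, p1) + radius
  ix <- subRange(coords[[1]], lo[1], hi[1])
  iy <- subRange(coords[[2]], lo[2], hi[2])
  iz <- subRange(coords[[3]], lo[3], hi[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(out)
  g <- expand.grid(x = coords[[1]][ix], y = coords[[2]][iy],
                   z = coords[[3]][iz])
  u <- p1 - p0
  len2 <- sum(u^2)
  w <- cbind(g$x - p0[1], g$y - p0[2], g$z - p0[3])
  t <- pmin(pmax((w %*% u) / len2, 0), 1)
  d2 <- rowSums((w - t %*% t(u))^2)
  out[ix, iy, iz] <- array(d2 <= radius^2, c(length(ix), length(iy),
                                             length(iz)))
  out
}

# ---- generation ----

#' Generate a synthetic head phantom
#'
#' Rasterizes the phantom anatomy onto the spec's grid and returns the CT
#' volume together with the exact ground-truth masks of every structure.
#' Deterministic for a given spec (noise, if enabled, uses the spec seed).
#'
#' @param spec a [PhantomSpec-class].
#' @param originShift numeric(3), extra world translation applied to the
#'   grid origin (simulates couch position; voxel content is unchanged).
#' @return List with elements \code{ct} (a [CTVolume-class]) and
#'   \code{masks} (named list of [BinaryMask-class]: external, brain,
#'   eye_L, eye_R, lens_L, lens_R).
#' @examples
#' ph <- generatePhantom(phantomSpec(spacing = c(2, 2, 2),
#'                                   gridShape = c(80, 104, 86)))
#' ph$ct
#' @export
generatePhantom <- function(spec, originShift = c(0, 0, 0)) {
  validObject(spec)
  shape <- spec@gridShape
  origin <- -(shape - 1) / 2 * spec@spacing
  coords <- lapply(1:3, function(a)
    origin[a] + (seq_len(shape[a]) - 1) * spec@spacing[a])
  hu <- spec@huValues

  head <- rasterEllipsoid(coords, c(0, 0, 0), spec@headSemiaxes, shape)
  skullOuter <- rasterEllipsoid(coords, spec@brainCenter,
                                spec@brainSemiaxes + spec@skullThickness,
                                shape)
  brain <- rasterEllipsoid(coords, spec@brainCenter, spec@brainSemiaxes,
                           shape)
  eyeL <- rasterSphere(coords, spec@eyeCenterOffsets[1, ], spec@eyeRadius,
                       shape)
  eyeR <- rasterSphere(coords, spec@eyeCenterOffsets[2, ], spec@eyeRadius,
                       shape)
  lensOff <- c(0, spec@eyeRadius - spec@lensSemiaxes[2] - 2.5, 0)
  lensL <- rasterEllipsoid(coords, spec@eyeCenterOffsets[1, ] + lensOff,
                           spec@lensSemiaxes, shape)
  lensR <- rasterEllipsoid(coords, spec@eyeCenterOffsets[2, ] + lensOff,
                           spec@lensSemiaxes, shape)

  # structural legality
  if (any(eyeL & brain) || any(eyeR & brain))
    stop("illegal phantom: an eye overlaps the brain", call. = FALSE)
  if (any(eyeL & !head) || any(eyeR & !head))
    stop("illegal phantom: an eye extends outside the head", call. = FALSE)
  if (any(lensL & !eyeL) || any(lensR & !eyeR))
    stop("illegal phantom: a lens extends outside its eye", call. = FALSE)
  if (any(eyeL & eyeR))
    stop("illegal phantom: the eyes overlap", call. = FALSE)
  if (any(brain & !head))
    stop("illegal phantom: brain extends outside the head", call. = FALSE)

  vol <- array(hu[["air"]], shape)
  vol[head] <- hu[["scalp"]]
  vol[skullOuter & !brain & head] <- hu[["skull"]]
  vol[brain] <- hu[["brain"]]
  for (side in 1:2) {
    eye <- if (side == 1) eyeL else eyeR
    ec <- spec@eyeCenterOffsets[side, ]
    orbit <- rasterSphere(coords, ec, spec@eyeRadius + spec@orbitThickness,
                          shape) & !eye & head & !brain
    vol[orbit] <- hu[["skull"]]
    if (spec@bridgeRadius > 0) {
      u <- spec@brainCenter - ec
      u <- u / sqrt(sum(u^2))
      # end the bridge just inside the brain surface along the eye-brain line
      tIn <- ellipsoidRayEntry(ec, u, spec@brainCenter, spec@brainSemiaxes)
      p1 <- ec + u * (tIn + 4)
      bridge <- rasterCylinder(coords, ec, p1, spec@bridgeRadius, shape) &
        head & !brain
      vol[bridge] <- hu[["muscle"]]
    }
  }
  vol[eyeL | eyeR] <- hu[["eye"]]
  vol[lensL | lensR] <- hu[["lens"]]

  if (spec@noiseSd > 0)
    vol <- vol + withSeed(spec@rngSeed,
                          array(stats::rnorm(length(vol), 0, spec@noiseSd),
                                shape))

  origin <- origin + originShift
  ct <- ctVolume(vol, spec@spacing, origin)
  mk <- function(a) binaryMask(a, spec@spacing, origin)
  list(ct = ct,
       masks = list(external = mk(head), brain = mk(brain),
                    eye_L = mk(eyeL), eye_R = mk(eyeR),
                    lens_L = mk(lensL), lens_R = mk(lensR)))
}

# Distance t along direction u from point p at which the ray enters the
# ellipsoid (center c, semiaxes a). Assumes p is outside and the ray hits.
ellipsoidRayEntry <- function(p, u, c, a) {
  pn <- (p - c) / a
  un <- u / a
  A <- sum(un^2); B <- 2 * sum(pn * un); C <- sum(pn^2) - 1
  disc <- B^2 - 4 * A * C
  if (disc < 0) stop("bridge axis misses the brain", call. = FALSE)
  (-B - sqrt(disc)) / (2 * A)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a database of jittered phantom cases with template plans
#'
#' Each case perturbs the head, brain and eye geometry by independent
#' uniform jitter (half-widths from \code{spec@jitter}), applies a random
#' couch translation, and attaches a synthetic whole-brain plan: two
#' lateral opposed beams (gantry 90/270), isocenter at the brain centroid,
#' rectangular placeholder MLC apertures and unique patient metadata.
#' Case i is seeded with \code{spec@rngSeed + i}, so the database is fully
#' reproducible.
#'
#' @param spec a [PhantomSpec-class]; jitter half-widths taken from it.
#' @param nCases number of cases (>= 1).
#' @return List of cases, each a list with \code{id}, \code{ct},
#'   \code{masks} and \code{plan} (a [PlanTemplate-class]).
#' @examples
#' spec <- phantomSpec(spacing = c(2, 2, 2), gridShape = c(80, 104, 86))
#' db <- generateDatabase(spec, 2)
#' db[[1]]$plan
#' @export
generateDatabase <- function(spec, nCases) {
  validObject(spec)
  if (!is.numeric(nCases) || nCases < 1)
    stop("nCases must be >= 1", call. = FALSE)
  lapply(seq_len(as.integer(nCases)), function(i) databaseCase(spec, i))
}

#' Generate a single database case
#'
#' Case \code{i} of the database [generateDatabase()] would produce
#' (deterministic, so individual cases can be regenerated without
#' materializing the whole database).
#'
#' @param spec a [PhantomSpec-class].
#' @param i case number (>= 1).
#' @return A case list with \code{id}, \code{ct}, \code{masks},
#'   \code{plan}.
#' @export
databaseCase <- function(spec, i) {
  i <- as.integer(i)
  stopifnot(i >= 1L)
  spi <- jitterSpec(spec, spec@rngSeed + i)
  couch <- withSeed(spec@rngSeed + i + 500000L,
                    stats::runif(3, -spec@jitter[["couch"]],
                                 spec@jitter[["couch"]]))
  ph <- generatePhantom(spi, originShift = couch)
  iso <- maskCentroid(ph$masks$brain)
  plan <- makeTemplatePlan(sprintf("CASE_%03d", i), sprintf("DB%03d", i),
                           iso, seedUID = spec@rngSeed + i)
  list(id = sprintf("case_%03d", i), ct = ph$ct, masks = ph$masks,
       plan = plan)
}

jitterSpec <- function(spec, seed) {
  j <- spec@jitter
  withSeed(seed, {
    u <- function(m, n = 3) stats::runif(n, -m, m)
    sp <- spec
    sp@headSemiaxes <- spec@headSemiaxes + u(j[["head_semiaxes"]])
    sp@brainSemiaxes <- spec@brainSemiaxes + u(j[["brain_semiaxes"]])
    sp@brainCenter <- spec@brainCenter + u(j[["brain_center"]])
    sp@eyeCenterOffsets <- spec@eyeCenterOffsets +
      rbind(u(j[["eye_center"]]), u(j[["eye_center"]]))
    sp@eyeRadius <- spec@eyeRadius + u(j[["eye_radius"]], 1)
    sp@rngSeed <- as.integer(seed)
    sp
  })
}

# Two lateral opposed open beams with placeholder rectangular MLC.
makeTemplatePlan <- function(name, id, iso, seedUID = NULL) {
  mlcBoundaries <- seq(-100, 100, by = 5)
  nPairs <- length(mlcBoundaries) - 1L
  beam <- function(num, gantry) {
    list(beam_number = num, beam_name = sprintf("LAT %d", gantry),
         gantry_angle_deg = gantry, collimator_angle_deg = 0,
         couch_angle_deg = 0,
         jaws_mm = list(x1 = -90, x2 = 90, y1 = -75, y2 = 75),
         mlc = list(leaf_boundaries_mm = mlcBoundaries,
                    bank_a_mm = rep(-85, nPairs),
                    bank_b_mm = rep(85, nPairs)),
         monitor_units = 250)
  }
  uid <- if (is.null(seedUID)) freshUID() else withSeed(seedUID, freshUID())
  planTemplate(patientName = name, patientID = id, isocenter = iso,
               beams = list(beam(1L, 90), beam(2L, 270)),
               planLabel = "WBRT_TEMPLATE", sopInstanceUID = uid,
               extra = list(approval = "APPROVED", machine = "LINAC1"))
}
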