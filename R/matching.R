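# Anatomy-similarity search: surface extraction, nape-to-forehead
# cropping, translations-only ICP, and the direction-selective RMS score
# that ranks database cases. The score pools every point of the cropped
# brain and both eye surfaces, takes each point's full-3D nearest
# neighbour in the database cloud, and accumulates only the y
# (anterior-posterior) and z (superior-inferior) residual components --
# the ones perpendicular to the lateral beams -- squared, so large local
# discrepancies are penalized over uniform small ones:
#   score = sqrt( (1/N) sum_i (dy_i^2 + dz_i^2) ).

#' Sample a mask boundary as a surface cloud
#'
#' Boundary voxel centers in world mm, uniformly decimated to at most
#' \code{maxPoints} with a seeded sampler (deterministic).
#'
#' @param mask a nonempty [BinaryMask-class].
#' @param maxPoints maximum number of points kept.
#' @param label structure label attached to the points.
#' @param seed decimation seed.
#' @return A [SurfaceCloud-class].
#' @export
maskToSurface <- function(mask, maxPoints = 2000L, label = "surface",
                          seed = 42L) {
  if (!any(mask@mask)) stop("empty mask has no surface", call. = FALSE)
  pts <- worldCoords(mask, boundaryMask(mask)@mask)
  n <- nrow(pts)
  if (n > maxPoints) {
    keep <- sort(withSeed(seed, sample.int(n, maxPoints)))
    pts <- pts[keep, , drop = FALSE]
  }
  surfaceCloud(pts, label)
}

#' Crop a segmentation for matching
#'
#' Returns the brain surface points on the eye side of the cropping plane
#' plus the full surfaces of both eyes. The default plane passes through
#' the superior pole of the eye globes with its normal tilted
#' \code{tiltDeg} degrees from +z towards -y ("from the nape toward the
#' forehead"), so posterior and superior brain surface -- irradiated by
#' the open field -- is discarded and only anatomy near the MLC-shaped
#' brain-eye interface is scored.
#'
#' @param structures a [SegmentationResult-class] or named list of
#'   [BinaryMask-class] with brain, eye_L, eye_R.
#' @param plane a [CropPlane-class]; built from the eyes when NULL.
#' @param tiltDeg tilt for the default plane, degrees.
#' @param maxPoints named numeric: points kept per structure.
#' @param seed decimation seed.
#' @return A [SurfaceCloud-class] with labels brain, eye_L, eye_R.
#' @export
cropForMatching <- function(structures, plane = NULL, tiltDeg = 15,
                            maxPoints = c(brain = 1200, eye = 400),
                            seed = 42L) {
  if (is(structures, "SegmentationResult")) structures <- structures@structures
  need <- c("brain", "eye_L", "eye_R")
  if (!all(need %in% names(structures)))
    stop("matching needs brain, eye_L and eye_R", call. = FALSE)
  if (is.null(plane)) plane <- defaultCropPlane(structures, tiltDeg)
  brainCloud <- maskToSurface(structures$brain, maxPoints[["brain"]],
                              "brain", seed)
  keep <- planeSide(brainCloud@points, plane) <= 1e-9
  if (!any(keep))
    stop("cropping plane discards all brain points", call. = FALSE)
  eyeL <- maskToSurface(structures$eye_L, maxPoints[["eye"]], "eye_L", seed)
  eyeR <- maskToSurface(structures$eye_R, maxPoints[["eye"]], "eye_R", seed)
  surfaceCloud(rbind(brainCloud@points[keep, , drop = FALSE],
                     eyeL@points, eyeR@points),
               c(rep("brain", sum(keep)),
                 eyeL@label, eyeR@label))
}

# Signed side of each point: > 0 lies on the discarded
# (posterior-superior) side of the plane.
planeSide <- function(pts, plane) {
  sweep(pts, 2, plane@point) %*% plane@normal
}

# Default plane: through the superior pole of the eye globes (mean eye
# centroid y, max eye surface z), tilted towards the forehead.
defaultCropPlane <- function(structures, tiltDeg) {
  cL <- maskCentroid(structures$eye_L)
  cR <- maskCentroid(structures$eye_R)
  zTop <- max(worldCoords(structures$eye_L,
                          structures$eye_L@mask)[, 3],
              worldCoords(structures$eye_R,
                          structures$eye_R@mask)[, 3])
  cropPlane(c(0, mean(c(cL[2], cR[2])), zTop), tiltDeg)
}

#' Translations-only iterative closest point alignment
#'
#' Initialized at the centroid difference, then alternates full-3D
#' nearest-neighbour assignment with a translation update by the mean
#' residual, until the update falls below \code{tolMm} or \code{maxIter}
#' is reached. No rotation or scaling.
#'
#' @param moving,fixed [SurfaceCloud-class] objects (or n x 3 matrices).
#' @param maxIter maximum iterations.
#' @param tolMm convergence tolerance on the translation update (mm).
#' @return numeric(3) translation (mm) that maps moving onto fixed, with
#'   attribute \code{iterations}.
#' @export
icpAlign <- function(moving, fixed, maxIter = 100L, tolMm = 1e-3) {
  mp <- if (is(moving, "SurfaceCloud")) moving@points else as.matrix(moving)
  fp <- if (is(fixed, "SurfaceCloud")) fixed@points else as.matrix(fixed)
  if (nrow(mp) == 0L || nrow(fp) == 0L)
    stop("ICP needs two nonempty clouds", call. = FALSE)
  if (!all(is.finite(mp)) || !all(is.finite(fp)))
    stop("ICP requires finite coordinates", call. = FALSE)
  tr <- colMeans(fp) - colMeans(mp)
  it <- 0L
  for (i in seq_len(maxIter)) {
    it <- i
    moved <- sweep(mp, 2, tr, "+")
    idx <- cpp_nn_index(moved, fp)
    upd <- colMeans(fp[idx, , drop = FALSE] - moved)
    tr <- tr + upd
    if (max(abs(upd)) < tolMm) break
  }
  tr <- as.numeric(tr)
  names(tr) <- c("x", "y", "z")
  attr(tr, "iterations") <- it
  tr
}

#' Direction-selective match score between two surface clouds
#'
#' Aligns the patient cloud to the database cloud with [icpAlign()] (when
#' \code{align = TRUE}), then for every patient point finds its full-3D
#' nearest neighbour in the database cloud and accumulates the squared y
#' and z residual components only; the x (left-right, along-beam)
#' component is discarded. Returns the root mean square, in mm; squared
#' residuals make a localized large discrepancy score worse than a
#' uniform small one of equal mean.
#'
#' @param patient,dbCase [SurfaceCloud-class] objects (patient = new
#'   case; the sum runs over its points).
#' @param align run ICP first (set FALSE if the clouds are already
#'   aligned).
#' @param maxIter,tolMm ICP controls.
#' @return Score in mm with attributes \code{translation} (the ICP
#'   result) and \code{nPoints}.
#' @examples
#' pts <- cbind(runif(200, -50, 50), runif(200, -50, 50), runif(200, -50, 50))
#' a <- surfaceCloud(pts)
#' matchScore(a, a)  # 0
#' @export
matchScore <- function(patient, dbCase, align = TRUE, maxIter = 100L,
                       tolMm = 1e-3) {
  pp <- patient@points
  dp <- dbCase@points
  if (nrow(pp) == 0L || nrow(dp) == 0L)
    stop("match score needs two nonempty clouds", call. = FALSE)
  tr <- if (align) icpAlign(patient, dbCase, maxIter, tolMm) else c(0, 0, 0)
  moved <- sweep(pp, 2, tr, "+")
  idx <- cpp_nn_index(moved, dp)
  res <- moved - dp[idx, , drop = FALSE]
  score <- sqrt(mean(res[, 2]^2 + res[, 3]^2))
  attr(score, "translation") <- as.numeric(tr)
  attr(score, "nPoints") <- nrow(pp)
  score
}

# ---- database index ----

#' Build a database index from cases
#'
#' Precomputes the cropped surface cloud of every case; CT data are never
#' stored (the matcher works on structure sets only). Cases are in-memory
#' lists (from [generateDatabase()]) or directories written by
#' [writeCaseDir()].
#'
#' @param cases list of cases, each with \code{id}, \code{masks} and
#'   \code{plan} (or \code{planPath}).
#' @param tiltDeg,maxPoints,seed cropping controls, see
#'   [cropForMatching()].
#' @return A database index: list with \code{cases} (each holding id,
#'   cloud, plan or planPath) and the cropping parameters.
#' @export
buildDatabaseIndex <- function(cases, tiltDeg = 15,
                               maxPoints = c(brain = 1200, eye = 400),
                               seed = 42L) {
  if (length(cases) == 0L) stop("empty database", call. = FALSE)
  entries <- lapply(cases, function(cs) {
    cloud <- cropForMatching(cs$masks, tiltDeg = tiltDeg,
                             maxPoints = maxPoints, seed = seed)
    list(id = cs$id, cloud = cloud,
         plan = cs$plan, planPath = cs$planPath)
  })
  list(cases = entries,
       params = list(tiltDeg = tiltDeg, maxPoints = as.list(maxPoints),
                     seed = seed))
}

#' Generate a synthetic database directly as an index
#'
#' Builds the database one case at a time, keeping only each case's
#' cropped surface cloud and template plan and discarding the CT volume
#' and masks immediately -- mirroring how the matcher's database stores
#' structure sets only. Memory stays flat in the number of cases.
#'
#' @param spec a [PhantomSpec-class].
#' @param nCases number of cases (>= 1).
#' @inheritParams buildDatabaseIndex
#' @return A database index (see [buildDatabaseIndex()]).
#' @export
generateDatabaseIndex <- function(spec, nCases, tiltDeg = 15,
                                  maxPoints = c(brain = 1200, eye = 400),
                                  seed = 42L) {
  if (!is.numeric(nCases) || nCases < 1)
    stop("nCases must be >= 1", call. = FALSE)
  entries <- lapply(seq_len(as.integer(nCases)), function(i) {
    cs <- databaseCase(spec, i)
    cloud <- cropForMatching(cs$masks, tiltDeg = tiltDeg,
                             maxPoints = maxPoints, seed = seed)
    list(id = cs$id, cloud = cloud, plan = cs$plan, planPath = NULL)
  })
  list(cases = entries,
       params = list(tiltDeg = tiltDeg, maxPoints = as.list(maxPoints),
                     seed = seed))
}

#' Read database case directories into an index
#'
#' Each subdirectory must hold \code{structures.json} and
#' \code{plan.json} (see [writeCaseDir()]).
#'
#' @param dbDir directory of case subdirectories.
#' @inheritParams buildDatabaseIndex
#' @return A database index (see [buildDatabaseIndex()]).
#' @export
indexFromDirectory <- function(dbDir, tiltDeg = 15,
                               maxPoints = c(brain = 1200, eye = 400),
                               seed = 42L) {
  dirs <- list.dirs(dbDir, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "structures.json"))]
  if (length(dirs) == 0L)
    stop("no cases found under ", dbDir, call. = FALSE)
  cases <- lapply(dirs, function(d) {
    list(id = basename(d),
         masks = readStructureSet(file.path(d, "structures.json")),
         planPath = file.path(d, "plan.json"))
  })
  buildDatabaseIndex(cases, tiltDeg, maxPoints, seed)
}

#' Write / read a database index manifest
#'
#' JSON manifest holding the precomputed cropped point clouds and plan
#' file paths -- never CT data.
#'
#' @param index a database index.
#' @param path manifest JSON path.
#' @return `writeDatabaseIndex` the path, invisibly;
#'   `readDatabaseIndex` the index.
#' @export
writeDatabaseIndex <- function(index, path) {
  doc <- list(format = "wbrt-db-index", params = index$params,
              cases = lapply(index$cases, function(cs) {
                list(id = cs$id, planPath = cs$planPath,
                     points = cs$cloud@points, label = cs$cloud@label)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDatabaseIndex
#' @export
readDatabaseIndex <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "wbrt-db-index"))
    stop("not a database index: ", path, call. = FALSE)
  cases <- lapply(doc$cases, function(cs) {
    pts <- cs$points
    if (!is.matrix(pts))
      pts <- do.call(rbind, lapply(pts, unlist))
    list(id = cs$id, planPath = cs$planPath,
         cloud = surfaceCloud(pts, unlist(cs$label)))
  })
  list(cases = cases, params = doc$params)
}

#' Rank database cases by anatomical similarity
#'
#' Scores every case with [matchScore()] (ICP then the direction-
#' selective RMS), sorts ascending by score with ties broken by case id,
#' and attaches the best match's plan (or plan path).
#'
#' @param patient a [SegmentationResult-class], named mask list, or an
#'   already-cropped [SurfaceCloud-class].
#' @param index a database index from [buildDatabaseIndex()],
#'   [indexFromDirectory()] or [readDatabaseIndex()].
#' @param maxIter,tolMm ICP controls.
#' @return data.frame with case_id, score, tx, ty, tz, n_points, ordered
#'   best first; attributes \code{bestPlan} / \code{bestPlanPath}.
#' @export
rankDatabase <- function(patient, index, maxIter = 100L, tolMm = 1e-3) {
  if (length(index$cases) == 0L) stop("empty database", call. = FALSE)
  cloud <- if (is(patient, "SurfaceCloud")) patient
           else cropForMatching(patient,
                                tiltDeg = index$params$tiltDeg,
                                maxPoints = unlist(index$params$maxPoints),
                                seed = index$params$seed)
  rows <- lapply(index$cases, function(cs) {
    s <- matchScore(cloud, cs$cloud, maxIter = maxIter, tolMm = tolMm)
    tr <- attr(s, "translation")
    data.frame(case_id = cs$id, score = as.numeric(s),
               tx = tr[1], ty = tr[2], tz = tr[3],
               n_points = attr(s, "nPoints"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$score, out$case_id), , drop = FALSE]
  rownames(out) <- NULL
  best <- index$cases[[match(out$case_id[1],
                             vapply(index$cases, `[[`, "", "id"))]]
  attr(out, "bestPlan") <- best$plan
  attr(out, "bestPlanPath") <- best$planPath
  out
}
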