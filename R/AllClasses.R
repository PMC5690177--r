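#' @useDynLib wbrt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Patient coordinate convention
#'
#' All world coordinates in this package are in mm with a fixed axis
#' convention: x = left-right (the lateral beam axis, +x towards the
#' patient's left), y = anterior-posterior (+y anterior), z =
#' superior-inferior (+z superior). Grids are axis-aligned: world
#' position of voxel (i, j, k) is \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @name wbrt-coordinates
#' @keywords internal
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' CTVolume: a CT image on a regular grid
#'
#' A 3D scalar grid of Hounsfield units with physical geometry
#' (per-axis voxel spacing and the world position of the first voxel
#' center). See \link{wbrt-coordinates} for the axis convention.
#'
#' @slot voxels 3D numeric array of HU values.
#' @slot spacing numeric(3), voxel size in mm per axis, all > 0.
#' @slot origin numeric(3), world position (mm) of voxel (1, 1, 1).
#'
#' @seealso [ctVolume()], [BinaryMask-class]
#' @exportClass CTVolume
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (!all(is.finite(object@voxels)))
    msg <- c(msg, "HU values must be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) world position of the first voxel center (mm).
#'   Defaults to a grid centered on the world origin.
#' @return A [CTVolume-class] object.
#' @examples
#' ct <- ctVolume(array(0, c(8, 8, 8)), spacing = c(2, 2, 2))
#' dim(voxels(ct))
#' @export
ctVolume <- function(voxels, spacing = c(1, 1, 1), origin = NULL) {
  storage.mode(voxels) <- "double"
  if (is.null(origin))
    origin <- -(dim(voxels) - 1) / 2 * spacing
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' BinaryMask: a structure mask sharing a CT grid
#'
#' A 3D logical grid with the same geometry model as [CTVolume-class];
#' one mask per anatomical structure.
#'
#' @slot mask 3D logical array.
#' @slot spacing numeric(3), voxel size in mm.
#' @slot origin numeric(3), world position of voxel (1, 1, 1).
#' @seealso [binaryMask()], [maskVolume()], [maskToSurface()]
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(mask = "array", spacing = "numeric", origin = "numeric"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 3D logical array")
  if (anyNA(object@mask))
    msg <- c(msg, "mask must not contain NA")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryMask
#'
#' @param mask 3D logical array.
#' @param spacing numeric(3) voxel size in mm, or a [CTVolume-class] /
#'   [BinaryMask-class] whose geometry is copied.
#' @param origin numeric(3) world position of the first voxel center.
#' @return A [BinaryMask-class].
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- TRUE
#' bm <- binaryMask(m, spacing = c(1, 1, 1))
#' maskVolume(bm)  # 27 mm^3
#' @export
binaryMask <- function(mask, spacing = c(1, 1, 1), origin = NULL) {
  if (is(spacing, "CTVolume") || is(spacing, "BinaryMask")) {
    ref <- spacing
    spacing <- ref@spacing
    origin <- ref@origin
  }
  if (is.null(origin))
    origin <- -(dim(mask) - 1) / 2 * spacing
  mode(mask) <- "logical"
  new("BinaryMask", mask = mask, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' SurfaceCloud: labelled boundary points in patient coordinates
#'
#' Points (mm) sampled on structure boundaries, each carrying the name of
#' the structure it came from. Used by the anatomy matcher.
#'
#' @slot points numeric matrix, one row per point, columns x, y, z (mm).
#' @slot label character vector, structure name per point.
#' @seealso [maskToSurface()], [icpAlign()], [matchScore()]
#' @exportClass SurfaceCloud
setClass("SurfaceCloud",
  representation(points = "matrix", label = "character"))

setValidity("SurfaceCloud", function(object) {
  msg <- character()
  if (ncol(object@points) != 3L)
    msg <- c(msg, "points must have 3 columns (x, y, z)")
  if (!all(is.finite(object@points)))
    msg <- c(msg, "point coordinates must be finite")
  if (length(object@label) != nrow(object@points))
    msg <- c(msg, "one label per point required")
  if (length(msg)) msg else TRUE
})

#' Construct a SurfaceCloud
#'
#' @param points numeric matrix (n x 3) of mm coordinates.
#' @param label character vector of per-point structure names (recycled).
#' @return A [SurfaceCloud-class].
#' @export
surfaceCloud <- function(points, label = "surface") {
  points <- as.matrix(points)
  colnames(points) <- c("x", "y", "z")
  new("SurfaceCloud", points = points,
      label = rep_len(as.character(label), nrow(points)))
}

#' CropPlane: the nape-to-forehead cropping plane
#'
#' A plane in the sagittal (y-z) family used to discard posterior and
#' superior brain surface before matching, keeping only anatomy near the
#' MLC-shaped brain-eye interface. The normal has zero x-component and
#' points towards the discarded (posterior-superior) half-space.
#'
#' @slot point numeric(3), a point on the plane (mm).
#' @slot normal numeric(3), unit normal with zero x-component.
#' @slot tiltDeg tilt of the normal from +z towards -y, degrees.
#' @seealso [cropPlane()], [cropForMatching()]
#' @exportClass CropPlane
setClass("CropPlane",
  representation(point = "numeric", normal = "numeric", tiltDeg = "numeric"))

setValidity("CropPlane", function(object) {
  msg <- character()
  if (length(object@point) != 3L || !all(is.finite(object@point)))
    msg <- c(msg, "point must be 3 finite values")
  if (length(object@normal) != 3L || !all(is.finite(object@normal)))
    msg <- c(msg, "normal must be 3 finite values")
  if (abs(object@normal[1]) > 1e-9)
    msg <- c(msg, "normal must have zero x-component")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-6)
    msg <- c(msg, "normal must be a unit vector")
  if (length(msg)) msg else TRUE
})

#' Construct a CropPlane
#'
#' The plane passes through \code{point}; its normal is +z tilted by
#' \code{tiltDeg} degrees towards -y (i.e. from the nape towards the
#' forehead). Points with \code{normal . (p - point) > 0} (superior /
#' posterior side) are discarded by [cropForMatching()].
#'
#' @param point numeric(3), a point on the plane (mm).
#' @param tiltDeg tilt angle in degrees (default 15).
#' @return A [CropPlane-class].
#' @examples
#' pl <- cropPlane(c(0, 60, -8), tiltDeg = 15)
#' pl@normal
#' @export
cropPlane <- function(point, tiltDeg = 15) {
  th <- tiltDeg * pi / 180
  new("CropPlane", point = as.numeric(point),
      normal = c(0, -sin(th), cos(th)), tiltDeg = as.numeric(tiltDeg))
}

#' PlanTemplate: a parsed radiotherapy plan
#'
#' The editable subset of an RT plan (patient identity, isocenter, beam
#' geometry and MLC settings) plus an opaque pass-through list for every
#' other attribute, preserved verbatim on round trip.
#'
#' @slot patientName character(1).
#' @slot patientID character(1).
#' @slot planLabel character(1).
#' @slot sopInstanceUID character(1), unique plan identifier.
#' @slot isocenter numeric(3), mm in patient coordinates.
#' @slot beams list of beams; each beam is a list with gantry/collimator
#'   angles, jaw positions, MLC leaf positions and monitor units.
#' @slot extra opaque pass-through attributes (list, possibly empty).
#' @seealso [planTemplate()], [readPlan()], [retargetPlan()]
#' @exportClass PlanTemplate
setClass("PlanTemplate",
  representation(patientName = "character", patientID = "character",
    planLabel = "character", sopInstanceUID = "character",
    isocenter = "numeric", beams = "list", extra = "listOrNULL"))

setValidity("PlanTemplate", function(object) {
  msg <- character()
  if (length(object@beams) < 1L)
    msg <- c(msg, "plan must have at least one beam")
  if (length(object@isocenter) != 3L || !all(is.finite(object@isocenter)))
    msg <- c(msg, "isocenter must be 3 finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a PlanTemplate
#'
#' @param patientName,patientID patient identity strings.
#' @param isocenter numeric(3) mm.
#' @param beams list of beam description lists.
#' @param planLabel plan label string.
#' @param sopInstanceUID unique identifier; freshly generated when NULL.
#' @param extra opaque pass-through attribute list.
#' @return A [PlanTemplate-class].
#' @export
planTemplate <- function(patientName, patientID, isocenter, beams,
                         planLabel = "WBRT", sopInstanceUID = NULL,
                         extra = list()) {
  if (is.null(sopInstanceUID))
    sopInstanceUID <- freshUID()
  new("PlanTemplate", patientName = patientName, patientID = patientID,
      planLabel = planLabel, sopInstanceUID = sopInstanceUID,
      isocenter = as.numeric(isocenter), beams = beams, extra = extra)
}

#' SegmentationResult: the five auto-segmented structures
#'
#' Brain, left/right eye and left/right lens masks on the CT grid, plus
#' per-step diagnostics (blob counts, selection scores) from the
#' morphological pipeline.
#'
#' @slot structures named list of [BinaryMask-class]: brain, eye_L, eye_R,
#'   lens_L, lens_R.
#' @slot diagnostics list of per-step diagnostics.
#' @seealso [segmentAll()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(structures = "list", diagnostics = "list"))

setValidity("SegmentationResult", function(object) {
  need <- c("brain", "eye_L", "eye_R", "lens_L", "lens_R")
  msg <- character()
  if (!all(need %in% names(object@structures)))
    msg <- c(msg, paste("structures must include",
                        paste(need, collapse = ", ")))
  if (!all(vapply(object@structures, is, TRUE, "BinaryMask")))
    msg <- c(msg, "all structures must be BinaryMask")
  if (length(msg)) msg else TRUE
})

# ---- accessors ----

#' @describeIn ctVolume Extract the HU array.
#' @param x a CTVolume.
#' @export
voxels <- function(x) x@voxels

#' Grid spacing in mm
#' @param x a CTVolume or BinaryMask.
#' @return numeric(3).
#' @export
gridSpacing <- function(x) x@spacing

#' Grid origin in mm (world position of voxel 1,1,1)
#' @param x a CTVolume or BinaryMask.
#' @return numeric(3).
#' @export
gridOrigin <- function(x) x@origin

#' @describeIn binaryMask Extract the logical array.
#' @param x a BinaryMask.
#' @export
maskArray <- function(x) x@mask

#' Physical volume of a mask in mm^3
#' @param x a BinaryMask.
#' @return numeric(1), voxel count times voxel volume.
#' @export
maskVolume <- function(x) sum(x@mask) * prod(x@spacing)

#' @describeIn surfaceCloud Extract the point matrix.
#' @param x a SurfaceCloud.
#' @export
cloudPoints <- function(x) x@points

#' Structures of a segmentation result
#' @param x a SegmentationResult.
#' @param name optional structure name; when given, that BinaryMask.
#' @return Named list of BinaryMask, or a single BinaryMask.
#' @export
segStructures <- function(x, name = NULL) {
  if (is.null(name)) x@structures else x@structures[[name]]
}

#' Beams of a plan
#' @param x a PlanTemplate.
#' @return List of beam descriptions.
#' @export
planBeams <- function(x) x@beams

#' Isocenter of a plan
#' @param x a PlanTemplate.
#' @return numeric(3) mm.
#' @export
planIsocenter <- function(x) x@isocenter

# ---- geometry helpers ----

sameGeometry <- function(a, b, tol = 1e-6) {
  da <- if (is(a, "CTVolume")) dim(a@voxels) else dim(a@mask)
  db <- if (is(b, "CTVolume")) dim(b@voxels) else dim(b@mask)
  identical(da, db) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol)
}

stopIfGeometryDiffers <- function(a, b) {
  if (!sameGeometry(a, b))
    stop("masks/volumes do not share one grid geometry", call. = FALSE)
  invisible(TRUE)
}

# World coordinates of the voxel centers along each axis.
axisCoords <- function(x) {
  d <- if (is(x, "CTVolume")) dim(x@voxels) else dim(x@mask)
  lapply(1:3, function(a) x@origin[a] + (seq_len(d[a]) - 1) * x@spacing[a])
}

# World coordinates (n x 3) of TRUE voxels of a logical array on x's grid.
worldCoords <- function(x, arr) {
  idx <- which(arr, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, x@spacing, "*"), 2, x@origin, "+")
}

#' Centroid of a mask in world coordinates
#' @param m a nonempty [BinaryMask-class].
#' @return numeric(3) mm.
#' @export
maskCentroid <- function(m) {
  idx <- which(m@mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid", call. = FALSE)
  unname(m@origin + (colMeans(idx) - 1) * m@spacing)
}

freshUID <- function() {
  paste0("2.25.", paste(sample(0:9, 24, replace = TRUE), collapse = ""))
}

# ---- show methods ----

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  HU range [%g, %g], origin (%s) mm\n",
              min(object@voxels), max(object@voxels),
              paste(format(object@origin, digits = 4), collapse = ", ")))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryMask: %d x %d x %d voxels, %d foreground (%.1f mm^3)\n",
              d[1], d[2], d[3], sum(object@mask), maskVolume(object)))
})

setMethod("show", "SurfaceCloud", function(object) {
  cat(sprintf("SurfaceCloud: %d points, structures: %s\n",
              nrow(object@points),
              paste(unique(object@label), collapse = ", ")))
})

setMethod("show", "PlanTemplate", function(object) {
  cat(sprintf("PlanTemplate '%s' for %s (%s): %d beam(s), isocenter (%s) mm\n",
              object@planLabel, object@patientName, object@patientID,
              length(object@beams),
              paste(format(object@isocenter, digits = 4), collapse = ", ")))
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult:\n")
  for (nm in names(object@structures)) {
    m <- object@structures[[nm]]
    cat(sprintf("  %-7s %8d voxels (%.0f mm^3)\n", nm, sum(m@mask),
                maskVolume(m)))
  }
})
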