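# Readers/writers for the formats the pipeline touches. Everything is
# plain text (JSON) except the fast internal volume format, which is
# NIfTI (compressed array) plus a JSON geometry header.
#
# CT series: a directory with one JSON file per axial slice carrying the
#   usual series semantics (series UID, slice location, pixel spacing,
#   rescale slope/intercept, stored pixel data). Slices are sorted by
#   position on read, whatever the file order.
# Structure set: JSON of per-slice contour polygons in mm; rasterized
#   onto a reference grid on read (a voxel belongs to a structure iff its
#   center is inside the polygons, even-odd rule), contoured at the 0.5
#   iso-level on write.
# Plan: JSON with the editable beam/MLC/identity attributes plus an
#   opaque pass-through block preserved verbatim.

# ---- internal volume format ----

#' Write / read a volume in the internal format
#'
#' NIfTI (.nii.gz, compressed voxel array) next to a JSON geometry header
#' (`<stem>.json` with spacing and origin), the package's fast internal
#' exchange format.
#'
#' @param x a [CTVolume-class] or [BinaryMask-class].
#' @param stem output path without extension.
#' @return `writeVolume` the stem, invisibly; `readVolume` a
#'   [CTVolume-class] (or [BinaryMask-class] when the header marks a mask).
#' @export
writeVolume <- function(x, stem) {
  arr <- if (is(x, "BinaryMask")) x@mask * 1 else x@voxels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x@spacing
  RNifti::writeNifti(img, paste0(stem, ".nii.gz"))
  hdr <- list(format = "wbrt-volume", kind = if (is(x, "BinaryMask")) "mask" else "ct",
              spacing_mm = x@spacing, origin_mm = x@origin)
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname writeVolume
#' @export
readVolume <- function(stem) {
  stem <- sub("\\.nii\\.gz$", "", stem)
  hdrPath <- paste0(stem, ".json")
  niiPath <- paste0(stem, ".nii.gz")
  if (!file.exists(hdrPath) || !file.exists(niiPath))
    stop("not an internal volume (missing .nii.gz or .json): ", stem,
         call. = FALSE)
  hdr <- jsonlite::read_json(hdrPath, simplifyVector = TRUE)
  if (!identical(hdr$format, "wbrt-volume"))
    stop("not an internal volume header: ", hdrPath, call. = FALSE)
  img <- RNifti::readNifti(niiPath)
  arr <- array(as.numeric(img), dim(img))
  if (identical(hdr$kind, "mask"))
    binaryMask(arr > 0.5, hdr$spacing_mm, hdr$origin_mm)
  else
    ctVolume(arr, hdr$spacing_mm, hdr$origin_mm)
}

# ---- CT series ----

#' Write a CT volume as a slice series
#'
#' One JSON file per axial slice with series UID, instance number, slice
#' location, pixel spacing and rescale-encoded stored values
#' (HU = slope * stored + intercept, slope 1 / intercept -1024).
#'
#' @param ct a [CTVolume-class].
#' @param dir output directory (created if needed).
#' @param seriesUID series identifier; generated when NULL.
#' @return The directory, invisibly.
#' @export
writeCTSeries <- function(ct, dir, seriesUID = NULL) {
  if (is.null(seriesUID)) seriesUID <- freshUID()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(ct@voxels)
  intercept <- -1024
  for (k in seq_len(d[3])) {
    sl <- list(modality = "CT", series_uid = seriesUID,
               instance_number = k,
               slice_location_mm = ct@origin[3] + (k - 1) * ct@spacing[3],
               image_position_mm = c(ct@origin[1], ct@origin[2],
                                     ct@origin[3] + (k - 1) * ct@spacing[3]),
               pixel_spacing_mm = ct@spacing[1:2],
               shape = d[1:2],
               rescale_slope = 1, rescale_intercept = intercept,
               pixel_data = as.integer(round(ct@voxels[, , k] - intercept)))
    jsonlite::write_json(sl, file.path(dir, sprintf("slice_%04d.json", k)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a CT slice series into a volume
#'
#' Slices are sorted by slice location (file order is irrelevant), checked
#' for a single coherent series and uniform slice spacing, and rescaled to
#' HU.
#'
#' @param dir directory containing the slice files.
#' @param tol relative tolerance on slice-spacing uniformity.
#' @return A [CTVolume-class].
#' @export
readCTSeries <- function(dir, tol = 1e-3) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L)
    stop("no CT slices found in ", dir, call. = FALSE)
  slices <- lapply(files, jsonlite::read_json, simplifyVector = TRUE)
  need <- c("modality", "series_uid", "slice_location_mm",
            "pixel_spacing_mm", "shape", "rescale_slope",
            "rescale_intercept", "pixel_data")
  for (s in slices)
    if (!all(need %in% names(s)))
      stop("CT slice is missing required geometry tags", call. = FALSE)
  if (length(unique(vapply(slices, `[[`, "", "series_uid"))) != 1L)
    stop("directory contains mixed CT series", call. = FALSE)
  locs <- vapply(slices, `[[`, 0, "slice_location_mm")
  ord <- order(locs)
  slices <- slices[ord]
  locs <- locs[ord]
  if (length(locs) < 2L)
    stop("CT series needs at least two slices", call. = FALSE)
  dz <- diff(locs)
  if (any(dz <= 0) || (max(dz) - min(dz)) / mean(dz) > tol)
    stop("non-uniform slice spacing beyond tolerance", call. = FALSE)
  shape <- slices[[1]]$shape
  arr <- array(0, c(shape[1], shape[2], length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    if (!identical(as.integer(s$shape), as.integer(shape)))
      stop("inconsistent slice shapes in series", call. = FALSE)
    arr[, , k] <- s$rescale_slope * s$pixel_data + s$rescale_intercept
  }
  sp <- c(slices[[1]]$pixel_spacing_mm, mean(dz))
  org <- c(slices[[1]]$image_position_mm[1:2], locs[1])
  ctVolume(arr, sp, org)
}

# ---- structure sets ----

#' Write a structure set as per-slice contours
#'
#' Each mask is contoured slice by slice at the 0.5 iso-level of its
#' indicator (vertices sit midway between foreground and background voxel
#' centers), in world mm.
#'
#' @param ss named list of [BinaryMask-class] (or a
#'   [SegmentationResult-class]).
#' @param path output JSON file.
#' @return The path, invisibly.
#' @export
writeStructureSet <- function(ss, path) {
  if (is(ss, "SegmentationResult")) ss <- ss@structures
  if (!is.list(ss) || length(ss) == 0L)
    stop("empty structure set", call. = FALSE)
  ref <- ss[[1]]
  structures <- lapply(names(ss), function(nm) {
    m <- ss[[nm]]
    stopIfGeometryDiffers(ref, m)
    if (!any(m@mask))
      stop("structure '", nm, "' has no contours", call. = FALSE)
    cs <- axisCoords(m)
    ks <- which(apply(m@mask, 3, any))
    slices <- lapply(ks, function(k) {
      polys <- sliceContours(m@mask[, , k], cs[[1]], cs[[2]])
      list(z_mm = cs[[3]][k], polygons = polys)
    })
    list(name = nm, slices = slices)
  })
  doc <- list(format = "RTSTRUCT",
              geometry = list(shape = dim(ref@mask), spacing_mm = ref@spacing,
                              origin_mm = ref@origin),
              structures = structures)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a structure set, rasterizing contours onto a grid
#'
#' A voxel belongs to a structure iff its center lies inside the slice
#' polygons (even-odd rule, half-open on edge crossings).
#'
#' @param path structure-set JSON file.
#' @param reference a [CTVolume-class] or [BinaryMask-class] providing the
#'   target grid; when NULL the geometry header embedded in the file is
#'   used.
#' @return Named list of [BinaryMask-class].
#' @export
readStructureSet <- function(path, reference = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "RTSTRUCT"))
    stop("not a structure set: ", path, call. = FALSE)
  if (is.null(reference)) {
    g <- doc$geometry
    reference <- binaryMask(array(FALSE, g$shape), g$spacing_mm, g$origin_mm)
  }
  cs <- axisCoords(reference)
  d <- c(length(cs[[1]]), length(cs[[2]]), length(cs[[3]]))
  dz <- (max(cs[[3]]) - min(cs[[3]])) / max(1, d[3] - 1)
  out <- list()
  for (st in doc$structures) {
    if (length(st$slices) == 0L)
      stop("structure '", st$name, "' has no contours", call. = FALSE)
    arr <- array(FALSE, d)
    for (sl in st$slices) {
      k <- which(abs(cs[[3]] - sl$z_mm) <= dz / 2 + 1e-6)
      if (length(k) == 0L)
        stop("contour slice at z=", sl$z_mm,
             " mm falls outside the reference grid", call. = FALSE)
      k <- k[which.min(abs(cs[[3]][k] - sl$z_mm))]
      arr[, , k] <- arr[, , k] | rasterizeSlicePolygons(sl$polygons,
                                                       cs[[1]], cs[[2]])
    }
    out[[st$name]] <- binaryMask(arr, reference@spacing, reference@origin)
  }
  out
}

# Contour a binary slice at level 0.5; returns list of polygons, each
# list(x = ..., y = ...) in world mm. The slice is zero-padded so all
# contours close even when the mask touches the slice border.
sliceContours <- function(slice, xs, ys) {
  dx <- if (length(xs) > 1) xs[2] - xs[1] else 1
  dy <- if (length(ys) > 1) ys[2] - ys[1] else 1
  px <- c(xs[1] - dx, xs, xs[length(xs)] + dx)
  py <- c(ys[1] - dy, ys, ys[length(ys)] + dy)
  pz <- matrix(0, length(px), length(py))
  pz[2:(length(xs) + 1), 2:(length(ys) + 1)] <- slice * 1
  cl <- grDevices::contourLines(px, py, pz, levels = 0.5)
  lapply(cl, function(p) list(x = p$x, y = p$y))
}

# Even-odd scanline rasterization of closed polygons onto voxel centers.
rasterizeSlicePolygons <- function(polys, xs, ys) {
  out <- matrix(FALSE, length(xs), length(ys))
  if (length(polys) == 0L) return(out)
  edges <- do.call(rbind, lapply(polys, function(p) {
    x <- as.numeric(p$x); y <- as.numeric(p$y)
    n <- length(x)
    if (n < 3L) return(NULL)
    cbind(x0 = x, y0 = y, x1 = x[c(2:n, 1)], y1 = y[c(2:n, 1)])
  }))
  if (is.null(edges)) return(out)
  for (j in seq_along(ys)) {
    yc <- ys[j]
    lower <- pmin(edges[, "y0"], edges[, "y1"])
    upper <- pmax(edges[, "y0"], edges[, "y1"])
    hit <- which(lower <= yc & yc < upper)  # half-open: vertex counted once
    if (length(hit) == 0L) next
    e <- edges[hit, , drop = FALSE]
    t <- (yc - e[, "y0"]) / (e[, "y1"] - e[, "y0"])
    xc <- sort(e[, "x0"] + t * (e[, "x1"] - e[, "x0"]))
    out[, j] <- findInterval(xs, xc) %% 2L == 1L
  }
  out
}

# ---- plans ----

#' Write a plan to disk
#'
#' All attributes round-trip verbatim except the SOP instance UID, which
#' is freshly generated on every write (unique plan identity).
#'
#' @param pt a [PlanTemplate-class].
#' @param path output JSON file.
#' @return The path, invisibly.
#' @export
writePlan <- function(pt, path) {
  validObject(pt)
  doc <- list(format = "RTPLAN",
              patient_name = pt@patientName, patient_id = pt@patientID,
              plan_label = pt@planLabel, sop_instance_uid = freshUID(),
              isocenter_mm = pt@isocenter, beams = pt@beams,
              extra = pt@extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plan from disk
#'
#' @param path plan JSON file.
#' @return A [PlanTemplate-class].
#' @export
readPlan <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e)
                    stop("corrupted or unreadable plan file: ", path,
                         call. = FALSE))
  if (!identical(doc$format, "RTPLAN"))
    stop("file is not an RT plan: ", path, call. = FALSE)
  planTemplate(patientName = doc$patient_name, patientID = doc$patient_id,
               isocenter = doc$isocenter_mm, beams = doc$beams,
               planLabel = doc$plan_label,
               sopInstanceUID = doc$sop_instance_uid,
               extra = doc$extra)
}

# ---- database case on disk ----

#' Write a database case directory
#'
#' One directory per prior case holding its structure set and plan (the
#' matcher never stores CT data; pass \code{withCT = TRUE} to keep the
#' volume for inspection).
#'
#' @param case list with \code{masks} (named list of masks) and
#'   \code{plan}; as produced by [generateDatabase()].
#' @param dir output directory.
#' @param withCT also write the CT volume in the internal format.
#' @return The directory, invisibly.
#' @export
writeCaseDir <- function(case, dir, withCT = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeStructureSet(case$masks, file.path(dir, "structures.json"))
  writePlan(case$plan, file.path(dir, "plan.json"))
  if (withCT) writeVolume(case$ct, file.path(dir, "ct"))
  invisible(dir)
}
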