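# Automatic segmentation of brain, eyes and lenses from a head CT with a
# chain of morphological operators and no user interaction:
#   brain  = largest soft-tissue component after bone-edge cleanup and an
#            erosion that severs thin connections (extraocular muscles),
#            restored by the paired dilation and smoothed by closing;
#   eyes   = the two roundest remaining soft-tissue components after the
#            same erosion (which disconnects the globes from facial
#            tissue), refined by a morphological level set against the CT
#            after erasing the bright lens;
#   lenses = largest H-convex bright patch inside each eye's VOI.

#' SegmentationParams: tunable parameters of the auto-segmentation
#'
#' @slot window numeric(2), soft-tissue HU window (default [-200, 200]).
#' @slot erosionRadius mm; severs soft-tissue connections thinner than
#'   this (extraocular-muscle scale) before component selection.
#' @slot closingRadius mm; final smoothing closing for the brain.
#' @slot edgeStrategy "subtract" removes a dilated band around strong
#'   Sobel bone edges from the soft-tissue mask before component
#'   analysis; "none" skips the edge step.
#' @slot edgeThreshold HU/mm; Sobel gradient magnitude above which a
#'   voxel is treated as a bone interface.
#' @slot edgeDilate mm; dilation of the edge band before subtraction.
#' @slot hconvexHeight HU; H-convex height for lens detection (lens must
#'   exceed surrounding vitreous by at least this much).
#' @slot levelsetIterations iterations of the eye level-set refinement.
#' @slot levelsetCurvature curvature weight: number of 26-neighbourhood
#'   majority (median) smoothing passes per iteration.
#' @slot roundnessMin minimum sphericity for an eye candidate.
#' @slot eyeVoiMargin mm; margin around the eye bounding box for the lens
#'   search volume of interest.
#' @slot lensClosingRadius mm; smoothing closing for the lens.
#' @slot minCandidateMm3 mm^3; minimum component volume considered an eye
#'   candidate.
#' @seealso [segmentationParams()], [segmentAll()]
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(window = "numeric", erosionRadius = "numeric",
    closingRadius = "numeric", edgeStrategy = "character",
    edgeThreshold = "numeric", edgeDilate = "numeric",
    hconvexHeight = "numeric", levelsetIterations = "integer",
    levelsetCurvature = "numeric", roundnessMin = "numeric",
    eyeVoiMargin = "numeric", lensClosingRadius = "numeric",
    minCandidateMm3 = "numeric"))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be an increasing HU interval")
  for (nm in c("erosionRadius", "closingRadius", "hconvexHeight",
               "lensClosingRadius"))
    if (slot(object, nm) <= 0) msg <- c(msg, paste(nm, "must be > 0"))
  if (!object@edgeStrategy %in% c("subtract", "none"))
    msg <- c(msg, "edgeStrategy must be 'subtract' or 'none'")
  if (length(msg)) msg else TRUE
})

#' Construct segmentation parameters
#'
#' Defaults: soft-tissue window [-200, 200] HU; erosion radius 2 mm
#' (severs extraocular-muscle-scale bridges while preserving the brain);
#' closing radius 3 mm; Sobel edge threshold 300 HU/mm with a 1 mm
#' subtraction band; H-convex height 40 HU (lens at 80-120 HU against
#' vitreous at 0-30 HU); 50 level-set iterations with curvature weight 1;
#' minimum eye-candidate sphericity 0.7; 4 mm lens VOI margin.
#'
#' @param window,erosionRadius,closingRadius,edgeStrategy,edgeThreshold,edgeDilate
#'   see [SegmentationParams-class].
#' @param hconvexHeight,levelsetIterations,levelsetCurvature,roundnessMin
#'   see [SegmentationParams-class].
#' @param eyeVoiMargin,lensClosingRadius,minCandidateMm3
#'   see [SegmentationParams-class].
#' @return A [SegmentationParams-class].
#' @export
segmentationParams <- function(window = c(-200, 200), erosionRadius = 2,
                               closingRadius = 3,
                               edgeStrategy = "subtract",
                               edgeThreshold = 300, edgeDilate = 1,
                               hconvexHeight = 40,
                               levelsetIterations = 50L,
                               levelsetCurvature = 1,
                               roundnessMin = 0.7, eyeVoiMargin = 4,
                               lensClosingRadius = 1.5,
                               minCandidateMm3 = 500) {
  new("SegmentationParams", window = as.numeric(window),
      erosionRadius = as.numeric(erosionRadius),
      closingRadius = as.numeric(closingRadius),
      edgeStrategy = edgeStrategy, edgeThreshold = as.numeric(edgeThreshold),
      edgeDilate = as.numeric(edgeDilate),
      hconvexHeight = as.numeric(hconvexHeight),
      levelsetIterations = as.integer(levelsetIterations),
      levelsetCurvature = as.numeric(levelsetCurvature),
      roundnessMin = as.numeric(roundnessMin),
      eyeVoiMargin = as.numeric(eyeVoiMargin),
      lensClosingRadius = as.numeric(lensClosingRadius),
      minCandidateMm3 = as.numeric(minCandidateMm3))
}

# ---- elementary operators ----

#' Soft-tissue mask by HU windowing
#'
#' @param ct a [CTVolume-class].
#' @param window numeric(2) HU interval (closed).
#' @return A [BinaryMask-class], true exactly where
#'   \code{window[1] <= HU <= window[2]}.
#' @export
softTissueMask <- function(ct, window = c(-200, 200)) {
  m <- ct@voxels >= window[1] & ct@voxels <= window[2]
  if (!any(m))
    stop("degenerate input: no soft-tissue voxels in window", call. = FALSE)
  binaryMask(m, ct)
}

#' Sobel bone-edge image
#'
#' 3D Sobel gradient magnitude of the CT, in HU/mm for isotropic 1 mm
#' grids (the kernel is normalized so a unit axis-aligned step has unit
#' peak response). Maxima localize at soft-tissue/bone interfaces.
#'
#' @param ct a [CTVolume-class].
#' @return Numeric array of gradient magnitudes, same shape as the CT.
#' @export
boneEdges <- function(ct) {
  g <- cpp_sobel_magnitude(ct@voxels, dim(ct@voxels))
  dim(g) <- dim(ct@voxels)
  g
}

#' Roundness (sphericity) of a component
#'
#' \code{pi^(1/3) (6V)^(2/3) / A}: 1 for a perfect sphere in the
#' continuum limit, smaller for every other shape. Surface area comes
#' from [surfaceArea()]; the default gradient estimator is asymptotically
#' unbiased on smooth shapes, while "face" counts exposed voxel faces
#' (exact for boxes).
#'
#' @param m a nonempty [BinaryMask-class] (single component).
#' @param method surface-area estimator, "gradient" (default) or "face".
#' @return Sphericity score in (0, 1] (may slightly exceed 1 on very
#'   small blobs under the gradient estimator).
#' @export
roundness <- function(m, method = c("gradient", "face")) {
  if (!any(m@mask)) stop("empty component has no roundness", call. = FALSE)
  v <- maskVolume(m)
  a <- surfaceArea(m, match.arg(method))
  pi^(1 / 3) * (6 * v)^(2 / 3) / a
}

# ---- brain ----

#' Segment the brain
#'
#' Chain: soft-tissue mask, subtraction of a dilated band around strong
#' Sobel bone edges, binary erosion (severing connections thinner than
#' the erosion radius), largest connected component, the paired dilation,
#' and a final closing. Returns a single connected component.
#'
#' @param ct a [CTVolume-class].
#' @param params a [SegmentationParams-class].
#' @return A [BinaryMask-class] with attribute \code{diagnostics}.
#' @export
segmentBrain <- function(ct, params = segmentationParams()) {
  soft <- softTissueMask(ct, params@window)
  work <- soft
  if (params@edgeStrategy == "subtract") {
    edges <- binaryMask(boneEdges(ct) > params@edgeThreshold, ct)
    work <- binaryMask(work@mask & !dilateMask(edges, params@edgeDilate)@mask,
                       ct)
  }
  er <- erodeMask(work, params@erosionRadius)
  comp <- componentMasks(er)
  if (length(comp$ids) == 0L)
    stop("no soft-tissue component found for the brain", call. = FALSE)
  largest <- binaryMask(comp$labels == comp$ids[1], ct)
  grown <- dilateMask(largest, params@erosionRadius)
  closed <- closeMask(grown, params@closingRadius)
  if (params@edgeStrategy == "subtract") {
    # undo the edge-band subtraction: grow back into the removed rim but
    # never past the soft-tissue window (bone stops the regrowth)
    snap <- params@edgeDilate + max(ct@spacing)
    closed <- binaryMask(dilateMask(closed, snap)@mask & soft@mask, ct)
  }
  final <- componentMasks(closed)
  brain <- binaryMask(final$labels == final$ids[1], ct)
  attr(brain, "diagnostics") <- list(n_components = length(comp$ids),
                                     component_voxels = comp$counts)
  brain
}

# ---- eyes ----

#' Segment the eye globes
#'
#' The soft tissue outside the brain is eroded (disconnecting the globes
#' from facial tissue and muscle bridges), components are ranked by
#' roundness, and the two roundest above the threshold are kept. Each is
#' refined by erasing lens-bright voxels to the candidate's median HU,
#' growing a morphological level set against the CT inside its VOI, and a
#' smoothing closing. Left/right are assigned by the sign of the
#' x-centroid (+x = patient left).
#'
#' @param ct a [CTVolume-class].
#' @param brainMask the brain [BinaryMask-class] (candidates exclude it).
#' @param params a [SegmentationParams-class].
#' @return List with \code{eye_L}, \code{eye_R} ([BinaryMask-class]) and
#'   \code{diagnostics}.
#' @export
segmentEyes <- function(ct, brainMask, params = segmentationParams()) {
  soft <- softTissueMask(ct, params@window)
  cand <- binaryMask(soft@mask & !brainMask@mask, ct)
  er <- erodeMask(cand, params@erosionRadius)
  comp <- componentMasks(er, minVoxels = max(
    1L, as.integer(params@minCandidateMm3 / prod(ct@spacing))))
  if (length(comp$ids) < 2L)
    stop("fewer than two eye candidates found", call. = FALSE)
  scores <- vapply(comp$ids, function(id)
    roundness(binaryMask(comp$labels == id, ct)), 0)
  ord <- order(scores, decreasing = TRUE)
  good <- ord[scores[ord] >= params@roundnessMin]
  if (length(good) < 2L)
    stop("fewer than two eye candidates above the roundness threshold",
         call. = FALSE)
  picks <- comp$ids[good[1:2]]
  eyes <- lapply(picks, function(id)
    refineEye(ct, binaryMask(comp$labels == id, ct), soft, params))
  cx <- vapply(eyes, function(m) maskCentroid(m)[1], 0)
  # +x is patient left
  res <- if (cx[1] >= cx[2]) list(eye_L = eyes[[1]], eye_R = eyes[[2]])
         else list(eye_L = eyes[[2]], eye_R = eyes[[1]])
  res$diagnostics <- list(n_candidates = length(comp$ids),
                          roundness = sort(scores, decreasing = TRUE))
  res
}

# Per-eye refinement: lens erasure, morphological level set, closing.
refineEye <- function(ct, seed, soft, params) {
  bb <- maskBBox(seed, marginMm = params@erosionRadius + params@eyeVoiMargin)
  sub <- ct@voxels[bb$ix, bb$iy, bb$iz]
  seedSub <- seed@mask[bb$ix, bb$iy, bb$iz]
  softSub <- soft@mask[bb$ix, bb$iy, bb$iz]
  # erase lens-bright voxels to the candidate's median HU so the level
  # set does not stall on the internal lens edge
  med <- stats::median(sub[seedSub])
  hc <- hConvex(sub, params@hconvexHeight)
  bright <- hc >= params@hconvexHeight - 1e-9 & sub <= params@window[2]
  sub[bright] <- med
  u <- levelSetGrow(sub, seedSub, softSub, ct@spacing,
                    iters = params@levelsetIterations,
                    smoothPasses = round(params@levelsetCurvature))
  # the outermost soft voxel layer carries the bone-interface gradient and
  # is skipped by the edge-stopped growth; snap onto it (bone still blocks)
  snap <- cpp_dilate(u, dim(u), sphereOffsets(max(ct@spacing), ct@spacing))
  dim(snap) <- dim(u)
  u <- u | (snap & softSub)
  full <- array(FALSE, dim(ct@voxels))
  full[bb$ix, bb$iy, bb$iz] <- u
  closeMask(binaryMask(full, ct), params@erosionRadius)
}

# Morphological geodesic level set: balloon growth restricted to weak-
# gradient soft tissue, with majority-filter curvature smoothing.
levelSetGrow <- function(vol, seed, domain, spacing, iters = 50L,
                         smoothPasses = 1L, lambda = 60) {
  d <- dim(vol)
  g2 <- array(0, d)
  for (ax in 1:3) {
    gax <- (shiftArray(vol, ax, -1L) - shiftArray(vol, ax, 1L)) /
      (2 * spacing[ax])
    g2 <- g2 + gax^2
  }
  gstop <- 1 / (1 + g2 / lambda^2)
  grow <- domain & gstop > 0.3
  u <- seed & domain
  off <- sphereOffsets(max(spacing), spacing)
  for (it in seq_len(iters)) {
    nxt <- cpp_dilate(u, d, off)
    dim(nxt) <- d
    nxt <- (nxt & grow) | u
    for (s in seq_len(max(0L, smoothPasses)))
      nxt <- majority26(nxt) & domain
    if (identical(nxt, u)) break
    u <- nxt
  }
  u
}

# 26-neighbourhood majority vote (discrete mean-curvature smoothing).
majority26 <- function(u) {
  cnt <- array(0L, dim(u))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    s <- u
    if (dx != 0) s <- shiftArray(s, 1L, dx)
    if (dy != 0) s <- shiftArray(s, 2L, dy)
    if (dz != 0) s <- shiftArray(s, 3L, dz)
    cnt <- cnt + s
  }
  cnt >= 14L
}

# Index ranges of the mask bounding box expanded by a margin in mm.
maskBBox <- function(m, marginMm = 0) {
  idx <- which(m@mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box", call. = FALSE)
  d <- dim(m@mask)
  mv <- ceiling(marginMm / m@spacing)
  lo <- pmax(1L, apply(idx, 2, min) - mv)
  hi <- pmin(d, apply(idx, 2, max) + mv)
  list(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3])
}

# ---- lenses ----

#' Segment the lenses
#'
#' Per eye: a volume of interest (eye bounding box plus margin) is cut
#' out, the H-convex transform (thresholded at its height parameter)
#' isolates patches brighter than their surroundings, candidates are
#' restricted to the soft-tissue window (bone rims excluded), the largest
#' patch is kept and smoothed by closing. An eye without a
#' supra-threshold patch yields an empty mask with a warning.
#'
#' @param ct a [CTVolume-class].
#' @param eyes list with \code{eye_L} and \code{eye_R} masks.
#' @param params a [SegmentationParams-class].
#' @return List with \code{lens_L} and \code{lens_R} [BinaryMask-class].
#' @export
segmentLenses <- function(ct, eyes, params = segmentationParams()) {
  out <- lapply(c(L = "eye_L", R = "eye_R"), function(nm) {
    eye <- eyes[[nm]]
    if (!any(eye@mask)) stop("empty eye mask: ", nm, call. = FALSE)
    bb <- maskBBox(eye, marginMm = params@eyeVoiMargin)
    sub <- ct@voxels[bb$ix, bb$iy, bb$iz]
    hc <- hConvex(sub, params@hconvexHeight)
    cand <- hc >= params@hconvexHeight - 1e-9 &
      sub <= params@window[2] & sub >= params@window[1]
    full <- array(FALSE, dim(ct@voxels))
    if (!any(cand)) {
      warning("no lens-bright patch found in ", nm, " VOI", call. = FALSE)
      return(binaryMask(full, ct))
    }
    sm <- binaryMask(insertSub(full, cand, bb), ct)
    comp <- componentMasks(sm)
    largest <- binaryMask(comp$labels == comp$ids[1], ct)
    closeMask(largest, params@lensClosingRadius)
  })
  names(out) <- c("lens_L", "lens_R")
  out
}

insertSub <- function(full, sub, bb) {
  full[bb$ix, bb$iy, bb$iz] <- sub
  full
}

# ---- composition ----

#' Run the full auto-segmentation
#'
#' Composes [segmentBrain()], [segmentEyes()] and [segmentLenses()];
#' deterministic for fixed input and parameters.
#'
#' @param ct a [CTVolume-class].
#' @param params a [SegmentationParams-class].
#' @return A [SegmentationResult-class].
#' @examples
#' \donttest{
#' ph <- generatePhantom(phantomSpec(spacing = c(2, 2, 2),
#'                                   gridShape = c(80, 104, 86)))
#' seg <- segmentAll(ph$ct)
#' seg
#' }
#' @export
segmentAll <- function(ct, params = segmentationParams()) {
  brain <- segmentBrain(ct, params)
  eyes <- segmentEyes(ct, brain, params)
  lenses <- segmentLenses(ct, eyes, params)
  new("SegmentationResult",
      structures = list(brain = brain, eye_L = eyes$eye_L,
                        eye_R = eyes$eye_R, lens_L = lenses$lens_L,
                        lens_R = lenses$lens_R),
      diagnostics = list(brain = attr(brain, "diagnostics"),
                         eyes = eyes$diagnostics))
}
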