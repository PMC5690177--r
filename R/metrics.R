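# Segmentation agreement metrics: Dice overlap, symmetrized mean surface
# distance and Hausdorff distance between boundary voxel centers.

#' Dice overlap coefficient
#'
#' \code{2 |A n B| / (|A| + |B|)}: 0 for disjoint masks, 1 for identical
#' masks. Undefined (error) when both masks are empty.
#'
#' @param a,b [BinaryMask-class] objects on the same grid.
#' @return Numeric in [0, 1].
#' @examples
#' m <- array(FALSE, c(10, 10, 10)); m[2:6, 2:6, 2:6] <- TRUE
#' a <- binaryMask(m); dice(a, a)  # 1
#' @export
dice <- function(a, b) {
  stopIfGeometryDiffers(a, b)
  na <- sum(a@mask); nb <- sum(b@mask)
  if (na + nb == 0L)
    stop("Dice is undefined for two empty masks", call. = FALSE)
  2 * sum(a@mask & b@mask) / (na + nb)
}

#' Jaccard index (convenience alias)
#'
#' \code{|A n B| / |A u B|}; monotone transform of [dice()].
#' @inheritParams dice
#' @return Numeric in [0, 1].
#' @export
jaccard <- function(a, b) {
  d <- dice(a, b)
  d / (2 - d)
}

#' Surface distances between two masks
#'
#' Distances from each boundary voxel center of one mask to the nearest
#' boundary voxel center of the other, in both directions.
#' \code{mean_mm} is the symmetrized mean (average over the pooled
#' directed distances); \code{hausdorff_mm} is the maximum over both
#' directions.
#'
#' @param a,b nonempty [BinaryMask-class] objects on the same grid.
#' @return List with \code{mean_mm} and \code{hausdorff_mm}.
#' @export
surfaceDistances <- function(a, b) {
  stopIfGeometryDiffers(a, b)
  if (!any(a@mask) || !any(b@mask))
    stop("surface distances need two nonempty masks", call. = FALSE)
  pa <- worldCoords(a, boundaryMask(a)@mask)
  pb <- worldCoords(b, boundaryMask(b)@mask)
  dab <- nnDistances(pa, pb)
  dba <- nnDistances(pb, pa)
  list(mean_mm = mean(c(dab, dba)),
       hausdorff_mm = max(max(dab), max(dba)))
}

nnDistances <- function(query, ref) {
  idx <- cpp_nn_index(query, ref)
  sqrt(rowSums((query - ref[idx, , drop = FALSE])^2))
}

#' Per-structure agreement report between two structure sets
#'
#' @param a,b named lists of [BinaryMask-class] (or
#'   [SegmentationResult-class]); metrics are computed for every
#'   structure name present in both.
#' @return data.frame with columns structure, dice,
#'   mean_surface_distance_mm, hausdorff_mm.
#' @export
metricReport <- function(a, b) {
  if (is(a, "SegmentationResult")) a <- a@structures
  if (is(b, "SegmentationResult")) b <- b@structures
  common <- intersect(names(a), names(b))
  if (length(common) == 0L)
    stop("no common structures to compare", call. = FALSE)
  rows <- lapply(common, function(nm) {
    ma <- a[[nm]]; mb <- b[[nm]]
    if (!any(ma@mask) && !any(mb@mask))
      return(data.frame(structure = nm, dice = NA_real_,
                        mean_surface_distance_mm = NA_real_,
                        hausdorff_mm = NA_real_))
    if (!any(ma@mask) || !any(mb@mask))
      return(data.frame(structure = nm, dice = 0,
                        mean_surface_distance_mm = NA_real_,
                        hausdorff_mm = NA_real_))
    sd <- surfaceDistances(ma, mb)
    data.frame(structure = nm, dice = dice(ma, mb),
               mean_surface_distance_mm = sd$mean_mm,
               hausdorff_mm = sd$hausdorff_mm)
  })
  do.call(rbind, rows)
}
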