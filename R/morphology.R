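#' @include geometry.R
NULL

## Offsets (voxels) of a physical-space ball of the given radius (mm) on an
## anisotropic grid: a 2 mm ball spans different voxel extents along the
## 0.5 mm in-plane and 1.2 mm through-plane axes of a black-bone grid.
.ballOffsets <- function(radiusMm, spacing) {
  r <- pmax(0L, as.integer(floor(radiusMm / spacing)))
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 +
          (g$dz * spacing[3])^2 <= radiusMm^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

.morphOnce <- function(maskArr, dims, offs, dilate) {
  array(cpp_morph(as.logical(maskArr), as.integer(dims), offs,
                  as.integer(dilate)), dim = dims)
}

## Per-voxel squared distance to the array border (outside = background).
.borderDistanceSq <- function(dims, spacing) {
  bx <- pmin(seq_len(dims[1]), rev(seq_len(dims[1]))) * spacing[1]
  by <- pmin(seq_len(dims[2]), rev(seq_len(dims[2]))) * spacing[2]
  bz <- pmin(seq_len(dims[3]), rev(seq_len(dims[3]))) * spacing[3]
  outer(outer(bx, by, pmin), bz, pmin)^2
}

## Ball erosion/dilation through the exact Euclidean distance transform:
## dilation keeps voxels within radius of the mask, erosion removes voxels
## within radius of the complement (or of the array border). Equivalent to
## sweeping the physical-space ball structuring element, but O(n).
.morphBall <- function(maskArr, dims, spacing, radiusMm, dilate) {
  r2 <- radiusMm^2 + 1e-9
  if (dilate) {
    d2 <- array(cpp_edt_sq(as.logical(maskArr), as.integer(dims), spacing),
                dim = dims)
    maskArr | d2 <= r2
  } else {
    d2 <- array(cpp_edt_sq(as.logical(!maskArr), as.integer(dims), spacing),
                dim = dims)
    maskArr & d2 > r2 & .borderDistanceSq(dims, spacing) > r2
  }
}

#' Binary morphology in physical space
#'
#' Structuring elements are physical balls of `radiusMm` millimetres,
#' converted to (possibly anisotropic) voxel extents per axis, so a given
#' radius means the same physical reach on every acquisition grid.
#' `fill_holes` fills cavities not connected to the volume border and ignores
#' `radiusMm`.
#'
#' @param mask A [BinaryMask-class].
#' @param op One of `"erode"`, `"dilate"`, `"close"`, `"open"`,
#'   `"fill_holes"`.
#' @param radiusMm Ball radius in mm (>= 0). A radius smaller than half the
#'   smallest voxel spacing returns the input unchanged with a warning
#'   (except `fill_holes`).
#' @return The transformed [BinaryMask-class].
#' @export
morphology <- function(mask, op = c("erode", "dilate", "close", "open",
                                    "fill_holes"), radiusMm = 0) {
  op <- match.arg(op)
  stopifnot(is(mask, "BinaryMask"), radiusMm >= 0)
  dims <- dim(mask@voxels)
  if (op == "fill_holes") {
    out <- array(cpp_fill_holes(as.logical(mask@voxels), as.integer(dims)),
                 dim = dims)
    return(BinaryMask(out, grid = mask))
  }
  if (radiusMm < min(mask@spacing) / 2) {
    if (radiusMm > 0)
      warning("structuring element smaller than half a voxel; returning input")
    return(mask)
  }
  sp <- mask@spacing
  arr <- mask@voxels
  arr <- switch(op,
    erode  = .morphBall(arr, dims, sp, radiusMm, FALSE),
    dilate = .morphBall(arr, dims, sp, radiusMm, TRUE),
    close  = .morphBall(.morphBall(arr, dims, sp, radiusMm, TRUE),
                        dims, sp, radiusMm, FALSE),
    open   = .morphBall(.morphBall(arr, dims, sp, radiusMm, FALSE),
                        dims, sp, radiusMm, TRUE))
  BinaryMask(arr, grid = mask)
}

#' Connected-component labelling
#'
#' @param mask A [BinaryMask-class].
#' @param connectivity 6 (face) or 26 (face/edge/vertex) neighbourhood.
#' @return Integer array of component labels (0 = background), assigned in
#'   raster-scan order.
#' @export
connectedComponents <- function(mask, connectivity = 26) {
  stopifnot(is(mask, "BinaryMask"), connectivity %in% c(6, 26))
  dims <- dim(mask@voxels)
  array(cpp_label(as.logical(mask@voxels), as.integer(dims),
                  as.integer(connectivity)), dim = dims)
}

#' Keep only the largest connected component
#'
#' Ties are broken towards the component whose first voxel has the lowest
#' linear (column-major) index.
#'
#' @param mask A [BinaryMask-class].
#' @param connectivity 6 or 26.
#' @return A [BinaryMask-class] containing one component (or an empty mask,
#'   with a warning, if the input is empty).
#' @export
largestComponent <- function(mask, connectivity = 26) {
  lab <- connectedComponents(mask, connectivity)
  if (max(lab) == 0L) {
    warning("largestComponent: input mask is empty")
    return(mask)
  }
  sizes <- tabulate(lab)
  keep <- which.max(sizes)  # lowest label among ties = lowest first index
  BinaryMask(lab == keep, grid = mask)
}

#' Drop components smaller than a voxel-count threshold
#'
#' The facial skeleton is not guaranteed singly connected at mask
#' resolution, so pipeline cleanup keeps every component at or above the
#' threshold rather than only the largest.
#'
#' @param mask A [BinaryMask-class].
#' @param minVoxels Minimum component size (voxels) to retain.
#' @param connectivity 6 or 26.
#' @return The cleaned [BinaryMask-class].
#' @export
keepComponents <- function(mask, minVoxels, connectivity = 26) {
  if (minVoxels <= 1) return(mask)
  lab <- connectedComponents(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab)
  keep <- which(sizes >= minVoxels)
  BinaryMask(array(lab %in% keep & lab > 0L, dim = dim(lab)), grid = mask)
}

#' Dice overlap coefficient
#'
#' `2|A . B| / (|A| + |B|)`; defined as 1 when both masks are empty. The
#' quantitative surrogate used throughout for visual mask assessment.
#'
#' @param a,b [BinaryMask-class] objects on the same grid.
#' @return Numeric in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
  if (!sameGrid(a, b)) stop("diceCoefficient: masks are not on the same grid")
  na <- sum(a@voxels); nb <- sum(b@voxels)
  if (na + nb == 0L) return(1.0)
  2 * sum(a@voxels & b@voxels) / (na + nb)
}
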