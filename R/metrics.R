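#' @include morphology.R
NULL

## Boundary voxels: mask voxels with at least one 6-neighbour outside the mask.
.boundaryArray <- function(maskArr, dims) {
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1), c(0, 0, 0))
  er <- array(cpp_morph(as.logical(maskArr), as.integer(dims), offs, 0L),
              dim = dims)
  maskArr & !er
}

#' Mean absolute surface distance between two masks (mm)
#'
#' Symmetric: the average, over boundary voxels of each mask, of the
#' Euclidean distance (anisotropic spacing respected) to the other mask's
#' boundary, averaged over both directions. Returns 0 when both masks are
#' empty and `Inf` when exactly one is.
#'
#' @param a,b [BinaryMask-class] objects on the same grid.
#' @return Distance in millimetres.
#' @export
meanSurfaceDistance <- function(a, b) {
  if (!sameGrid(a, b)) stop("meanSurfaceDistance: masks not on the same grid")
  dims <- dim(a@voxels)
  ba <- .boundaryArray(a@voxels, dims)
  bb <- .boundaryArray(b@voxels, dims)
  if (!any(ba) && !any(bb)) return(0)
  if (!any(ba) || !any(bb)) return(Inf)
  dtb <- sqrt(array(cpp_edt_sq(as.logical(bb), as.integer(dims), a@spacing),
                    dim = dims))
  dta <- sqrt(array(cpp_edt_sq(as.logical(ba), as.integer(dims), a@spacing),
                    dim = dims))
  (mean(dtb[ba]) + mean(dta[bb])) / 2
}

#' Overlap and surface metrics of a mask against ground truth
#'
#' @param mask Candidate [BinaryMask-class].
#' @param truth Reference [BinaryMask-class] on the same grid.
#' @return Named list: `dice`, `recall`, `precision`,
#'   `surface_distance_mm` (symmetric mean absolute surface distance).
#' @export
maskMetrics <- function(mask, truth) {
  if (!sameGrid(mask, truth)) stop("maskMetrics: masks not on the same grid")
  tp <- sum(mask@voxels & truth@voxels)
  nm <- sum(mask@voxels); nt <- sum(truth@voxels)
  list(dice = diceCoefficient(mask, truth),
       recall = if (nt > 0) tp / nt else 1,
       precision = if (nm > 0) tp / nm else 1,
       surface_distance_mm = meanSurfaceDistance(mask, truth))
}

## Fraction of truth-mask voxels present in mask (false-positive rate when
## truth is a structure that should be excluded, e.g. internal air).
.maskedFraction <- function(mask, truth) {
  nt <- sum(truth@voxels)
  if (nt == 0L) return(0)
  sum(mask@voxels & truth@voxels) / nt
}
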