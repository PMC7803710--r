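#' @include AllClasses.R
NULL

## Rotation matrix for Euler angles in degrees, composed Rz %*% Ry %*% Rx.
.rotationMatrix <- function(rotDeg) {
  r <- rotDeg * pi / 180
  ca <- cos(r[1]); sa <- sin(r[1])
  cb <- cos(r[2]); sb <- sin(r[2])
  cc <- cos(r[3]); sc <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

## Euler angles (degrees, Rz Ry Rx convention) from a rotation matrix.
.eulerFromMatrix <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(b)) > 1e-9) {
    a <- atan2(R[3, 2], R[3, 3])
    c <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock: fold everything into a
    a <- atan2(-R[2, 3], R[2, 2])
    c <- 0
  }
  c(a, b, c) * 180 / pi
}

## Affine (A, b) form of a rigid transform: x -> A x + b.
.transformAffine <- function(tf) {
  A <- .rotationMatrix(tf@rotation)
  b <- tf@center + tf@translation - A %*% tf@center
  list(A = A, b = as.numeric(b))
}

#' Apply a rigid transform to physical points
#'
#' @param transform A [RigidTransform-class].
#' @param points Numeric matrix, one point per row (mm, LPS), or a length-3
#'   vector.
#' @return Transformed points in the same shape.
#' @export
transformPoints <- function(transform, points) {
  af <- .transformAffine(transform)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  out <- points %*% t(af$A) + matrix(af$b, nrow(points), 3, byrow = TRUE)
  if (nrow(out) == 1L) as.numeric(out) else out
}

#' Invert a rigid transform
#'
#' @param transform A [RigidTransform-class].
#' @return The inverse [RigidTransform-class] (centre at the origin).
#' @export
invertTransform <- function(transform) {
  af <- .transformAffine(transform)
  Ai <- t(af$A)
  bi <- as.numeric(-Ai %*% af$b)
  RigidTransform(rotation = .eulerFromMatrix(Ai), translation = bi,
                 center = c(0, 0, 0))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [RigidTransform-class] objects.
#' @return The composed [RigidTransform-class] (centre at the origin).
#' @export
composeTransforms <- function(second, first) {
  a2 <- .transformAffine(second)
  a1 <- .transformAffine(first)
  A <- a2$A %*% a1$A
  b <- as.numeric(a2$A %*% a1$b + a2$b)
  RigidTransform(rotation = .eulerFromMatrix(A), translation = b,
                 center = c(0, 0, 0))
}

#' Is a transform the identity?
#'
#' @param transform A [RigidTransform-class].
#' @param tol Tolerance on parameters.
#' @return Logical.
#' @export
isIdentityTransform <- function(transform, tol = 1e-9) {
  all(abs(transform@rotation) < tol) && all(abs(transform@translation) < tol)
}

## ---- grids -----------------------------------------------------------------

## Uniform internal representation of a voxel grid.
.gridOf <- function(x) {
  if (is(x, "ImageVolume") || is(x, "BinaryMask"))
    list(dim = dim(x@voxels), spacing = x@spacing, origin = x@origin,
         direction = x@direction)
  else if (is(x, "BiasField"))
    list(dim = dim(x@values), spacing = x@spacing, origin = x@origin,
         direction = x@direction)
  else if (is.list(x) && all(c("dim", "spacing", "origin", "direction") %in%
                             names(x)))
    x
  else stop("cannot interpret object as a voxel grid")
}

## A centred axis-aligned grid covering extent (mm) at the given spacing.
.makeGrid <- function(extent, spacing) {
  dims <- pmax(2L, as.integer(ceiling(extent / spacing)))
  origin <- -(dims - 1) / 2 * spacing
  list(dim = dims, spacing = spacing, origin = origin, direction = diag(3))
}

#' Do two grid-carrying objects share a voxel grid?
#'
#' @param a,b [ImageVolume-class] or [BinaryMask-class] objects.
#' @param tol Tolerance (mm for spacing/origin, absolute for direction).
#' @return Logical.
#' @export
sameGrid <- function(a, b, tol = 1e-4) {
  ga <- .gridOf(a); gb <- .gridOf(b)
  all(ga$dim == gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) <= tol &&
    max(abs(ga$origin - gb$origin)) <= tol &&
    max(abs(ga$direction - gb$direction)) <= 1e-6
}

## World coordinates (n x 3) of 0-based voxel indices (n x 3).
.indexToWorld <- function(grid, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(idx %*% diag(grid$spacing) %*% t(grid$direction), 2, grid$origin, "+")
}

## Physical corner points of a grid's bounding box.
.gridCorners <- function(grid) {
  d <- grid$dim - 1
  idx <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3])))
  .indexToWorld(grid, idx)
}

## Fraction of target-grid voxel centres falling inside the source volume
## (coarse 8x8x8 probe); used for the anatomy-overlap precondition.
.overlapFraction <- function(sourceGrid, targetGrid) {
  n <- 8L
  probe <- as.matrix(expand.grid(
    seq(0, targetGrid$dim[1] - 1, length.out = n),
    seq(0, targetGrid$dim[2] - 1, length.out = n),
    seq(0, targetGrid$dim[3] - 1, length.out = n)))
  w <- .indexToWorld(targetGrid, probe)
  rel <- sweep(w, 2, sourceGrid$origin, "-") %*% sourceGrid$direction
  cidx <- sweep(rel, 2, sourceGrid$spacing, "/")
  inside <- cidx[, 1] >= 0 & cidx[, 1] <= sourceGrid$dim[1] - 1 &
            cidx[, 2] >= 0 & cidx[, 2] <= sourceGrid$dim[2] - 1 &
            cidx[, 3] >= 0 & cidx[, 3] <= sourceGrid$dim[3] - 1
  mean(inside)
}

## ---- resampling ------------------------------------------------------------

## Low-level array resampler: transform maps target-world -> source-world.
.resampleArray <- function(srcArr, srcGrid, targetGrid, transform,
                           nearest = FALSE, fill = 0) {
  af <- .transformAffine(transform)
  Ss <- diag(srcGrid$spacing)
  St <- diag(targetGrid$spacing)
  DsT <- t(srcGrid$direction)
  M <- diag(1 / srcGrid$spacing) %*% DsT %*% af$A %*% targetGrid$direction %*% St
  off <- diag(1 / srcGrid$spacing) %*% DsT %*%
    (af$A %*% targetGrid$origin + af$b - srcGrid$origin)
  out <- cpp_resample(as.numeric(srcArr), as.integer(dim(srcArr)),
                      as.integer(targetGrid$dim), M, as.numeric(off),
                      as.integer(nearest), fill)
  array(out, dim = targetGrid$dim)
}

#' Resample a volume or mask onto a target grid through a rigid transform
#'
#' The transform maps target-space physical points into source-space physical
#' points (the resampling convention: to pull intensities onto the target
#' grid). With the identity transform, resampling realises a pure grid
#' change, e.g. bringing the coarse ZTE bone mask onto the fine black-bone
#' grid, where the z voxel-size mismatch between sequences lives.
#'
#' @param source An [ImageVolume-class] or [BinaryMask-class].
#' @param targetGrid Object carrying the destination grid (an `ImageVolume`,
#'   `BinaryMask`, or a list with `dim`, `spacing`, `origin`, `direction`).
#' @param transform A [RigidTransform-class] mapping target world coordinates
#'   to source world coordinates; identity by default.
#' @param interpolation `"linear"` or `"nearest"`. Masks always use nearest;
#'   nearest on intensity volumes emits a warning.
#' @param fill Value assigned outside the source volume (default 0).
#' @return Object of the same class as `source`, on the target grid.
#' @export
setGeneric("resample",
  function(source, targetGrid, transform = RigidTransform(),
           interpolation = "linear", fill = 0) standardGeneric("resample"))

#' @rdname resample
setMethod("resample", "ImageVolume",
  function(source, targetGrid, transform = RigidTransform(),
           interpolation = "linear", fill = 0) {
    interpolation <- match.arg(interpolation, c("linear", "nearest"))
    if (interpolation == "nearest")
      warning("nearest-neighbour interpolation on an intensity volume")
    if (isIdentityTransform(transform) && sameGrid(source, targetGrid))
      return(source)  # pure identity: exact, no interpolation round-off
    tg <- .gridOf(targetGrid)
    arr <- .resampleArray(source@voxels, .gridOf(source), tg, transform,
                          nearest = (interpolation == "nearest"), fill = fill)
    ImageVolume(arr, spacing = tg$spacing, origin = tg$origin,
                direction = tg$direction, modality = source@modality,
                meta = source@meta)
  })

#' @rdname resample
setMethod("resample", "BinaryMask",
  function(source, targetGrid, transform = RigidTransform(),
           interpolation = "nearest", fill = 0) {
    tg <- .gridOf(targetGrid)
    arr <- .resampleArray(source@voxels + 0, .gridOf(source), tg, transform,
                          nearest = TRUE, fill = 0)
    BinaryMask(arr > 0.5, spacing = tg$spacing, origin = tg$origin,
               direction = tg$direction)
  })
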