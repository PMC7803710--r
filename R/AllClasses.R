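#' @include CranioSeg-package.R
NULL

.modalities <- c("ZTE", "BB", "FIESTA_C", "DERIVED")

.checkGeometry <- function(dimv, spacing, origin, direction) {
  errs <- character()
  if (length(dimv) != 3L)
    errs <- c(errs, "voxel array must be three-dimensional")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    errs <- c(errs, "spacing must be three strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    errs <- c(errs, "origin must be three finite values")
  if (!is.matrix(direction) || any(dim(direction) != c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    errs <- c(errs, "direction must be a 3x3 orthonormal matrix (tol 1e-6)")
  errs
}

#' ImageVolume: a 3D scalar field with physical grid geometry
#'
#' The universal currency of the segmentation pipelines: a 3D array of real
#' intensities together with its voxel spacing (mm), the physical position of
#' the centre of voxel (0,0,0), a 3x3 orthonormal direction matrix, and a
#' modality tag. World coordinates are LPS millimetres (DICOM convention);
#' voxel indices are 0-based in all geometry computations.
#'
#' @slot voxels 3D numeric array of intensities (arbitrary units).
#' @slot spacing Per-axis voxel size in mm, strictly positive.
#' @slot origin Physical position (mm, LPS) of the centre of voxel (0,0,0).
#' @slot direction 3x3 orthonormal orientation matrix (columns are the
#'   physical directions of the voxel axes).
#' @slot modality One of `"ZTE"`, `"BB"`, `"FIESTA_C"`, `"DERIVED"`.
#' @slot meta Free-form provenance list (e.g. normalisation scale factors).
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix", modality = "character", meta = "list"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), direction = diag(3),
            modality = "DERIVED", meta = list()))

setValidity("ImageVolume", function(object) {
  errs <- .checkGeometry(dim(object@voxels), object@spacing, object@origin,
                         object@direction)
  if (!all(is.finite(object@voxels)))
    errs <- c(errs, "voxels must be finite (no NaN/Inf)")
  if (length(object@modality) != 1L || !(object@modality %in% .modalities))
    errs <- c(errs, paste("modality must be one of:",
                          paste(.modalities, collapse = ", ")))
  if (length(errs)) errs else TRUE
})

#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing Voxel size per axis in mm.
#' @param origin Physical position of voxel (0,0,0) centre, mm (LPS).
#' @param direction 3x3 orthonormal orientation matrix.
#' @param modality Modality tag.
#' @param meta Optional provenance list.
#' @return An [ImageVolume-class] object.
#' @export
ImageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3), modality = "DERIVED",
                        meta = list()) {
  storage.mode(voxels) <- "double"
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction,
      modality = modality, meta = meta)
}

#' BinaryMask: a boolean field sharing an ImageVolume's grid
#'
#' Head masks, skin shells and bone masks. Carries the same geometry fields
#' as [ImageVolume-class]; use [sameGrid()] to check two objects share a grid.
#'
#' @slot voxels 3D logical array.
#' @slot spacing,origin,direction Grid geometry, as for ImageVolume.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), direction = diag(3)))

setValidity("BinaryMask", function(object) {
  errs <- .checkGeometry(dim(object@voxels), object@spacing, object@origin,
                         object@direction)
  if (!is.logical(object@voxels))
    errs <- c(errs, "mask voxels must be logical")
  if (anyNA(object@voxels))
    errs <- c(errs, "mask voxels must not contain NA")
  if (length(errs)) errs else TRUE
})

#' Construct a BinaryMask on the grid of an existing volume or mask
#'
#' @param voxels 3D logical array.
#' @param grid An [ImageVolume-class] or [BinaryMask-class] supplying the
#'   geometry, or `NULL` to pass geometry explicitly.
#' @param spacing,origin,direction Geometry, used when `grid` is `NULL`.
#' @return A [BinaryMask-class].
#' @export
BinaryMask <- function(voxels, grid = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), direction = diag(3)) {
  if (!is.null(grid)) {
    spacing <- grid@spacing; origin <- grid@origin; direction <- grid@direction
  }
  storage.mode(voxels) <- "logical"
  new("BinaryMask", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction)
}

#' RigidTransform: 6-parameter mapping between physical spaces
#'
#' Three Euler angles (degrees, applied as Rz Ry Rx) and three translations
#' (mm) about a rotation centre (mm). Maps a point x to
#' `R (x - c) + c + t`. Models the inter-acquisition motion between the ZTE
#' and high-resolution scans.
#'
#' @slot rotation Euler angles (rx, ry, rz) in degrees.
#' @slot translation Offsets (mm).
#' @slot center Rotation centre (mm).
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric",
                 center = "numeric"),
  prototype(rotation = c(0, 0, 0), translation = c(0, 0, 0),
            center = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  if (length(object@rotation) != 3L || length(object@translation) != 3L ||
      length(object@center) != 3L ||
      any(!is.finite(c(object@rotation, object@translation, object@center))))
    "rotation, translation and center must each be three finite values"
  else TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation Euler angles (degrees), order (rx, ry, rz), composed Rz Ry Rx.
#' @param translation Translation in mm.
#' @param center Rotation centre in mm.
#' @return A [RigidTransform-class].
#' @export
RigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", rotation = as.numeric(rotation),
      translation = as.numeric(translation), center = as.numeric(center))
}

#' BiasField: a smooth multiplicative intensity inhomogeneity field
#'
#' Strictly positive field on an image grid; by convention the mean of its
#' logarithm over the estimation mask is zero, so it carries shading only,
#' not overall scale.
#'
#' @slot values 3D numeric array of multiplicative factors.
#' @slot spacing,origin,direction Grid geometry.
#' @exportClass BiasField
setClass("BiasField",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix"))

setValidity("BiasField", function(object) {
  errs <- .checkGeometry(dim(object@values), object@spacing, object@origin,
                         object@direction)
  if (any(!is.finite(object@values)) || any(object@values <= 0))
    errs <- c(errs, "bias field values must be finite and strictly positive")
  if (min(object@values) < 0.2 || max(object@values) > 5.0)
    errs <- c(errs, "bias field values must lie in [0.2, 5.0]")
  if (length(errs)) errs else TRUE
})

#' SegmentationResult: the output of a bone segmentation pipeline
#'
#' @slot boneMask Final bone mask on the high-resolution grid.
#' @slot renderVolume Intensity-preserving render volume (non-bone suppressed,
#'   bone-dark contrasts inverted so bone renders bright).
#' @slot provenance `"BB_ONLY"` or `"ZTE_DRIVEN"`.
#' @slot config The [PipelineConfig-class] snapshot used.
#' @slot transform The [RigidTransform-class] used to map the high-resolution
#'   grid into ZTE space (identity unless registration was enabled).
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(boneMask = "BinaryMask", renderVolume = "ImageVolume",
                 provenance = "character", config = "ANY",
                 transform = "RigidTransform"))

setValidity("SegmentationResult", function(object) {
  if (!(object@provenance %in% c("BB_ONLY", "ZTE_DRIVEN")))
    "provenance must be BB_ONLY or ZTE_DRIVEN"
  else TRUE
})

#' SeriesMetadata: identifying and rescale metadata for an image series
#'
#' @slot patientID,patientName,seriesDescription Character identifiers
#'   (anonymisable).
#' @slot modality Modality tag written to exported series.
#' @slot spacing,direction Original grid geometry.
#' @slot rescaleSlope,rescaleIntercept Window applied when quantising
#'   intensities for DICOM export.
#' @exportClass SeriesMetadata
setClass("SeriesMetadata",
  representation(patientID = "character", patientName = "character",
                 modality = "character", seriesDescription = "character",
                 spacing = "numeric", direction = "matrix",
                 rescaleSlope = "numeric", rescaleIntercept = "numeric"),
  prototype(patientID = "ANON", patientName = "ANON", modality = "OT",
            seriesDescription = "CranioSeg derived series",
            spacing = c(1, 1, 1), direction = diag(3),
            rescaleSlope = 1, rescaleIntercept = 0))

#' Construct SeriesMetadata
#' @param patientID,patientName,modality,seriesDescription Identifiers.
#' @param spacing,direction Grid geometry.
#' @param rescaleSlope,rescaleIntercept DICOM rescale mapping.
#' @return A [SeriesMetadata-class].
#' @export
SeriesMetadata <- function(patientID = "ANON", patientName = "ANON",
                           modality = "OT",
                           seriesDescription = "CranioSeg derived series",
                           spacing = c(1, 1, 1), direction = diag(3),
                           rescaleSlope = 1, rescaleIntercept = 0) {
  new("SeriesMetadata", patientID = patientID, patientName = patientName,
      modality = modality, seriesDescription = seriesDescription,
      spacing = as.numeric(spacing), direction = direction,
      rescaleSlope = rescaleSlope, rescaleIntercept = rescaleIntercept)
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume [%s]  %d x %d x %d voxels\n", object@modality,
              d[1], d[2], d[3]))
  cat(sprintf("  spacing : %.4g x %.4g x %.4g mm\n", object@spacing[1],
              object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin  : (%.2f, %.2f, %.2f) mm LPS\n", object@origin[1],
              object@origin[2], object@origin[3]))
  r <- range(object@voxels)
  cat(sprintf("  range   : [%.4g, %.4g]\n", r[1], r[2]))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("BinaryMask  %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(object@voxels)))
  cat(sprintf("  spacing : %.4g x %.4g x %.4g mm\n", object@spacing[1],
              object@spacing[2], object@spacing[3]))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(
    "RigidTransform  rot (%.3f, %.3f, %.3f) deg  trans (%.3f, %.3f, %.3f) mm\n",
    object@rotation[1], object@rotation[2], object@rotation[3],
    object@translation[1], object@translation[2], object@translation[3]))
  cat(sprintf("  center  : (%.2f, %.2f, %.2f) mm\n", object@center[1],
              object@center[2], object@center[3]))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult [%s]\n", object@provenance))
  cat(sprintf("  bone voxels : %d\n", sum(object@boneMask@voxels)))
  d <- dim(object@renderVolume@voxels)
  cat(sprintf("  grid        : %d x %d x %d @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@boneMask@spacing[1],
              object@boneMask@spacing[2], object@boneMask@spacing[3]))
})

## ---- accessors -------------------------------------------------------------

#' Accessors for image containers
#'
#' `voxelData` returns the raw array, `voxelSpacing`/`voxelOrigin`/
#' `voxelDirection` the grid geometry, `modality` the modality tag.
#'
#' @param x An [ImageVolume-class], [BinaryMask-class] or [BiasField-class].
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setGeneric("voxelDirection", function(x) standardGeneric("voxelDirection"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
setMethod("voxelData", "ImageVolume", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelData", "BinaryMask", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelData", "BiasField", function(x) x@values)
#' @rdname accessors
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "BinaryMask", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "BiasField", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelOrigin", "ImageVolume", function(x) x@origin)
#' @rdname accessors
setMethod("voxelOrigin", "BinaryMask", function(x) x@origin)
#' @rdname accessors
setMethod("voxelDirection", "ImageVolume", function(x) x@direction)
#' @rdname accessors
setMethod("voxelDirection", "BinaryMask", function(x) x@direction)
#' @rdname accessors
setMethod("modality", "ImageVolume", function(x) x@modality)
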