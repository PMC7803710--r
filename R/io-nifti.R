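#' @include registration.R
NULL

## NIfTI stores RAS world coordinates; the package works in LPS (DICOM).
.lps2ras <- diag(c(-1, -1, 1))

.volumeToAffineRAS <- function(spacing, origin, direction) {
  m <- .lps2ras %*% direction %*% diag(spacing)
  rbind(cbind(m, .lps2ras %*% origin), c(0, 0, 0, 1))
}

.affineRASToGeometry <- function(aff) {
  m <- .lps2ras %*% aff[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("invalid orientation matrix in NIfTI header")
  direction <- sweep(m, 2, spacing, "/")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-4)
    stop("NIfTI orientation matrix is not orthogonal")
  ## re-orthonormalise residual float error
  sv <- svd(direction)
  direction <- sv$u %*% t(sv$v)
  list(spacing = spacing, origin = as.numeric(.lps2ras %*% aff[1:3, 4]),
       direction = direction)
}

.writeNiftiVolume <- function(arr, spacing, origin, direction, path,
                              datatype = "double") {
  im <- RNifti::asNifti(arr, datatype = datatype)
  aff <- .volumeToAffineRAS(spacing, origin, direction)
  im <- RNifti::`sform<-`(im, structure(aff, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

.readNiftiGeometry <- function(im) {
  hdr <- RNifti::niftiHeader(im)
  if (hdr$sform_code == 0 && hdr$qform_code == 0)
    stop("NIfTI file carries no orientation metadata (sform/qform both 0)")
  aff <- RNifti::xform(im)
  .affineRASToGeometry(aff)
}

#' Read a volume from NIfTI or a DICOM series directory
#'
#' DICOM slices are sorted by their position along the slice normal, never
#' by filename. Geometry (spacing, origin, direction; LPS mm) is populated
#' from the headers; absent orientation metadata is an error, never a
#' silent default.
#'
#' @param path A `.nii`/`.nii.gz` file or a directory holding one DICOM
#'   series.
#' @param kind `"auto"` (directory implies DICOM), `"nifti"` or
#'   `"dicom_dir"`.
#' @param modality Modality tag to stamp on the returned volume.
#' @return List with `volume` ([ImageVolume-class]) and `metadata`
#'   ([SeriesMetadata-class]).
#' @export
readVolume <- function(path, kind = c("auto", "nifti", "dicom_dir"),
                       modality = "DERIVED") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("readVolume: path does not exist: ", path)
  if (kind == "auto") kind <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (kind == "dicom_dir") return(.readDicomSeries(path, modality))
  im <- RNifti::readNifti(path)
  geo <- .readNiftiGeometry(im)
  arr <- array(as.numeric(im), dim = dim(im))
  vol <- ImageVolume(arr, spacing = geo$spacing, origin = geo$origin,
                     direction = geo$direction, modality = modality)
  meta <- SeriesMetadata(spacing = geo$spacing, direction = geo$direction)
  list(volume = vol, metadata = meta)
}

#' Write a volume as NIfTI or as a DICOM series
#'
#' NIfTI round-trips voxel data exactly (64-bit float). DICOM export
#' quantises to unsigned 16-bit with the rescale slope/intercept recorded in
#' the headers, so applying them recovers intensities within one
#' quantisation step; slice files carry monotone positions along the slice
#' normal.
#'
#' @param volume An [ImageVolume-class].
#' @param path Output file (NIfTI) or directory (DICOM series).
#' @param kind `"nifti"` or `"dicom_dir"`.
#' @param meta Optional [SeriesMetadata-class] for DICOM export.
#' @return Invisibly, the path written.
#' @export
writeVolume <- function(volume, path, kind = c("nifti", "dicom_dir"),
                        meta = NULL) {
  kind <- match.arg(kind)
  stopifnot(is(volume, "ImageVolume"))
  if (kind == "nifti")
    return(invisible(.writeNiftiVolume(volume@voxels, volume@spacing,
                                       volume@origin, volume@direction,
                                       path)))
  .writeDicomSeries(volume, path, meta)
}

#' Read or write a binary mask as NIfTI
#'
#' Masks are stored with values {0, 1} (unsigned 8-bit).
#'
#' @param mask A [BinaryMask-class].
#' @param path NIfTI file path.
#' @return `writeMask` returns the path invisibly; `readMask` a
#'   [BinaryMask-class].
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  invisible(.writeNiftiVolume(mask@voxels + 0, mask@spacing, mask@origin,
                              mask@direction, path, datatype = "uint8"))
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  im <- RNifti::readNifti(path)
  geo <- .readNiftiGeometry(im)
  BinaryMask(array(as.numeric(im) > 0.5, dim = dim(im)),
             spacing = geo$spacing, origin = geo$origin,
             direction = geo$direction)
}
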