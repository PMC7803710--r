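#' @include mesh.R
NULL

#' PipelineConfig: every tunable of the segmentation pipelines
#'
#' Centralises the thresholds, radii and flags the algorithms depend on, and
#' serialises losslessly to YAML. Defaults reproduce the published pipeline
#' behaviour on the bundled phantom; every value is overridable.
#'
#' @slot denoiseMethod `"curvature_flow"` (edge-preserving, default),
#'   `"gaussian"`, or `"none"`.
#' @slot denoiseStrength Iterations for curvature flow; Gaussian sigma in mm.
#' @slot headmaskThresholdMethod `"otsu"` (default) or `"fixed"`.
#' @slot headmaskThresholdValue Threshold when the method is `"fixed"`.
#' @slot headmaskCloseRadiusMm Morphological closing radius for the head
#'   mask (mm).
#' @slot skinThicknessMm Depth of the scalp shell eroded off the head mask
#'   before bone classification (mm).
#' @slot zteBoneLow,zteBoneHigh Bone window on the negative-log normalised
#'   ZTE intensity `-ln(I/1000)`: soft tissue sits near 0, air far above;
#'   bone is the intermediate band.
#' @slot zteOpenRadiusMm Morphological opening radius applied to the ZTE
#'   bone mask (mm); 0 disables it, preserving bone thinner than the ZTE
#'   voxel (orbital walls).
#' @slot zteAirGuardMm Voxels within this distance of clearly-air ZTE
#'   voxels (above `zteBoneHigh` on the negative-log scale) are excluded
#'   from the ZTE bone mask. This exploits ZTE's defining ability to
#'   identify air, and suppresses the partial-volume rim around air
#'   cavities that would otherwise masquerade as bone.
#' @slot bbBoneThreshold Bone/air candidate threshold on the high-resolution
#'   volume, as a fraction of the soft-tissue reference intensity.
#' @slot searchDilationMm Dilation of the grid-transferred ZTE bone mask
#'   forming the search region in which dark high-resolution voxels are
#'   accepted as bone.
#' @slot minComponentVoxels Components smaller than this are dropped during
#'   mask cleanup.
#' @slot registrationEnabled Run rigid mutual-information registration
#'   between ZTE and the high-resolution volume (default `FALSE`: header
#'   geometry only).
#' @slot renderWindowLow,renderWindowHigh Intensity window mapped onto
#'   `[0, 32767]` for the render volume.
#' @slot seed Seed forwarded to any stochastic stage (none by default).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(denoiseMethod = "character", denoiseStrength = "numeric",
                 headmaskThresholdMethod = "character",
                 headmaskThresholdValue = "numeric",
                 headmaskCloseRadiusMm = "numeric",
                 skinThicknessMm = "numeric",
                 zteBoneLow = "numeric", zteBoneHigh = "numeric",
                 zteOpenRadiusMm = "numeric", zteAirGuardMm = "numeric",
                 bbBoneThreshold = "numeric", searchDilationMm = "numeric",
                 minComponentVoxels = "numeric",
                 registrationEnabled = "logical",
                 renderWindowLow = "numeric", renderWindowHigh = "numeric",
                 seed = "numeric"))

setValidity("PipelineConfig", function(object) {
  errs <- character()
  if (!(object@denoiseMethod %in% c("curvature_flow", "gaussian", "none")))
    errs <- c(errs, "denoiseMethod must be curvature_flow, gaussian or none")
  if (!(object@headmaskThresholdMethod %in% c("otsu", "fixed")))
    errs <- c(errs, "headmaskThresholdMethod must be otsu or fixed")
  radii <- c(object@headmaskCloseRadiusMm, object@skinThicknessMm,
             object@zteOpenRadiusMm, object@zteAirGuardMm,
             object@searchDilationMm)
  if (any(radii < 0)) errs <- c(errs, "all radii must be >= 0")
  if (object@zteBoneLow >= object@zteBoneHigh)
    errs <- c(errs, "zteBoneLow must be < zteBoneHigh")
  if (object@renderWindowLow >= object@renderWindowHigh)
    errs <- c(errs, "renderWindowLow must be < renderWindowHigh")
  if (object@bbBoneThreshold <= 0 || object@bbBoneThreshold >= 1)
    errs <- c(errs, "bbBoneThreshold must be in (0, 1)")
  if (length(errs)) errs else TRUE
})

#' Construct a PipelineConfig
#'
#' @param ... Named overrides of the defaults documented in
#'   [PipelineConfig-class].
#' @return A validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    denoiseMethod = "curvature_flow", denoiseStrength = 3,
    headmaskThresholdMethod = "otsu", headmaskThresholdValue = 0,
    headmaskCloseRadiusMm = 2, skinThicknessMm = 3,
    zteBoneLow = 0.15, zteBoneHigh = 1.5, zteOpenRadiusMm = 0,
    zteAirGuardMm = 2,
    bbBoneThreshold = 0.35, searchDilationMm = 3,
    minComponentVoxels = 100, registrationEnabled = FALSE,
    renderWindowLow = 0, renderWindowHigh = 1500, seed = 42)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  vals <- defaults
  vals[names(over)] <- over
  do.call(new, c(list("PipelineConfig"), vals))
}

.configAsList <- function(config) {
  slots <- slotNames("PipelineConfig")
  out <- lapply(slots, function(s) slot(config, s))
  names(out) <- slots
  out
}

#' Read / write a pipeline configuration as YAML
#'
#' Key names match the [PipelineConfig-class] slot names exactly and the
#' round trip is lossless.
#'
#' @param config A [PipelineConfig-class].
#' @param path YAML file path.
#' @return `writePipelineConfig` the path invisibly; `readPipelineConfig`
#'   a [PipelineConfig-class].
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  for (s in slotNames("PipelineConfig"))
    cat(sprintf("  %-24s %s\n", s, format(slot(object, s))))
})
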