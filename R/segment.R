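#' @include preprocess.R
NULL

#' Segment bone on a preprocessed ZTE volume
#'
#' ZTE detects signal from cortical bone, so bone separates from air: on the
#' negative-log normalised intensity `x = -ln(I / 1000)`, soft tissue sits
#' near 0, bone in an intermediate band, and air far above. Voxels with
#' `x` in `[zteBoneLow, zteBoneHigh]` inside the head mask are classified
#' bone, optionally opened, and cleaned of small components. Background air
#' (outside the head) is excluded entirely.
#'
#' @param zte Preprocessed [ImageVolume-class]: denoised, bias-corrected,
#'   normalised so the interior median is 1000. A deviation of more than
#'   10 percent is an error.
#' @param config A [PipelineConfig-class].
#' @param head Optional head [BinaryMask-class]; computed from `zte` when
#'   missing.
#' @param interior Optional interior mask used only for the normalisation
#'   check; defaults to `head`.
#' @return Bone [BinaryMask-class] on the ZTE grid.
#' @export
zteBoneMask <- function(zte, config = pipelineConfig(), head = NULL,
                        interior = NULL) {
  stopifnot(is(zte, "ImageVolume"))
  if (is.null(head)) head <- headMask(zte, config)
  if (is.null(interior)) interior <- head
  med <- median(zte@voxels[interior@voxels])
  if (abs(med - 1000) > 100)
    stop("zteBoneMask: input is not normalised (interior median ",
         round(med), ", expected 1000 +/- 10%)")
  x <- -log(pmax(zte@voxels, 1e-3) / 1000)
  bone <- BinaryMask(x >= config@zteBoneLow & x <= config@zteBoneHigh &
                       head@voxels, grid = zte)
  if (config@zteAirGuardMm > 0) {
    ## air is what ZTE can see: keep bone clear of identified air so the
    ## partial-volume rim around cavities is not mistaken for bone
    airGuard <- morphology(BinaryMask(x > config@zteBoneHigh, grid = zte),
                           "dilate", config@zteAirGuardMm)
    bone <- BinaryMask(bone@voxels & !airGuard@voxels, grid = zte)
  }
  if (config@zteOpenRadiusMm > 0)
    bone <- morphology(bone, "open", config@zteOpenRadiusMm)
  keepComponents(bone, config@minComponentVoxels)
}

#' Bone/air candidate voxels on a black-bone or FIESTA-C volume
#'
#' In black-bone contrast, cortical bone returns minimal signal and soft
#' tissue is uniformly bright; FIESTA-C likewise renders bone dark. Voxels
#' below `bbBoneThreshold` times the soft-tissue reference, inside the
#' skin-removed interior, become candidates. By construction this mask
#' conflates bone with internal air — the two are indistinguishable in
#' these contrasts — which is exactly the limitation the ZTE-driven
#' pipeline exists to resolve.
#'
#' @param highres Preprocessed [ImageVolume-class] (interior median 1000).
#' @param interior Skin-removed head [BinaryMask-class].
#' @param config A [PipelineConfig-class].
#' @return Candidate [BinaryMask-class].
#' @export
bbBoneCandidates <- function(highres, interior, config = pipelineConfig()) {
  stopifnot(is(highres, "ImageVolume"), is(interior, "BinaryMask"))
  if (!any(interior@voxels))
    stop("bbBoneCandidates: interior mask is empty")
  ref <- median(highres@voxels[interior@voxels])
  BinaryMask(highres@voxels < config@bbBoneThreshold * ref &
               interior@voxels, grid = highres)
}

#' Intensity-preserving render volume from a bone mask
#'
#' Rather than delivering a binary mask, the output keeps the windowed
#' intensities so the end user can tune the volume rendering with their own
#' anatomical judgement. For bone-dark contrasts the intensities are
#' inverted (`32767 - v`) so bone renders bright, then multiplied by the
#' bone mask dilated by one voxel (a halo retaining the cortical surface
#' gradient); everything else is zeroed.
#'
#' @param highres Render-windowed [ImageVolume-class] (see
#'   [rescaleForRender()]).
#' @param bone Final bone [BinaryMask-class] on the same grid.
#' @param config A [PipelineConfig-class].
#' @return The render [ImageVolume-class], modality `"DERIVED"`.
#' @export
makeRenderVolume <- function(highres, bone, config = pipelineConfig()) {
  stopifnot(is(highres, "ImageVolume"), is(bone, "BinaryMask"))
  if (!sameGrid(highres, bone))
    stop("makeRenderVolume: volume and mask grids differ")
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) <= 1, , drop = FALSE]  # 6-neighbour halo
  halo <- .morphOnce(bone@voxels, dim(bone@voxels), offs, 1L)
  v <- (32767 - highres@voxels) * halo
  ImageVolume(v, spacing = highres@spacing, origin = highres@origin,
              direction = highres@direction, modality = "DERIVED",
              meta = highres@meta)
}

#' Black-bone-only segmentation pipeline
#'
#' The baseline fully automated algorithm: denoising, intensity
#' normalisation, head mask generation, bias correction, skin removal,
#' dark-voxel bone classification, component cleanup, render windowing and
#' masking. Its known failure mode — internal air (sinus, oropharynx)
#' classified as bone — is inherent to the contrast and is reproduced, not
#' hidden.
#'
#' @param bb Raw black-bone (or FIESTA-C) [ImageVolume-class].
#' @param config A [PipelineConfig-class].
#' @return A [SegmentationResult-class] with provenance `"BB_ONLY"`.
#' @export
bbOnlyPipeline <- function(bb, config = pipelineConfig()) {
  pp <- .preprocessVolume(bb, config)
  cand <- bbBoneCandidates(pp$volume, pp$interior, config)
  bone <- keepComponents(cand, config@minComponentVoxels)
  rv <- rescaleForRender(pp$volume, config)
  render <- makeRenderVolume(rv, bone, config)
  new("SegmentationResult", boneMask = bone, renderVolume = render,
      provenance = "BB_ONLY", config = config,
      transform = RigidTransform())
}

#' ZTE-driven segmentation of high-resolution black-bone or FIESTA-C data
#'
#' ZTE identifies where bone is; the high-resolution volume delineates it.
#' The ZTE volume is preprocessed and its bone mask segmented on the ZTE
#' grid; the mask is brought onto the high-resolution grid (nearest
#' neighbour, optionally through a rigid registration, otherwise header
#' geometry alone) and dilated by `searchDilationMm` into a search region.
#' Dark high-resolution candidates are accepted as bone only inside that
#' region, so internal air and non-bony dark structures (tendons, muscle
#' attachments) outside the ZTE bone neighbourhood are excluded.
#'
#' @param zte Raw ZTE [ImageVolume-class].
#' @param highres Raw black-bone or FIESTA-C [ImageVolume-class] of the
#'   same head (modality `"BB"` or `"FIESTA_C"`).
#' @param config A [PipelineConfig-class]; set `registrationEnabled` to
#'   correct inter-acquisition motion.
#' @return A [SegmentationResult-class] with provenance `"ZTE_DRIVEN"`.
#' @export
zteDrivenPipeline <- function(zte, highres, config = pipelineConfig()) {
  stopifnot(is(zte, "ImageVolume"), is(highres, "ImageVolume"))
  if (!(highres@modality %in% c("BB", "FIESTA_C")))
    stop("zteDrivenPipeline: highres modality must be BB or FIESTA_C")
  if (.overlapFraction(.gridOf(zte), .gridOf(highres)) < 0.3)
    stop("zteDrivenPipeline: volumes do not cover the same anatomy")
  ppz <- .preprocessVolume(zte, config)
  zmask <- zteBoneMask(ppz$volume, config, head = ppz$headMask,
                       interior = ppz$interior)
  tf <- if (config@registrationEnabled) registerRigid(zte, highres)
        else RigidTransform()
  search <- resample(zmask, highres, transform = tf)
  search <- morphology(search, "dilate", config@searchDilationMm)
  pph <- .preprocessVolume(highres, config)
  cand <- bbBoneCandidates(pph$volume, pph$interior, config)
  bone <- BinaryMask(cand@voxels & search@voxels, grid = cand)
  bone <- keepComponents(bone, config@minComponentVoxels)
  rv <- rescaleForRender(pph$volume, config)
  render <- makeRenderVolume(rv, bone, config)
  new("SegmentationResult", boneMask = bone, renderVolume = render,
      provenance = "ZTE_DRIVEN", config = config, transform = tf)
}
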