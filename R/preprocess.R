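#' @include config.R
NULL

## Otsu's threshold on a numeric vector (256-bin histogram).
.otsuThreshold <- function(values, bins = 256) {
  r <- range(values)
  if (diff(r) == 0) stop("cannot threshold a constant image")
  h <- tabulate(pmin(bins, 1L + floor((values - r[1]) / diff(r) * bins)),
                nbins = bins)
  p <- h / sum(h)
  centres <- r[1] + (seq_len(bins) - 0.5) / bins * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * centres)
  muT <- mu[bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, bins)
  between[valid] <- (muT * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  centres[which.max(between)]
}

#' Denoise a volume
#'
#' Default method is level-set curvature flow, chosen for edge preservation:
#' thin cortical bone (the orbital walls) must not be blurred into
#' neighbouring tissue. `"gaussian"` smooths with a physical-space sigma of
#' `denoiseStrength` mm; `"none"` is the identity.
#'
#' @param volume An [ImageVolume-class].
#' @param config A [PipelineConfig-class].
#' @return The denoised [ImageVolume-class].
#' @export
denoise <- function(volume, config = pipelineConfig()) {
  stopifnot(is(volume, "ImageVolume"))
  method <- config@denoiseMethod
  if (method == "none") return(volume)
  d <- dim(volume@voxels)
  arr <- if (method == "gaussian") {
    sig <- config@denoiseStrength / volume@spacing
    array(cpp_gauss(as.numeric(volume@voxels), as.integer(d), sig), dim = d)
  } else {
    array(cpp_curvature_flow(as.numeric(volume@voxels), as.integer(d),
                             as.integer(round(config@denoiseStrength)), 0.1),
          dim = d)
  }
  ImageVolume(arr, spacing = volume@spacing, origin = volume@origin,
              direction = volume@direction, modality = volume@modality,
              meta = volume@meta)
}

#' Generate the head mask
#'
#' Thresholds the (denoised) volume so the head — all tissue plus internal
#' cavities — separates from background air, closes the result, keeps the
#' largest connected component and fills internal cavities, so sinus and
#' oropharynx air ends up inside the mask. Works on any of the three
#' modalities: in each, tissue is brighter than the surrounding air.
#'
#' @param volume Denoised [ImageVolume-class].
#' @param config A [PipelineConfig-class].
#' @return A single-component, hole-free [BinaryMask-class].
#' @export
headMask <- function(volume, config = pipelineConfig()) {
  stopifnot(is(volume, "ImageVolume"))
  thr <- if (config@headmaskThresholdMethod == "otsu")
    .otsuThreshold(as.numeric(volume@voxels))
  else config@headmaskThresholdValue
  fg <- volume@voxels > thr
  if (!any(fg)) stop("head_mask: no head found (empty threshold result)")
  m <- BinaryMask(fg, grid = volume)
  m <- morphology(m, "close", config@headmaskCloseRadiusMm)
  m <- largestComponent(m, connectivity = 26)
  if (sum(m@voxels) < config@minComponentVoxels)
    stop("head_mask: no head found (largest component below minComponentVoxels)")
  morphology(m, "fill_holes")
}

#' Estimate and remove a smooth multiplicative bias field
#'
#' Fits a smooth shading field in the log domain inside the head mask: an
#' iteratively-reweighted (Tukey bisquare) quadratic polynomial in world
#' coordinates, so tissue structure — the dark bone/air tail — is
#' downweighted as outliers and only the slowly-varying coil inhomogeneity
#' is captured. The fitted log-field is centred to mean zero over the mask
#' (shading only, no overall rescale), exponentiated, and divided out.
#'
#' @param volume An [ImageVolume-class] with non-negative intensities.
#' @param mask Head [BinaryMask-class] delimiting the fit.
#' @param config A [PipelineConfig-class].
#' @param maxSamples Voxel subsample size for the fit.
#' @return List with `volume` (corrected [ImageVolume-class]) and `field`
#'   (the [BiasField-class] divided out).
#' @export
estimateAndCorrectBias <- function(volume, mask, config = pipelineConfig(),
                                   maxSamples = 40000) {
  stopifnot(is(volume, "ImageVolume"), is(mask, "BinaryMask"))
  if (!sameGrid(volume, mask))
    stop("estimateAndCorrectBias: volume and mask grids differ")
  inMask <- which(mask@voxels & volume@voxels > 0)
  if (!length(inMask))
    stop("estimateAndCorrectBias: masked region has no positive intensities")
  stride <- max(1L, length(inMask) %/% maxSamples)
  sel <- inMask[seq(1L, length(inMask), by = stride)]
  d <- dim(volume@voxels)
  ijk <- arrayInd(sel, d) - 1L
  w <- .indexToWorld(.gridOf(volume), ijk)
  ## normalise coordinates to [-1, 1] over the mask bounding box
  ctr <- (apply(w, 2, max) + apply(w, 2, min)) / 2
  hw <- pmax((apply(w, 2, max) - apply(w, 2, min)) / 2, 1e-6)
  u <- sweep(sweep(w, 2, ctr), 2, hw, "/")
  X <- cbind(1, u, u^2, u[, 1] * u[, 2], u[, 1] * u[, 3], u[, 2] * u[, 3])
  y <- log(volume@voxels[sel])
  wt <- rep(1, length(y))
  beta <- NULL
  for (it in 1:8) {
    fit <- lm.wfit(X, y, wt)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    res <- as.numeric(y - X %*% beta)
    s <- mad(res)
    if (s < 1e-8) break
    r <- abs(res) / (4.685 * s)
    wt <- as.numeric(ifelse(r < 1, (1 - r^2)^2, 0))
    if (sum(wt) < 10) { wt <- rep(1, length(y)); break }
  }
  ## evaluate the log-field over the whole grid, slice by slice
  grid <- .gridOf(volume)
  logf <- array(0, dim = d)
  sliceIdx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1)))
  for (k in seq_len(d[3])) {
    wS <- .indexToWorld(grid, cbind(sliceIdx, k - 1L))
    uS <- sweep(sweep(wS, 2, ctr), 2, hw, "/")
    XS <- cbind(1, uS, uS^2, uS[, 1] * uS[, 2], uS[, 1] * uS[, 3],
                uS[, 2] * uS[, 3])
    logf[, , k] <- as.numeric(XS %*% beta)
  }
  logf <- logf - mean(logf[mask@voxels])  # shading only, mean log = 0
  fieldArr <- pmin(pmax(exp(logf), 0.2), 5)
  field <- new("BiasField", values = fieldArr, spacing = volume@spacing,
               origin = volume@origin, direction = volume@direction)
  corrected <- ImageVolume(volume@voxels / fieldArr, spacing = volume@spacing,
                           origin = volume@origin,
                           direction = volume@direction,
                           modality = volume@modality, meta = volume@meta)
  list(volume = corrected, field = field)
}

#' Remove the scalp/skin shell from a head mask
#'
#' Erodes the head mask inward by `skinThicknessMm` with a physical-space
#' ball, so the removed shell has the configured thickness along surface
#' normals regardless of grid anisotropy.
#'
#' @param head Head [BinaryMask-class].
#' @param config A [PipelineConfig-class].
#' @return The interior [BinaryMask-class].
#' @export
removeSkin <- function(head, config = pipelineConfig()) {
  stopifnot(is(head, "BinaryMask"))
  if (config@skinThicknessMm == 0) return(head)
  out <- morphology(head, "erode", config@skinThicknessMm)
  if (!any(out@voxels))
    stop("remove_skin: skin thickness exceeds head radius")
  out
}

#' Normalise intensities to a fixed soft-tissue reference
#'
#' A single linear scale (no offset) mapping the median intensity over the
#' interior mask to 1000. The median is robust against the dark bone/air
#' tail of the interior histogram. The applied factor is recorded in the
#' result's `meta$normalisationScale`.
#'
#' @param volume An [ImageVolume-class].
#' @param interior Nonempty [BinaryMask-class] of reference tissue.
#' @return The rescaled [ImageVolume-class].
#' @export
normaliseIntensity <- function(volume, interior) {
  stopifnot(is(volume, "ImageVolume"), is(interior, "BinaryMask"))
  if (!any(interior@voxels)) stop("normaliseIntensity: interior mask is empty")
  med <- median(volume@voxels[interior@voxels])
  if (med <= 0) stop("normaliseIntensity: interior median is not positive")
  scale <- 1000 / med
  meta <- volume@meta
  meta$normalisationScale <- scale
  ImageVolume(volume@voxels * scale, spacing = volume@spacing,
              origin = volume@origin, direction = volume@direction,
              modality = volume@modality, meta = meta)
}

#' Window and rescale intensities for rendering
#'
#' Clamps intensities to `[renderWindowLow, renderWindowHigh]` and affinely
#' maps that window onto `[0, 32767]`. Monotone, so relative soft-tissue /
#' bone contrast survives for end-user volume rendering.
#'
#' @param volume Normalised [ImageVolume-class].
#' @param config A [PipelineConfig-class].
#' @return The windowed [ImageVolume-class].
#' @export
rescaleForRender <- function(volume, config = pipelineConfig()) {
  lo <- config@renderWindowLow
  hi <- config@renderWindowHigh
  if (lo >= hi) stop("rescaleForRender: degenerate render window")
  v <- pmin(pmax(volume@voxels, lo), hi)
  v <- (v - lo) / (hi - lo) * 32767
  meta <- volume@meta
  meta$renderWindow <- c(lo, hi)
  ImageVolume(v, spacing = volume@spacing, origin = volume@origin,
              direction = volume@direction, modality = volume@modality,
              meta = meta)
}

## Shared front half of both pipelines: denoise -> provisional normalisation
## -> head mask -> bias correction -> skin removal -> exact re-normalisation
## (interior median pinned to 1000, the scale downstream thresholds assume).
.preprocessVolume <- function(volume, config) {
  den <- denoise(volume, config)
  thr <- .otsuThreshold(as.numeric(den@voxels))
  fg <- den@voxels > thr
  if (!any(fg)) stop("preprocess: no foreground found")
  norm1 <- normaliseIntensity(den, BinaryMask(fg, grid = den))
  hm <- headMask(norm1, config)
  bc <- estimateAndCorrectBias(norm1, hm, config)
  interior <- removeSkin(hm, config)
  norm <- normaliseIntensity(bc$volume, interior)
  list(volume = norm, headMask = hm, interior = interior,
       biasField = bc$field)
}
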