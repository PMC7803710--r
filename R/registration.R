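#' @include metrics.R
NULL

## Intensity-weighted centre of mass in world coordinates.
.centreOfMass <- function(vol) {
  arr <- vol@voxels
  w <- arr - min(arr)
  s <- sum(w)
  if (s <= 0) stop("registerRigid: volume has no foreground (constant image)")
  d <- dim(arr)
  ix <- array(rep(0:(d[1] - 1), times = d[2] * d[3]), dim = d)
  iy <- array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), dim = d)
  iz <- array(rep(0:(d[3] - 1), each = d[1] * d[2]), dim = d)
  idx <- c(sum(w * ix), sum(w * iy), sum(w * iz)) / s
  as.numeric(.indexToWorld(.gridOf(vol), idx))
}

## Normalised mutual information (H(A)+H(B))/H(A,B) from paired samples.
.nmi <- function(fixedVals, movingVals, bins, fr, mr) {
  h <- cpp_joint_hist(fixedVals, movingVals, bins, fr[1], fr[2], mr[1], mr[2])
  n <- sum(h)
  if (n < 100) return(0)  # essentially no overlap
  p <- h / n
  px <- rowSums(matrix(p, bins, bins))
  py <- colSums(matrix(p, bins, bins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hj <- ent(p)
  if (hj <= 0) return(0)
  (ent(px) + ent(py)) / hj
}

## Coarse version of the fixed grid at the requested isotropic spacing.
.coarseGrid <- function(grid, iso) {
  extent <- (grid$dim - 1) * grid$spacing
  dims <- pmax(8L, as.integer(ceiling(extent / iso)) + 1L)
  list(dim = dims, spacing = rep(iso, 3), origin = grid$origin,
       direction = grid$direction)
}

#' Rigid registration of two volumes by mutual information
#'
#' Estimates the 6-parameter rigid transform mapping fixed-space physical
#' points into moving-space physical points (the convention `resample` needs
#' to pull the moving volume onto the fixed grid). Normalised mutual
#' information is the similarity, because the two inputs generally have
#' different contrasts (ZTE vs black-bone). The optimiser is a deterministic
#' multi-resolution Nelder-Mead initialised at centre-of-mass alignment.
#' If the optimum does not improve on the initialisation, the
#' centre-of-mass transform is returned with a warning.
#'
#' @param moving,fixed [ImageVolume-class] objects covering the same anatomy.
#' @param levels Isotropic sampling spacings (mm) of the coarse-to-fine
#'   schedule.
#' @param bins Joint-histogram bins per axis.
#' @param maxit Nelder-Mead iterations per level.
#' @return A [RigidTransform-class] (fixed world -> moving world).
#' @export
registerRigid <- function(moving, fixed, levels = c(6, 3, 1.5), bins = 32,
                          maxit = 400) {
  stopifnot(is(moving, "ImageVolume"), is(fixed, "ImageVolume"))
  fg <- .gridOf(fixed)
  mg <- .gridOf(moving)
  if (.overlapFraction(mg, fg) < 0.05)
    stop("registerRigid: volumes do not overlap in physical space")
  comF <- .centreOfMass(fixed)
  comM <- .centreOfMass(moving)
  center <- comF
  p0 <- c(0, 0, 0, comM - comF)
  mr <- range(moving@voxels)
  frange <- range(fixed@voxels)
  if (diff(mr) == 0 || diff(frange) == 0)
    stop("registerRigid: volume has no foreground (constant image)")

  p <- p0
  nmi0Final <- NA_real_
  for (iso in levels) {
    cg <- .coarseGrid(fg, iso)
    ## anti-alias both images towards the level's sampling density
    sigF <- pmax(0, iso / (2 * fg$spacing))
    fArr <- array(cpp_gauss(as.numeric(fixed@voxels), as.integer(fg$dim),
                            sigF), dim = fg$dim)
    sigM <- pmax(0, iso / (2 * mg$spacing))
    mArr <- array(cpp_gauss(as.numeric(moving@voxels), as.integer(mg$dim),
                            sigM), dim = mg$dim)
    fixedCoarse <- .resampleArray(fArr, fg, cg, RigidTransform(),
                                  nearest = FALSE, fill = NA_real_)
    fv <- as.numeric(fixedCoarse)
    ## restrict the metric to the fixed foreground (plus a one-voxel rim):
    ## background air carries no alignment information and dilutes NMI
    ok <- !is.na(fv)
    if (any(ok)) {
      thr <- .otsuThreshold(fv[ok])
      fgMask <- array(FALSE, dim = cg$dim)
      fgMask[ok] <- fv[ok] > thr
      offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      fgMask <- .morphOnce(fgMask, cg$dim, offs, 1L)
      fv[!fgMask] <- NA_real_
    }
    objective <- function(par) {
      tf <- RigidTransform(rotation = par[1:3], translation = par[4:6],
                           center = center)
      mv <- .resampleArray(mArr, mg, cg, tf, nearest = FALSE,
                           fill = NA_real_)
      .nmi(fv, as.numeric(mv), bins, frange, mr)
    }
    nmi0 <- objective(p)
    opt <- optim(p, objective, method = "Nelder-Mead",
                 control = list(fnscale = -1, maxit = maxit,
                                reltol = 1e-8))
    if (opt$value > nmi0) p <- opt$par
    if (iso == levels[length(levels)])
      nmi0Final <- c(init = objective(p0), final = max(opt$value, nmi0))
  }
  if (nmi0Final["final"] <= nmi0Final["init"] + 1e-12 &&
      !isTRUE(all.equal(p, p0))) {
    warning("registerRigid: similarity not improved; returning centre-of-mass initialisation")
    p <- p0
  }
  RigidTransform(rotation = p[1:3], translation = p[4:6], center = center)
}
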