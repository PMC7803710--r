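#' @include segment.R
NULL

#' PhantomSpec: parameterisation of the synthetic digital head
#'
#' A compact parametric head — ellipsoidal scalp, closed skull shell with
#' thin patches at the orbits and vertex, internal air cavities (frontal
#' sinus, oropharynx), optional muscle/tendon confounders — rasterised on a
#' fine master grid and resampled onto the three acquisition grids. The
#' per-modality intensity triplets emulate the contrasts: black-bone has
#' bone and air equally dark under uniform soft tissue; ZTE separates air
#' (dark) from bone (intermediate) and soft tissue (bright); FIESTA-C is
#' bone/air dark with very bright fluid.
#'
#' @slot name Spec name.
#' @slot headSemiAxes Scalp ellipsoid semi-axes (mm).
#' @slot skullThicknessMm Base skull shell thickness (mm).
#' @slot thinPatchThicknessMm Shell thickness inside the thin patches (mm).
#' @slot thinPatches List of `list(center, radius)` spheres (mm) marking
#'   orbit/vertex regions where the shell thins.
#' @slot skinThicknessMm Scalp layer thickness (mm).
#' @slot airCavities List of `list(center, semiAxes, kind)` ellipsoids,
#'   `kind` `"air"` or `"fluid"`, carved from soft tissue (clipped at the
#'   inner table, so a cavity placed against the skull shares a wall with
#'   bone).
#' @slot confounders List of `list(center, semiAxes, intensity)` ellipsoids
#'   with per-modality intensity (named `ZTE`, `BB`, `FIESTA_C`).
#' @slot intensities Per-modality named list of `c(air, bone, soft)` levels
#'   (plus `fluid` for FIESTA_C).
#' @slot noiseSigma Rician noise sigma (same units as intensities).
#' @slot biasAmplitude Log-linear bias amplitude `a`: the field runs from
#'   `1/(1+a)` to `(1+a)` across the head along `biasDirection`.
#' @slot biasDirection Direction (mm space) of the bias gradient.
#' @slot motion Inter-acquisition [RigidTransform-class] applied to the ZTE
#'   acquisition (identity = no motion).
#' @slot grids Named list of per-modality voxel spacings (mm).
#' @slot masterSpacingMm Isotropic master label grid spacing (mm).
#' @slot marginMm Background margin around the head (mm).
#' @slot seed Integer seed making generation bit-reproducible.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(name = "character", headSemiAxes = "numeric",
                 skullThicknessMm = "numeric",
                 thinPatchThicknessMm = "numeric", thinPatches = "list",
                 skinThicknessMm = "numeric", airCavities = "list",
                 confounders = "list", intensities = "list",
                 noiseSigma = "numeric", biasAmplitude = "numeric",
                 biasDirection = "numeric", motion = "RigidTransform",
                 grids = "list", masterSpacingMm = "numeric",
                 marginMm = "numeric", seed = "numeric"))

.ellipsoidSurfaceDirs <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  g / sqrt(rowSums(g^2))
})

setValidity("PhantomSpec", function(object) {
  errs <- character()
  if (length(object@headSemiAxes) != 3 || any(object@headSemiAxes <= 0))
    errs <- c(errs, "headSemiAxes must be three positive values")
  if (object@skullThicknessMm <= 0 || object@thinPatchThicknessMm <= 0 ||
      object@thinPatchThicknessMm > object@skullThicknessMm)
    errs <- c(errs,
      "shell thicknesses must be positive with thin patch <= base thickness")
  for (nm in c("ZTE", "BB", "FIESTA_C"))
    if (is.null(object@intensities[[nm]]))
      errs <- c(errs, paste("missing intensity triplet for", nm))
  inner <- object@headSemiAxes - object@skinThicknessMm -
    object@skullThicknessMm
  checkInside <- function(lst, what, bound) {
    for (i in seq_along(lst)) {
      el <- lst[[i]]
      pts <- sweep(.ellipsoidSurfaceDirs %*% diag(el$semiAxes), 2,
                   el$center, "+")
      if (any(rowSums(sweep(pts, 2, bound, "/")^2) >= 1))
        errs <<- c(errs, sprintf("%s %d extends outside the head", what, i))
    }
  }
  checkInside(object@airCavities, "air cavity", object@headSemiAxes)
  checkInside(object@confounders, "confounder", object@headSemiAxes)
  if (length(errs)) errs else TRUE
})

#' Construct a PhantomSpec
#'
#' @param ... Overrides of the slots documented in [PhantomSpec-class];
#'   defaults give a clean compact head on the three acquisition grids
#'   (ZTE 0.9 x 0.9 x 1.6, BB 0.5 x 0.5 x 1.2, FIESTA-C 0.4 x 0.4 x 0.7 mm).
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(...) {
  defaults <- list(
    name = "custom",
    headSemiAxes = c(26, 32, 28),
    skullThicknessMm = 3,
    thinPatchThicknessMm = 2,
    thinPatches = list(
      list(center = c(10, -24, 6), radius = 8),     # right orbit
      list(center = c(-10, -24, 6), radius = 8),    # left orbit
      list(center = c(0, 0, 25), radius = 10)),     # vertex
    skinThicknessMm = 3.5,
    airCavities = list(),
    confounders = list(),
    intensities = list(ZTE = c(air = 50, bone = 500, soft = 1000),
                       BB = c(air = 50, bone = 80, soft = 1000),
                       FIESTA_C = c(air = 50, bone = 60, soft = 1000,
                                    fluid = 2500)),
    noiseSigma = 0,
    biasAmplitude = 0,
    biasDirection = c(1, 0, 1),
    motion = RigidTransform(),
    grids = list(zte = c(0.9, 0.9, 1.6), bb = c(0.5, 0.5, 1.2),
                 fiesta = c(0.4, 0.4, 0.7)),
    masterSpacingMm = 0.4,
    marginMm = 6,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown phantom spec fields: ", paste(unknown, collapse = ", "))
  vals <- defaults
  vals[names(over)] <- over  # plain replacement: list-valued fields too
  do.call(new, c(list("PhantomSpec"), vals))
}

#' PhantomSet: generated multi-contrast volumes with ground truth
#'
#' @slot volumes Named list of [ImageVolume-class] (`zte`, `bb`, `fiesta`,
#'   as requested).
#' @slot truth Per-modality named list of [BinaryMask-class] ground truth:
#'   `head`, `bone`, `airInternal`, `skin`, `confounders` (all in anatomy
#'   space, consistent across grids).
#' @slot appliedBias The [BiasField-class] multiplied into the BB volume
#'   (the same world-space shading is applied to every modality).
#' @slot appliedMotion The [RigidTransform-class] through which the ZTE
#'   volume was acquired (identity = none).
#' @slot spec The generating [PhantomSpec-class].
#' @exportClass PhantomSet
setClass("PhantomSet",
  representation(volumes = "list", truth = "list", appliedBias = "BiasField",
                 appliedMotion = "RigidTransform", spec = "PhantomSpec"))

setMethod("show", "PhantomSet", function(object) {
  cat(sprintf("PhantomSet '%s'  (seed %d)\n", object@spec@name,
              as.integer(object@spec@seed)))
  for (nm in names(object@volumes)) {
    d <- dim(object@volumes[[nm]]@voxels)
    s <- object@volumes[[nm]]@spacing
    cat(sprintf("  %-7s %3d x %3d x %3d @ %.2g x %.2g x %.2g mm\n", nm,
                d[1], d[2], d[3], s[1], s[2], s[3]))
  }
})

## Ellipsoid quadratic form q(x) = sum(((x - c) / s)^2) evaluated on the
## tensor grid given by axis coordinate vectors.
.ellQ <- function(xs, ys, zs, center, semi) {
  qx <- ((xs - center[1]) / semi[1])^2
  qy <- ((ys - center[2]) / semi[2])^2
  qz <- ((zs - center[3]) / semi[3])^2
  outer(outer(qx, qy, "+"), qz, "+")
}

## Label codes on the master grid.
.LAB <- c(background = 0L, soft = 1L, skin = 2L, bone = 3L, air = 4L,
          confounder = 5L, fluid = 6L)

.rasteriseLabels <- function(spec) {
  extent <- 2 * (spec@headSemiAxes + spec@marginMm)
  grid <- .makeGrid(extent, rep(spec@masterSpacingMm, 3))
  xs <- grid$origin[1] + spec@masterSpacingMm * (0:(grid$dim[1] - 1))
  ys <- grid$origin[2] + spec@masterSpacingMm * (0:(grid$dim[2] - 1))
  zs <- grid$origin[3] + spec@masterSpacingMm * (0:(grid$dim[3] - 1))
  ctr <- c(0, 0, 0)
  head <- .ellQ(xs, ys, zs, ctr, spec@headSemiAxes) <= 1
  outerShell <- spec@headSemiAxes - spec@skinThicknessMm
  innerThick <- outerShell - spec@skullThicknessMm
  innerThin <- outerShell - spec@thinPatchThicknessMm
  inOuter <- .ellQ(xs, ys, zs, ctr, outerShell) <= 1
  inThick <- .ellQ(xs, ys, zs, ctr, innerThick) <= 1
  inThin <- .ellQ(xs, ys, zs, ctr, innerThin) <= 1
  patch <- array(FALSE, dim = grid$dim)
  for (p in spec@thinPatches)
    patch <- patch | .ellQ(xs, ys, zs, p$center, rep(p$radius, 3)) <= 1
  removal <- (inThin & patch) | (inThick & !patch)
  bone <- inOuter & !removal
  lab <- array(.LAB["background"], dim = grid$dim)
  lab[head] <- .LAB["soft"]
  lab[head & !inOuter] <- .LAB["skin"]
  lab[bone] <- .LAB["bone"]
  for (cav in spec@airCavities) {
    region <- .ellQ(xs, ys, zs, cav$center, cav$semiAxes) <= 1
    code <- if (identical(cav$kind, "fluid")) .LAB["fluid"] else .LAB["air"]
    lab[region & lab == .LAB["soft"]] <- code
  }
  for (cf in spec@confounders) {
    region <- .ellQ(xs, ys, zs, cf$center, cf$semiAxes) <= 1
    lab[region & lab == .LAB["soft"]] <- .LAB["confounder"]
  }
  list(labels = lab, grid = grid)
}

## Per-modality intensity for each label code (0..6).
.labelIntensities <- function(spec, modality, confIdx = 1) {
  lv <- spec@intensities[[modality]]
  fluid <- if (!is.na(lv["fluid"])) lv[["fluid"]] else lv[["soft"]]
  conf <- if (length(spec@confounders))
    spec@confounders[[confIdx]]$intensity[[modality]] else lv[["soft"]]
  c(lv[["air"]], lv[["soft"]], lv[["soft"]], lv[["bone"]], lv[["air"]],
    conf, fluid)
}

## Log-linear multiplicative bias field evaluated at world points.
.biasAt <- function(spec, w) {
  if (spec@biasAmplitude <= 0) return(rep(1, nrow(w)))
  u <- spec@biasDirection / sqrt(sum(spec@biasDirection^2))
  halfSpan <- sum(abs(u) * spec@headSemiAxes)
  d <- pmin(1, pmax(-1, (w %*% u) / halfSpan))
  exp(as.numeric(d) * log(1 + spec@biasAmplitude))
}

.biasArrayOnGrid <- function(spec, grid) {
  arr <- array(1, dim = grid$dim)
  sliceIdx <- as.matrix(expand.grid(0:(grid$dim[1] - 1),
                                    0:(grid$dim[2] - 1)))
  for (k in seq_len(grid$dim[3])) {
    w <- .indexToWorld(grid, cbind(sliceIdx, k - 1L))
    arr[, , k] <- .biasAt(spec, w)
  }
  arr
}

#' Generate a multi-contrast head phantom with ground truth
#'
#' Rasterises the labelled head on the fine isotropic master grid, assigns
#' per-modality intensity levels, resamples (nearest neighbour) onto each
#' acquisition grid — the ZTE volume through the spec's inter-acquisition
#' motion — applies the multiplicative bias field, and adds Rician noise
#' (magnitude of complex Gaussian). Ground-truth masks are nearest-sampled
#' from the same label volume in anatomy space on every grid. Regeneration
#' with an identical spec is bit-identical.
#'
#' @param spec A [PhantomSpec-class].
#' @param modalities Which volumes to synthesise (subset of `"zte"`,
#'   `"bb"`, `"fiesta"`).
#' @return A [PhantomSet-class].
#' @export
generatePhantom <- function(spec = phantomSpec(),
                            modalities = c("zte", "bb", "fiesta")) {
  validObject(spec)
  modalities <- match.arg(modalities, c("zte", "bb", "fiesta"),
                          several.ok = TRUE)
  ras <- .rasteriseLabels(spec)
  lab <- ras$labels
  master <- ras$grid
  extent <- 2 * (spec@headSemiAxes + spec@marginMm)
  modTag <- c(zte = "ZTE", bb = "BB", fiesta = "FIESTA_C")
  seedOff <- c(zte = 1L, bb = 2L, fiesta = 3L)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                         globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  volumes <- list()
  truth <- list()
  biasBB <- NULL
  for (m in modalities) {
    grid <- .makeGrid(extent, spec@grids[[m]])
    tf <- if (m == "zte") spec@motion else RigidTransform()
    labOnGrid <- .resampleArray(lab, master, grid, tf, nearest = TRUE,
                                fill = .LAB["background"])
    levels <- .labelIntensities(spec, modTag[[m]])
    img <- array(levels[labOnGrid + 1L], dim = grid$dim)
    biasArr <- .biasArrayOnGrid(spec, grid)
    img <- img * biasArr
    if (spec@noiseSigma > 0) {
      set.seed(as.integer(spec@seed) * 10L + seedOff[[m]])
      n <- prod(grid$dim)
      img <- sqrt((img + spec@noiseSigma * rnorm(n))^2 +
                    (spec@noiseSigma * rnorm(n))^2)
      img <- array(img, dim = grid$dim)
    }
    volumes[[m]] <- ImageVolume(img, spacing = grid$spacing,
                                origin = grid$origin,
                                direction = grid$direction,
                                modality = modTag[[m]])
    ## truth in anatomy space (no motion), same label volume, every grid
    labTruth <- if (m == "zte" && !isIdentityTransform(spec@motion))
      .resampleArray(lab, master, grid, RigidTransform(), nearest = TRUE,
                     fill = .LAB["background"])
    else labOnGrid
    mk <- function(code) BinaryMask(array(labTruth %in% code,
                                          dim = grid$dim),
                                    spacing = grid$spacing,
                                    origin = grid$origin,
                                    direction = grid$direction)
    truth[[m]] <- list(head = mk(c(1L, 2L, 3L, 4L, 5L, 6L)),
                       bone = mk(.LAB[["bone"]]),
                       airInternal = mk(.LAB[["air"]]),
                       skin = mk(.LAB[["skin"]]),
                       confounders = mk(.LAB[["confounder"]]))
    if (m == "bb")
      biasBB <- new("BiasField", values = pmin(pmax(biasArr, 0.2), 5),
                    spacing = grid$spacing, origin = grid$origin,
                    direction = grid$direction)
  }
  if (is.null(biasBB)) {
    g1 <- .makeGrid(extent, spec@grids[[modalities[1]]])
    biasBB <- new("BiasField",
                  values = pmin(pmax(.biasArrayOnGrid(spec, g1), 0.2), 5),
                  spacing = g1$spacing, origin = g1$origin,
                  direction = g1$direction)
  }
  new("PhantomSet", volumes = volumes, truth = truth, appliedBias = biasBB,
      appliedMotion = spec@motion, spec = spec)
}

#' Named phantom specifications covering the study conditions
#'
#' * `clean`: noiseless, bias-free head with no internal cavities or
#'   confounders — the baseline where both pipelines should excel.
#' * `sinus`: frontal sinus abutting the inner table plus an oropharynx —
#'   the air/bone interface where black-bone-only segmentation fails.
#' * `tendon`: muscular/cartilaginous confounders near the mandible and
#'   nose whose black-bone intensity sits near the bone threshold.
#' * `thin_bone`: orbital shell thinned to 1 mm, below the black-bone
#'   z-spacing.
#' * `moved`: the sinus geometry with a 2 mm / 1 degree inter-acquisition
#'   motion of the ZTE scan.
#'
#' @param seed Seed stored in each spec.
#' @return Named list of [PhantomSpec-class] objects.
#' @export
defaultSpecs <- function(seed = 1) {
  sinusCavities <- list(
    list(center = c(0, -23, 7), semiAxes = c(4, 2.5, 3.5), kind = "air"),
    list(center = c(0, 0, -6), semiAxes = c(7, 7, 11), kind = "air"))
  confounders <- list(
    list(center = c(11, 1, -8), semiAxes = c(3, 3, 6),
         intensity = list(ZTE = 950, BB = 300, FIESTA_C = 300)),
    list(center = c(0, -20, -2), semiAxes = c(2.5, 2.5, 4),
         intensity = list(ZTE = 950, BB = 300, FIESTA_C = 300)))
  list(
    clean = phantomSpec(name = "clean", seed = seed),
    sinus = phantomSpec(name = "sinus", airCavities = sinusCavities,
                        noiseSigma = 50, biasAmplitude = 0.15, seed = seed),
    tendon = phantomSpec(name = "tendon", airCavities = sinusCavities,
                         confounders = confounders, noiseSigma = 50,
                         biasAmplitude = 0.15, seed = seed),
    thin_bone = phantomSpec(name = "thin_bone",
                            thinPatchThicknessMm = 1,
                            airCavities = sinusCavities, noiseSigma = 50,
                            biasAmplitude = 0.15, seed = seed),
    moved = phantomSpec(name = "moved", airCavities = sinusCavities,
                        noiseSigma = 50, biasAmplitude = 0.15,
                        motion = RigidTransform(rotation = c(0, 0, 1),
                                                translation = c(1.5, -1, 0.8)),
                        seed = seed))
}
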