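test_that("noiseless generation reproduces the configured intensity levels", {
  ph <- cachedPhantom("clean", modalities = c("zte", "bb"))
  z <- ph@volumes$zte@voxels; tz <- ph@truth$zte
  expect_true(all(z[tz$bone@voxels] == 500))
  expect_true(all(z[!tz$head@voxels] == 50))
  b <- ph@volumes$bb@voxels; tb <- ph@truth$bb
  expect_true(all(b[tb$bone@voxels] == 80))
  soft <- tb$head@voxels & !tb$bone@voxels
  expect_true(all(b[soft] == 1000))
  expect_equal(sum(tb$airInternal@voxels), 0)  # clean: no cavities
})

test_that("generation is bit-identical for identical spec and seed", {
  spec <- defaultSpecs(seed = 17)$sinus
  a <- generatePhantom(spec, modalities = "zte")
  b <- generatePhantom(spec, modalities = "zte")
  expect_identical(a@volumes$zte@voxels, b@volumes$zte@voxels)
  expect_identical(a@truth$zte$bone@voxels, b@truth$zte$bone@voxels)
})

test_that("the applied bias field shows up as the configured pole ratio", {
  spec <- phantomSpec(biasAmplitude = 0.2, seed = 3)
  ph <- generatePhantom(spec, modalities = "bb")
  v <- ph@volumes$bb@voxels
  f <- ph@appliedBias@values
  soft <- ph@truth$bb$head@voxels & !ph@truth$bb$bone@voxels &
    !ph@truth$bb$skin@voxels
  g <- CranioSeg:::.gridOf(ph@volumes$bb)
  idx <- which(soft, arr.ind = TRUE) - 1
  proj <- CranioSeg:::.indexToWorld(g, idx) %*% (c(1, 0, 1) / sqrt(2))
  sel <- which(soft)
  hi <- sel[proj > quantile(proj, 0.95)]
  lo <- sel[proj < quantile(proj, 0.05)]
  expect_equal(mean(v[hi]) / mean(v[lo]), mean(f[hi]) / mean(f[lo]),
               tolerance = 0.05)
})

test_that("Rician background noise matches the configured sigma", {
  spec <- phantomSpec(noiseSigma = 50, seed = 3)
  ph <- generatePhantom(spec, modalities = "bb")
  bg <- ph@volumes$bb@voxels[!ph@truth$bb$head@voxels]
  ## second-moment (Rician-corrected) estimator: E[M^2] = nu^2 + 2 sigma^2
  sigmaHat <- sqrt((mean(bg^2) - 50^2) / 2)
  expect_equal(sigmaHat, 50, tolerance = 0.1 * 50)
})

test_that("the sinus cavity abuts bone: the targeted air/bone interface exists", {
  ph <- cachedPhantom("sinus", modalities = "bb")
  air <- ph@truth$bb$airInternal@voxels
  bone <- ph@truth$bb$bone@voxels
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) <= 1, , drop = FALSE]
  boneNb <- CranioSeg:::.morphOnce(bone, dim(bone), offs, 1L)
  expect_gt(sum(air & boneNb), 0)
  ## and the oropharynx bulk is clear of bone: the cavities differ in kind
  expect_gt(sum(air & !boneNb), sum(air & boneNb))
})

test_that("the thin_bone spec thins the orbital wall below the base shell", {
  ph <- generatePhantom(defaultSpecs(seed = 1)$thin_bone, modalities = "bb")
  bone <- ph@truth$bb$bone
  g <- CranioSeg:::.gridOf(bone)
  d2 <- array(cpp_edt_sq(!bone@voxels, as.integer(g$dim), g$spacing),
              dim = g$dim)
  idx <- which(bone@voxels, arr.ind = TRUE) - 1
  w <- CranioSeg:::.indexToWorld(g, idx)
  inPatch <- colSums((t(w) - c(10, -24, 6))^2) < 25
  inBase <- colSums((t(w) - c(0, 24, 0))^2) < 64  # posterior wall, full 3 mm
  thPatch <- 2 * sqrt(max(d2[bone@voxels][inPatch]))
  thBase <- 2 * sqrt(max(d2[bone@voxels][inBase]))
  ## configured 1 mm, below the black-bone z-spacing; allow half-voxel
  ## quantisation of the distance measurement on each side
  expect_lte(thPatch, 1.2 + sqrt(sum((g$spacing[1:2] / 2)^2)) * 2)
  expect_lt(thPatch / thBase, 0.6)
})

test_that("ground truth is consistent across the acquisition grids", {
  ph <- cachedPhantom("sinus", modalities = c("zte", "bb", "fiesta"))
  bb <- ph@truth$bb
  headZ <- resample(ph@truth$zte$head, bb$head)
  expect_gte(diceCoefficient(headZ, bb$head), 0.97)
  ## the 3 mm bone shell cannot keep that dice across a 1.6 mm grid; its
  ## consistency is bounded by surface distance instead (sub-voxel)
  boneZ <- resample(ph@truth$zte$bone, bb$bone)
  expect_lte(meanSurfaceDistance(boneZ, bb$bone), 1.0)
  boneF <- resample(ph@truth$fiesta$bone, bb$bone)
  expect_gte(diceCoefficient(boneF, bb$bone), 0.95)
})

test_that("spec validation lists geometry breaches", {
  expect_error(
    phantomSpec(airCavities = list(list(center = c(0, 30, 0),
                                        semiAxes = c(8, 8, 8),
                                        kind = "air"))),
    "outside the head")
  expect_error(phantomSpec(thinPatchThicknessMm = 5), "thickness")
})

test_that("named specs cover the study conditions", {
  specs <- defaultSpecs(seed = 1)
  expect_setequal(names(specs),
                  c("clean", "sinus", "tendon", "thin_bone", "moved"))
  expect_equal(length(specs$clean@airCavities), 0)
  expect_gt(length(specs$sinus@airCavities), 1)
  expect_gt(length(specs$tendon@confounders), 0)
  expect_false(isIdentityTransform(specs$moved@motion))
  expect_true(isIdentityTransform(specs$clean@motion))
  ## FIESTA fluid option: a fluid cavity renders very bright, not dark
  sp <- phantomSpec(airCavities = list(list(center = c(0, 10, 0),
                                            semiAxes = c(4, 4, 4),
                                            kind = "fluid")))
  phf <- generatePhantom(sp, modalities = "fiesta")
  expect_gt(max(phf@volumes$fiesta@voxels), 2000)  # fluid-bright present
  expect_equal(sum(phf@truth$fiesta$airInternal@voxels), 0)
})
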