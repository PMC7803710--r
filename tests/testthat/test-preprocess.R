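test_that("denoise honours the identity and constancy contracts", {
  set.seed(2)
  vol <- makeVol(array(rnorm(10^3), c(10, 10, 10)))
  expect_identical(denoise(vol, pipelineConfig(denoiseMethod = "none"))@voxels,
                   vol@voxels)
  const <- makeVol(array(7, c(10, 10, 10)))
  for (m in c("curvature_flow", "gaussian"))
    expect_equal(denoise(const, pipelineConfig(denoiseMethod = m))@voxels,
                 const@voxels, tolerance = 1e-12)
})

test_that("denoising reduces noise by at least a quarter without moving edges", {
  ph <- cachedPhantom("sinus", modalities = "bb")
  bb <- ph@volumes$bb
  den <- denoise(bb, pipelineConfig())
  ## homogeneous soft-tissue probe sphere (away from bone, cavities, bias pole)
  g <- CranioSeg:::.gridOf(bb)
  idx <- which(array(TRUE, dim(bb@voxels)), arr.ind = TRUE) - 1
  w <- CranioSeg:::.indexToWorld(g, idx)
  probe <- (w[, 1] - 8)^2 + (w[, 2] - 10)^2 + w[, 3]^2 < 25
  expect_lte(sd(den@voxels[probe]), 0.75 * sd(bb@voxels[probe]))
  ## skull boundary gradient peak displaced by less than one voxel
  clean <- cachedPhantom("clean", modalities = "bb")@volumes$bb
  denC <- denoise(clean, pipelineConfig())
  d <- dim(clean@voxels)
  prof0 <- clean@voxels[d[1] %/% 2, , d[3] %/% 2]
  prof1 <- denC@voxels[d[1] %/% 2, , d[3] %/% 2]
  half <- seq_len(length(prof0) %/% 2)  # anterior half: one skull crossing
  expect_lte(abs(which.max(abs(diff(prof0[half]))) -
                 which.max(abs(diff(prof1[half])))), 1)
})

test_that("head mask covers the head, fills cavities, rejects pure noise", {
  for (name in c("clean", "sinus")) {
    ph <- cachedPhantom(name, modalities = "bb")
    hm <- headMask(denoise(ph@volumes$bb, pipelineConfig()), pipelineConfig())
    expect_gte(diceCoefficient(hm, ph@truth$bb$head), 0.98)
    lab <- connectedComponents(hm)
    expect_equal(max(lab), 1)  # single connected component
    if (name == "sinus") {
      air <- ph@truth$bb$airInternal@voxels
      expect_gte(sum(hm@voxels & air) / sum(air), 0.999)  # cavities inside
    }
  }
  set.seed(4)
  noise <- makeVol(array(rnorm(20^3), c(20, 20, 20)))
  expect_error(headMask(noise, pipelineConfig(minComponentVoxels = 1e5)),
               "no head found")
})

test_that("bias estimation recovers simulated fields and is nearly idempotent", {
  cfg <- pipelineConfig()
  ## no simulated bias: estimated field stays within 5% of unity
  ph0 <- cachedPhantom("clean", modalities = "bb")
  den0 <- denoise(ph0@volumes$bb, cfg)
  hm0 <- headMask(den0, cfg)
  bc0 <- estimateAndCorrectBias(den0, hm0, cfg)
  expect_true(all(bc0$field@values[hm0@voxels] > 0.95 &
                  bc0$field@values[hm0@voxels] < 1.05))
  ## 20% linear-gradient bias: soft-tissue CV at least halved
  spec <- defaultSpecs(seed = 1)$clean
  spec@biasAmplitude <- 0.2
  ph <- generatePhantom(spec, modalities = "bb")
  den <- denoise(ph@volumes$bb, cfg)
  hm <- headMask(den, cfg)
  bc <- estimateAndCorrectBias(den, hm, cfg)
  softCore <- morphology(BinaryMask(
    ph@truth$bb$head@voxels & !ph@truth$bb$bone@voxels &
      !ph@truth$bb$skin@voxels, grid = hm), "erode", 2)@voxels
  cv <- function(v) sd(v) / mean(v)
  expect_lte(cv(bc$volume@voxels[softCore]), 0.5 * cv(den@voxels[softCore]))
  ## approximate idempotence: second correction changes < 2% RMS
  bc2 <- estimateAndCorrectBias(bc$volume, hm, cfg)
  relRMS <- sqrt(mean((bc2$volume@voxels[hm@voxels] -
                       bc$volume@voxels[hm@voxels])^2)) /
            mean(bc$volume@voxels[hm@voxels])
  expect_lt(relRMS, 0.02)
  ## degenerate input
  zero <- makeVol(array(0, c(6, 6, 6)))
  expect_error(estimateAndCorrectBias(zero, makeMask(array(TRUE, c(6, 6, 6))),
                                      cfg), "positive")
})

test_that("log-linear bias fields up to 30% are recovered to 0.05 RMS log-error", {
  cfg <- pipelineConfig()
  for (amp in c(0.1, 0.3)) {
    spec <- defaultSpecs(seed = 1)$clean
    spec@biasAmplitude <- amp
    ph <- generatePhantom(spec, modalities = "bb")
    den <- denoise(ph@volumes$bb, cfg)
    hm <- headMask(den, cfg)
    bc <- estimateAndCorrectBias(den, hm, cfg)
    lt <- log(ph@appliedBias@values[hm@voxels])
    le <- log(bc$field@values[hm@voxels])
    lt <- lt - mean(lt); le <- le - mean(le)
    expect_lte(sqrt(mean((le - lt)^2)), 0.05)
  }
})

test_that("skin removal erodes by the stated physical thickness", {
  cfg0 <- pipelineConfig(skinThicknessMm = 0)
  arr <- array(runif(8^3) < 0.5, c(8, 8, 8))
  expect_identical(removeSkin(makeMask(arr), cfg0)@voxels, arr)
  ## sphere of radius 80 mm, thickness 3 mm: volume ratio (77/80)^3
  n <- 165; co <- (1:n) - 83
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  sph <- makeMask(r2 <= 80^2)
  out <- removeSkin(sph, pipelineConfig(skinThicknessMm = 3))
  ratio <- sum(out@voxels) / sum(sph@voxels)
  shellFrac <- 3 * 77^2 / 80^3  # one-voxel shell tolerance
  expect_lt(abs(ratio - (77 / 80)^3), shellFrac)
  ## at default thickness no ground-truth skull voxel is removed
  ph <- cachedPhantom("clean", modalities = "bb")
  hm <- headMask(denoise(ph@volumes$bb, pipelineConfig()), pipelineConfig())
  interior <- removeSkin(hm, pipelineConfig())
  bone <- ph@truth$bb$bone@voxels
  expect_equal(sum(bone & !interior@voxels), 0)
  expect_error(removeSkin(makeMask(array(c(TRUE, rep(FALSE, 342)),
                                         c(7, 7, 7))),
                          pipelineConfig(skinThicknessMm = 10)),
               "exceeds head radius")
})

test_that("intensity normalisation is a pure scale pinning the interior median", {
  interior <- makeMask(array(TRUE, c(8, 8, 8)))
  v1 <- makeVol(array(rep(c(900, 1000, 1100), length.out = 512), c(8, 8, 8)))
  n1 <- normaliseIntensity(v1, interior)
  expect_equal(median(n1@voxels[interior@voxels]), 1000)
  expect_equal(n1@meta$normalisationScale, 1)
  v3 <- makeVol(v1@voxels * 3)
  n3 <- normaliseIntensity(v3, interior)
  expect_equal(n3@voxels, n1@voxels)  # scale invariance
  ## phantom BB: post-normalisation soft-tissue median 1000 +/- 1
  ph <- cachedPhantom("sinus", modalities = "bb")
  pp <- CranioSeg:::.preprocessVolume(ph@volumes$bb, pipelineConfig())
  expect_equal(median(pp$volume@voxels[pp$interior@voxels]), 1000,
               tolerance = 1e-3)
  neg <- makeVol(array(-5, c(4, 4, 4)))
  expect_error(normaliseIntensity(neg, makeMask(array(TRUE, c(4, 4, 4)))),
               "median")
})

test_that("render rescaling maps the window affinely onto [0, 32767]", {
  cfg <- pipelineConfig(renderWindowLow = 0, renderWindowHigh = 1500)
  v <- makeVol(array(c(-50, 0, 300, 750, 1500, 2000, rep(0, 21)), c(3, 3, 3)))
  out <- rescaleForRender(v, cfg)@voxels
  expect_equal(out[1], 0)          # clamp below
  expect_equal(out[2], 0)          # low bound -> 0
  expect_equal(out[5], 32767)      # high bound -> 32767
  expect_equal(out[6], 32767)      # clamp above
  expect_equal(out[4], 750 / 1500 * 32767)
  expect_lt(out[3], out[4])        # monotone
  expect_error(rescaleForRender(v, pipelineConfig(renderWindowLow = 10,
                                                  renderWindowHigh = 10)),
               "indow")
})
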