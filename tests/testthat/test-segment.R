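test_that("noiseless three-level ZTE separates bone exactly", {
  ph <- cachedPhantom("clean", modalities = c("zte", "bb"))
  mask <- zteBoneMask(ph@volumes$zte, pipelineConfig())
  expect_identical(mask@voxels, ph@truth$zte$bone@voxels)
})

test_that("noisy ZTE still segments bone with dice >= 0.90", {
  ph <- cachedPhantom("sinus", modalities = c("zte", "bb"))
  pp <- CranioSeg:::.preprocessVolume(ph@volumes$zte, pipelineConfig())
  mask <- zteBoneMask(pp$volume, pipelineConfig(), head = pp$headMask,
                      interior = pp$interior)
  expect_gte(diceCoefficient(mask, ph@truth$zte$bone), 0.90)
})

test_that("ZTE segmentation handles absent bone and rejects un-normalised input", {
  ## soft-tissue-only head: a bright ellipsoid in air, median already 1000
  n <- 40
  co <- seq(-20, 20, length.out = n)
  q <- outer(outer((co / 14)^2, (co / 16)^2, "+"), (co / 15)^2, "+")
  arr <- ifelse(q <= 1, 1000, 50)
  vol <- makeVol(arr, modality = "ZTE")
  mask <- zteBoneMask(vol, pipelineConfig())
  expect_equal(sum(mask@voxels), 0)
  expect_error(zteBoneMask(makeVol(arr * 3, modality = "ZTE"),
                           pipelineConfig()), "not normalised")
})

test_that("black-bone candidates conflate bone with internal air by design", {
  cfg <- pipelineConfig()
  ## cavity-free phantom: candidates recover bone cleanly
  ph <- cachedPhantom("clean", modalities = "bb")
  pp <- CranioSeg:::.preprocessVolume(ph@volumes$bb, cfg)
  cand <- bbBoneCandidates(pp$volume, pp$interior, cfg)
  expect_gte(diceCoefficient(cand, ph@truth$bb$bone), 0.95)
  ## with a frontal sinus: candidates contain bone AND internal air — the
  ## conflation is asserted, not merely tolerated
  ph2 <- cachedPhantom("sinus", modalities = "bb")
  pp2 <- CranioSeg:::.preprocessVolume(ph2@volumes$bb, cfg)
  cand2 <- bbBoneCandidates(pp2$volume, pp2$interior, cfg)
  boneIn <- ph2@truth$bb$bone@voxels & pp2$interior@voxels
  airIn <- ph2@truth$bb$airInternal@voxels & pp2$interior@voxels
  ## denoising blurs the thinnest shell and the cavity rims, so containment
  ## is near-complete rather than exact
  expect_gte(sum(cand2@voxels & boneIn) / sum(boneIn), 0.9)
  expect_gte(sum(cand2@voxels & airIn) / sum(airIn), 0.9)
  ## all-soft interior yields no candidates
  soft <- makeVol(array(1000, c(12, 12, 12)), modality = "BB")
  interior <- makeMask(array(TRUE, c(12, 12, 12)))
  expect_equal(sum(bbBoneCandidates(soft, interior, cfg)@voxels), 0)
  expect_error(bbBoneCandidates(soft, makeMask(array(FALSE, c(12, 12, 12))),
                                cfg), "empty")
})

test_that("the black-bone-only pipeline reproduces the published failure mode", {
  ph <- cachedPhantom("sinus", modalities = "bb")
  res <- cachedResult("sinus", "bb-only")
  expect_s4_class(res, "SegmentationResult")
  expect_equal(res@provenance, "BB_ONLY")
  expect_gte(diceCoefficient(res@boneMask, ph@truth$bb$bone), 0.85)
  ## internal air is misclassified as bone: the bone/air ambiguity of
  ## black-bone contrast
  airFP <- sum(res@boneMask@voxels & ph@truth$bb$airInternal@voxels) /
    sum(ph@truth$bb$airInternal@voxels)
  expect_gt(airFP, 0.5)
})

test_that("clean phantom black-bone segmentation reaches dice 0.93", {
  ph <- cachedPhantom("clean", modalities = "bb")
  res <- cachedResult("clean", "bb-only")
  expect_gte(diceCoefficient(res@boneMask, ph@truth$bb$bone), 0.93)
})

test_that("the ZTE-driven pipeline excludes air and confounders", {
  ph <- cachedPhantom("sinus", modalities = c("zte", "bb"))
  resB <- cachedResult("sinus", "bb-only")
  resZ <- cachedResult("sinus", "zte-driven")
  expect_equal(resZ@provenance, "ZTE_DRIVEN")
  dB <- diceCoefficient(resB@boneMask, ph@truth$bb$bone)
  dZ <- diceCoefficient(resZ@boneMask, ph@truth$bb$bone)
  expect_gt(dZ, dB)
  airFP <- sum(resZ@boneMask@voxels & ph@truth$bb$airInternal@voxels) /
    sum(ph@truth$bb$airInternal@voxels)
  expect_lt(airFP, 0.1)
  ## tendon/muscle confounders: present in BB-only, absent from ZTE-driven
  pht <- cachedPhantom("tendon", modalities = c("zte", "bb"))
  rB <- cachedResult("tendon", "bb-only")
  rZ <- cachedResult("tendon", "zte-driven")
  conf <- pht@truth$bb$confounders@voxels
  expect_gt(sum(rB@boneMask@voxels & conf), 0)
  expect_lt(sum(rZ@boneMask@voxels & conf) / max(1, sum(rB@boneMask@voxels & conf)),
            0.2)
})

test_that("the ZTE-driven pipeline transfers to FIESTA-C", {
  ph <- cachedPhantom("sinus", modalities = c("zte", "fiesta"))
  res <- cachedResult("sinus", "zte-driven", highres = "fiesta")
  expect_gte(diceCoefficient(res@boneMask, ph@truth$fiesta$bone), 0.90)
})

test_that("bone masks stay inside the skin-removed head and renders obey the halo", {
  for (key in list(c("sinus", "bb-only"), c("sinus", "zte-driven"))) {
    ph <- cachedPhantom("sinus", modalities = c("zte", "bb"))
    res <- cachedResult(key[1], key[2])
    pp <- CranioSeg:::.preprocessVolume(ph@volumes$bb, pipelineConfig())
    expect_equal(sum(res@boneMask@voxels & !pp$interior@voxels), 0)
    ## render voxels only within the one-voxel halo of the bone mask
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) <= 1, , drop = FALSE]
    halo <- CranioSeg:::.morphOnce(res@boneMask@voxels,
                                   dim(res@boneMask@voxels), offs, 1L)
    expect_equal(sum(res@renderVolume@voxels != 0 & !halo), 0)
  }
})

test_that("render volumes invert bone-dark contrast and keep cortical gradient", {
  ## direct inversion contract on a small synthetic case
  v <- makeVol(array(seq(0, 32767, length.out = 4^3), c(4, 4, 4)))
  bone <- makeMask(array(FALSE, c(4, 4, 4)))
  bone@voxels[2:3, 2:3, 2:3] <- TRUE
  out <- makeRenderVolume(v, bone, pipelineConfig())
  inMask <- which(bone@voxels)
  expect_equal(out@voxels[inMask], 32767 - v@voxels[inMask])
  expect_equal(out@modality, "DERIVED")
  empty <- makeMask(array(FALSE, c(4, 4, 4)))
  expect_true(all(makeRenderVolume(v, empty, pipelineConfig())@voxels == 0))
  ## phantom: bone renders brighter than its halo ring
  ph <- cachedPhantom("sinus", modalities = "bb")
  res <- cachedResult("sinus", "bb-only")
  bvox <- res@boneMask@voxels & ph@truth$bb$bone@voxels
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) <= 1, , drop = FALSE]
  halo <- CranioSeg:::.morphOnce(res@boneMask@voxels,
                                 dim(res@boneMask@voxels), offs, 1L) &
    !res@boneMask@voxels
  expect_gt(mean(res@renderVolume@voxels[bvox]),
            mean(res@renderVolume@voxels[halo]))
})

test_that("recall of true bone grows monotonically with the search dilation", {
  cfg <- pipelineConfig()
  ph <- cachedPhantom("sinus", modalities = c("zte", "bb"))
  ppz <- CranioSeg:::.preprocessVolume(ph@volumes$zte, cfg)
  zmask <- zteBoneMask(ppz$volume, cfg, head = ppz$headMask,
                       interior = ppz$interior)
  pph <- CranioSeg:::.preprocessVolume(ph@volumes$bb, cfg)
  cand <- bbBoneCandidates(pph$volume, pph$interior, cfg)
  onHigh <- resample(zmask, ph@volumes$bb)
  bone <- ph@truth$bb$bone@voxels
  last <- -1
  for (dil in c(0.6, 1.5, 3, 5)) {
    search <- morphology(onHigh, "dilate", dil)
    recall <- sum(cand@voxels & search@voxels & bone) / sum(bone)
    expect_gte(recall, last)
    last <- recall
  }
})

test_that("volumes that do not cover the same anatomy are refused", {
  a <- makeVol(array(rnorm(1000), c(10, 10, 10)), modality = "ZTE",
               origin = c(0, 0, 0))
  b <- makeVol(array(rnorm(1000), c(10, 10, 10)), modality = "BB",
               origin = c(500, 0, 0))
  expect_error(zteDrivenPipeline(a, b), "same anatomy")
  c2 <- makeVol(array(rnorm(1000), c(10, 10, 10)), modality = "DERIVED")
  expect_error(zteDrivenPipeline(a, c2), "modality")
})
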