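test_that("rigid transforms compose and invert to identity", {
  set.seed(7)
  box <- as.matrix(expand.grid(c(-40, 40), c(-50, 50), c(-45, 45)))
  for (i in 1:5) {
    tf <- RigidTransform(rotation = runif(3, -10, 10),
                         translation = runif(3, -8, 8),
                         center = runif(3, -5, 5))
    comp <- composeTransforms(invertTransform(tf), tf)
    err <- max(abs(transformPoints(comp, box) - box))
    expect_lt(err, 1e-6)
  }
})

test_that("resample with identity transform on the same grid is exact", {
  set.seed(1)
  vol <- makeVol(array(rnorm(5 * 6 * 7), c(5, 6, 7)), spacing = c(0.5, 0.5, 1.2))
  out <- resample(vol, vol)
  expect_identical(out@voxels, vol@voxels)
})

test_that("constant fields are invariant under rigid resampling", {
  vol <- makeVol(array(3.25, c(8, 8, 8)))
  tf <- RigidTransform(rotation = c(4, -3, 7), translation = c(0.6, -0.4, 0.9))
  out <- resample(vol, vol, transform = tf, fill = 0)
  ## voxels mapped fully inside the source, tracked with an indicator volume
  ones <- resample(makeVol(array(1, c(8, 8, 8))), vol, transform = tf,
                   fill = 0)
  interior <- ones@voxels > 1 - 1e-12
  expect_gt(sum(interior), 0)
  expect_true(all(abs(out@voxels[interior] - 3.25) < 1e-9))
})

test_that("nearest resampling matches a brute-force index-mapping oracle", {
  arr <- array(0, c(20, 20, 20))
  arr[9, 11, 13] <- 100
  vol <- makeVol(arr, spacing = c(1, 1, 1))
  ## pure translation of exactly one voxel along x: transform maps
  ## target world -> source world, so the bright voxel appears at +1
  tf <- RigidTransform(translation = c(-1, 0, 0))
  out <- suppressWarnings(resample(vol, vol, transform = tf,
                                   interpolation = "nearest"))
  expect_equal(which(out@voxels == 100, arr.ind = TRUE)[1, ],
               c(dim1 = 10, dim2 = 11, dim3 = 13))
  ## brute-force oracle: map every output index through the transform
  grid <- CranioSeg:::.gridOf(vol)
  oracle <- array(0, dim(arr))
  for (i in 0:19) for (j in 0:19) for (k in 0:19) {
    w <- CranioSeg:::.indexToWorld(grid, c(i, j, k))
    ws <- transformPoints(tf, as.numeric(w))
    src <- round((ws - grid$origin) / grid$spacing)
    if (all(src >= 0 & src <= 19))
      oracle[i + 1, j + 1, k + 1] <- arr[src[1] + 1, src[2] + 1, src[3] + 1]
  }
  expect_identical(out@voxels, oracle)
})

test_that("resampling is equivariant under transform composition on smooth fields", {
  ## the double-interpolation error scales with curvature per voxel^2, so
  ## the smooth-field property needs a well-resolved field
  n <- 96
  co <- seq(-1, 1, length.out = n)
  g <- outer(outer(exp(-co^2 * 1.5), exp(-co^2 * 1.5)), exp(-co^2 * 1.5))
  vol <- makeVol(g * 100, spacing = c(2, 2, 2))
  t1 <- RigidTransform(rotation = c(2, 0, -3), translation = c(1, -0.5, 0.8))
  t2 <- RigidTransform(rotation = c(-1, 2, 1), translation = c(-0.7, 0.3, 0.2))
  twoStep <- resample(resample(vol, vol, transform = t1, fill = 0), vol,
                      transform = t2, fill = 0)
  oneStep <- resample(vol, vol, transform = composeTransforms(t1, t2),
                      fill = 0)
  ones <- makeVol(array(1, dim(vol@voxels)), spacing = c(2, 2, 2))
  valid <- resample(resample(ones, ones, transform = t1, fill = 0), ones,
                    transform = t2, fill = 0)@voxels > 1 - 1e-9 &
           resample(ones, ones, transform = composeTransforms(t1, t2),
                    fill = 0)@voxels > 1 - 1e-9
  d <- abs(twoStep@voxels - oneStep@voxels)[valid]
  expect_lt(max(d), 1e-3 * diff(range(vol@voxels)))
})

test_that("geometry violations and interpolation misuse are reported", {
  expect_error(ImageVolume(array(0, c(3, 3, 3)),
                           direction = matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1),
                                              3, 3)),
               "orthonormal")
  expect_error(ImageVolume(array(c(1, NA, rep(0, 25)), c(3, 3, 3))), "finite")
  vol <- makeVol(array(rnorm(27), c(3, 3, 3)))
  expect_warning(resample(vol, vol, interpolation = "nearest"),
                 "nearest")
})

test_that("grids convert between voxel indices and LPS world coordinates", {
  vol <- makeVol(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 1.2),
                 origin = c(-10, 5, 2))
  g <- CranioSeg:::.gridOf(vol)
  expect_equal(as.numeric(CranioSeg:::.indexToWorld(g, c(0, 0, 0))),
               c(-10, 5, 2))
  expect_equal(as.numeric(CranioSeg:::.indexToWorld(g, c(2, 1, 3))),
               c(-10 + 1, 5 + 0.5, 2 + 3.6))
})
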