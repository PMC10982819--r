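test_that("axis-aligned rectangles measure exactly", {
  m <- matrix(0, 20, 50)
  m[6:15, 6:45] <- 1 # 10 x 40 px
  dm <- computeDiameters(m, 0.5)
  expect_equal(dm[["longDiamMm"]], 20)
  expect_equal(dm[["shortDiamMm"]], 5)
  expect_equal(dm[["diamRatio"]], 0.25)
})

test_that("a disk measures its diameter in both axes", {
  m <- ellipseMask(31, 10.5, 10.5) # diameter 21 px at 1 mm/px
  dm <- computeDiameters(m, 1)
  expect_lt(abs(dm[["longDiamMm"]] - 21), 1)
  expect_lt(abs(dm[["shortDiamMm"]] - 21), 1)
  expect_gte(dm[["diamRatio"]], 0.95)
  expect_lte(dm[["diamRatio"]], 1)
})

test_that("rotated ellipses agree with the rotating-calipers oracle", {
  set.seed(17)
  for (i in 1:10) {
    a <- runif(1, 6, 15)
    b <- runif(1, 3, a)
    th <- runif(1, 0, pi)
    m <- ellipseMask(48, a, b, th)
    dm <- computeDiameters(m, 1, method = "caliper")
    oc <- caliperDiameters(m, 1)
    expect_lt(abs(dm[["longDiamMm"]] - oc[["long"]]), 1)
    expect_lt(abs(dm[["shortDiamMm"]] - oc[["short"]]), 1)
    # the rectangle convention agrees on elongated shapes
    if (b <= 0.5 * a) {
      dr <- computeDiameters(m, 1)
      expect_lt(abs(dr[["shortDiamMm"]] - oc[["short"]]), 1)
    }
  }
})

test_that("diameters are rotation-equivariant and scale with spacing", {
  m <- ellipseMask(40, 12, 5, 0.4)
  dm <- computeDiameters(m, 0.7)
  rot <- t(m)[ncol(m):1, ] # 90-degree rotation
  dmr <- computeDiameters(rot, 0.7)
  expect_lt(abs(dm[["longDiamMm"]] - dmr[["longDiamMm"]]), 0.7)
  expect_lt(abs(dm[["shortDiamMm"]] - dmr[["shortDiamMm"]]), 0.7)
  dm2 <- computeDiameters(m, 1.4)
  expect_equal(dm2[["longDiamMm"]], 2 * dm[["longDiamMm"]])
  expect_equal(dm2[["shortDiamMm"]], 2 * dm[["shortDiamMm"]])
  expect_equal(dm2[["diamRatio"]], dm[["diamRatio"]])
})

test_that("degenerate masks follow the documented conventions", {
  expect_error(computeDiameters(matrix(0, 5, 5), 1), "empty mask")
  one <- matrix(0, 5, 5); one[3, 3] <- 1
  dm <- computeDiameters(one, 0.8)
  expect_equal(dm[["longDiamMm"]], 0.8)
  expect_equal(dm[["shortDiamMm"]], 0.8)
  expect_equal(dm[["diamRatio"]], 1)
})

test_that("anisotropic spacing converts to mm before geometry", {
  m <- matrix(0, 30, 30)
  m[11:20, 11:20] <- 1 # 10 x 10 px square
  dm <- computeDiameters(m, c(2, 0.5)) # rows 2 mm, cols 0.5 mm
  expect_equal(dm[["longDiamMm"]], 20)
  expect_equal(dm[["shortDiamMm"]], 5)
})

test_that("mean ADC matches hand and elementwise-loop oracles", {
  m <- matrix(0, 4, 4); m[2, 2] <- 1; m[3, 3] <- 1
  adc <- matrix(1.1, 4, 4)
  expect_equal(meanADC(m, adc), 1.1)
  adc[2, 2] <- 1.0; adc[3, 3] <- 2.0
  expect_equal(meanADC(m, adc), 1.5)
  set.seed(3)
  mm <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
  mm[1, 1] <- 1
  aa <- matrix(rnorm(32 * 32), 32, 32)
  tot <- 0; cnt <- 0
  for (i in 1:32) for (j in 1:32) if (mm[i, j] > 0.5) {
    tot <- tot + aa[i, j]; cnt <- cnt + 1
  }
  expect_equal(meanADC(mm, aa), tot / cnt)
  expect_error(meanADC(matrix(0, 4, 4), adc), "empty mask")
  expect_error(meanADC(m, matrix(0, 3, 3)), "grid")
})

test_that("patch extraction geometry follows the margin rule", {
  img <- matrix(rnorm(100 * 100), 100, 100)
  msk <- matrix(0, 100, 100)
  msk[41:56, 45:52] <- 1 # bbox 16 x 8
  ex <- extractPatch(img, msk, marginFactor = 2, outPx = 32L)
  expect_equal(ex$cropPx, 32L) # 2 x max(16, 8)
  expect_equal(dim(ex$patch), c(32L, 32L))
  # identity path: crop side equals outPx and no resampling occurs
  expect_true(all(ex$patch %in% img))
  expect_equal(ex$scale, 1)
})

test_that("extraction recenters the mask and pads at borders with warning", {
  img <- matrix(0, 60, 60)
  msk <- matrix(0, 60, 60)
  msk[20:31, 25:36] <- 1
  set.seed(2)
  img[] <- rnorm(3600)
  ex <- extractPatch(img, msk, marginFactor = 2, outPx = 24L)
  cm <- which(ex$croppedMask > 0.5, arr.ind = TRUE)
  ctr <- colMeans(cm)
  expect_lt(abs(ctr[1] - (24 + 1) / 2), 1.5)
  expect_lt(abs(ctr[2] - (24 + 1) / 2), 1.5)
  mskEdge <- matrix(0, 60, 60); mskEdge[1:10, 1:10] <- 1
  expect_warning(extractPatch(img, mskEdge, marginFactor = 3, outPx = 16L),
                 "edge padding")
})

test_that("extraction plus measurement recovers generation diameters", {
  set.seed(9)
  for (i in 1:5) {
    long <- runif(1, 8, 14); short <- runif(1, 4, long * 0.8)
    pm <- renderPatch(FALSE, long, short, spacing = 0.5, patchPx = 64L)
    ex <- extractPatch(pm$patch, pm$mask, marginFactor = 2, outPx = 32L)
    dm <- computeDiameters(ex$croppedMask, 0.5 * ex$scale)
    # raster half-pixel at the source grid plus up to two pixels of
    # nearest-neighbor boundary displacement at the resampled grid
    tolMm <- 0.5 + ex$scale
    expect_lt(abs(dm[["longDiamMm"]] - long), tolMm)
    expect_lt(abs(dm[["shortDiamMm"]] - short), tolMm)
  }
})

test_that("robust normalization is affine-invariant with median zero", {
  expect_true(all(normalizeIntensity(matrix(3.7, 10, 10)) == 0))
  set.seed(4)
  x <- matrix(rnorm(900), 30, 30)
  z <- normalizeIntensity(x)
  expect_equal(normalizeIntensity(2.3 * x + 17), z)
  expect_lt(abs(median(z)), 1e-6)
  expect_true(all(z >= -5 & z <= 5))
  expect_error(normalizeIntensity(matrix(c(1, NA), 2, 2)), "finite")
})
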