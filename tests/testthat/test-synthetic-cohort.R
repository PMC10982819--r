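test_that("invalid parameters are rejected with the field named", {
  expect_error(cohortParams(patientLnmRate = 1.4), "patientLnmRate")
  expect_error(cohortParams(visibleLnMean = 2), "visibleLnMean")
  expect_error(cohortParams(patchPx = 8), "patchPx")
  expect_error(cohortParams(hiddenNodeRate = 1), "hiddenNodeRate")
  expect_error(cohortParams(pixelSpacing = 0), "pixelSpacing")
})

test_that("a zero-metastasis cohort is all N0", {
  co <- statCohort(30, seed = 5, patientLnmRate = 0)
  for (b in bags(co)) {
    expect_identical(b@y, 0L)
    expect_identical(b@rho, 0)
    expect_identical(b@stageTrue, "N0")
  }
})

test_that("cohort generation is deterministic and order-independent", {
  a <- simulateCohort(cohortParams(nPatients = 4, seed = 9))
  b <- simulateCohort(cohortParams(nPatients = 4, seed = 9))
  expect_identical(nodes(bags(a)[[3]])[[2]]@patch,
                   nodes(bags(b)[[3]])[[2]]@patch)
  # patient 3 is identical whether 4 or 6 patients are generated
  c6 <- simulateCohort(cohortParams(nPatients = 6, seed = 9))
  expect_identical(nodes(bags(a)[[3]])[[1]]@patch,
                   nodes(bags(c6)[[3]])[[1]]@patch)
})

test_that("cohort statistics match the configured truncated distributions", {
  co <- statCohort(1000, seed = 11)
  nVis <- vapply(bags(co), function(b) length(b@nodes), integer(1))
  expect_gte(mean(nVis), 13)
  expect_lte(mean(nVis), 15)
  expect_true(all(nVis >= 5 & nVis <= 50))
  posFrac <- mean(bagY(co))
  expect_lt(abs(posFrac - 0.39), 0.05)
  k <- vapply(bags(co), function(b) b@nMetastatic, integer(1))
  expect_true(all(k >= 0 & k <= 35))
  # heavy-tailed metastatic count: overall mean near 1.6, SD near 3.2
  expect_lt(abs(mean(k) - 1.6), 0.45)
  expect_lt(abs(sd(k) - 3.2), 0.9)
})

test_that("bag invariants hold on every generated bag", {
  co <- statCohort(150, seed = 21, hiddenNodeRate = 0.15)
  for (b in bags(co)) {
    expect_lte(b@nMetastatic, b@nResected)
    expect_identical(b@y, as.integer(b@nMetastatic > 0))
    expect_equal(b@rho, b@nMetastatic / b@nResected)
    expect_identical(b@stageTrue, countToStage(b@nMetastatic))
  }
})

test_that("with no hidden nodes the visible latent truth matches pathology", {
  co <- statCohort(120, seed = 31, hiddenNodeRate = 0)
  for (b in bags(co)) {
    nLat <- sum(vapply(b@nodes, function(nd) nd@latentMet, logical(1)))
    expect_identical(nLat, b@nMetastatic)
    expect_identical(b@nResected, length(b@nodes))
  }
})

test_that("size effect monotonically widens the met/benign diameter gap", {
  gapAt <- function(se) {
    co <- statCohort(715, seed = 41, sizeEffect = se, patientLnmRate = 0.5)
    ft <- nodeFeatureTable(co)
    mean(ft$long_diam_mm[ft$latent_met]) -
      mean(ft$long_diam_mm[!ft$latent_met])
  }
  g <- c(gapAt(1), gapAt(1.4), gapAt(1.9))
  expect_true(all(diff(g) > 0))
})

test_that("rendered masks reproduce requested diameters within a pixel", {
  # the spec-level worked case
  set.seed(70)
  pm <- renderPatch(FALSE, 10, 5, spacing = 0.5, patchPx = 32L)
  dm <- computeDiameters(pm$mask, 0.5)
  expect_lt(abs(dm[["longDiamMm"]] - 10), 0.5 + 1e-9) # 1 px = 0.5 mm
  expect_lt(abs(dm[["shortDiamMm"]] - 5), 0.5 + 1e-9)
  # random shapes: rasterization noise (half a pixel) plus the half-pixel
  # corner-measurement convention bound the error by 1.25 px
  set.seed(7)
  for (i in 1:8) {
    long <- runif(1, 6, 13)
    short <- runif(1, 3, long * 0.9)
    pm <- renderPatch(FALSE, long, short, spacing = 0.5, patchPx = 32L)
    dm <- computeDiameters(pm$mask, 0.5)
    expect_lt(abs(dm[["longDiamMm"]] - long), 0.625 + 1e-9)
    expect_lt(abs(dm[["shortDiamMm"]] - short), 0.625 + 1e-9)
  }
})

test_that("patch rendering is bit-identical under a fixed RNG state", {
  set.seed(123)
  a <- renderPatch(TRUE, 10, 5, textureEffect = 2)
  set.seed(123)
  b <- renderPatch(TRUE, 10, 5, textureEffect = 2)
  expect_identical(a$patch, b$patch)
  expect_identical(a$mask, b$mask)
  expect_identical(a$adcPatch, b$adcPatch)
})

test_that("with zero texture effect the image carries no label signal", {
  set.seed(55)
  a <- renderPatch(TRUE, 9, 5, textureEffect = 0)
  set.seed(55)
  b <- renderPatch(FALSE, 9, 5, textureEffect = 0)
  expect_identical(a$patch, b$patch)
})

test_that("oversized nodes are rejected at rendering", {
  expect_error(renderPatch(FALSE, 40, 20, spacing = 0.5, patchPx = 32L),
               "larger than patch")
})
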