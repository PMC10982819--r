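test_that("the weak supervision loss reproduces closed forms", {
  expect_equal(weakSupervisionLoss(bagScores(0.5), y = 1, rho = 0,
                                   lambdaMil = 1, lambdaLlp = 0),
               log(2), tolerance = 1e-10)
  # hand-evaluated two-head value
  sc <- list(pMax = 0.8, pAvg = 0.2)
  expect_equal(weakSupervisionLoss(sc, y = 1, rho = 0.1),
               -log(0.8) - (0.1 * log(0.2) + 0.9 * log(0.8)),
               tolerance = 1e-10)
  # at-target minimum: loss reduces to the entropy of rho
  rho <- 0.3
  atTarget <- weakSupervisionLoss(list(pMax = 1 - 1e-7, pAvg = rho),
                                  y = 1, rho = rho)
  entropy <- -(rho * log(rho) + (1 - rho) * log(1 - rho))
  expect_equal(atTarget, entropy, tolerance = 1e-5)
  for (eps in c(-0.05, 0.05))
    expect_gt(weakSupervisionLoss(list(pMax = 1 - 1e-7, pAvg = rho + eps),
                                  y = 1, rho = rho), atTarget)
  expect_error(weakSupervisionLoss(sc, y = 1, rho = 1.2), "rho")
  expect_error(weakSupervisionLoss(sc, y = 1, rho = 0.1,
                                   lambdaMil = 0, lambdaLlp = 0), "weights")
})

test_that("loss is invariant to node order within a bag", {
  set.seed(8)
  p <- runif(9)
  l1 <- weakSupervisionLoss(bagScores(p), 1, 0.4)
  l2 <- weakSupervisionLoss(bagScores(sample(p)), 1, 0.4)
  expect_equal(l1, l2)
})

test_that("bag scoring preserves pooling identities", {
  co <- simulateCohort(cohortParams(nPatients = 6, seed = 3))
  m <- randomInitModel()
  for (b in bags(co)) {
    sc <- scoreBag(m, b)
    expect_length(sc$probs, length(b@nodes))
    expect_equal(sc$pMax, max(sc$probs))
    expect_equal(sc$pAvg, mean(sc$probs))
    expect_lte(sc$pAvg, sc$pMax)
    expect_true(all(sc$probs >= 0 & sc$probs <= 1))
    # repeated scoring is identical
    expect_identical(sc$probs, scoreBag(m, b)$probs)
  }
  b1 <- bags(co)[[1]]
  single <- new("PatientBag", patientId = "X", nodes = b1@nodes[1],
                nResected = 5L, nMetastatic = 0L, y = 0L, rho = 0,
                stageTrue = "N0", enrollOrder = 1L)
  sc1 <- scoreBag(m, single)
  expect_equal(sc1$pMax, sc1$probs[1])
  expect_equal(sc1$pAvg, sc1$probs[1])
  # duplicating a node leaves pMax unchanged, moves pAvg toward it
  dup <- new("PatientBag", patientId = "Y",
             nodes = c(b1@nodes, b1@nodes[which.max(sc1 <- scoreBag(m, b1)$probs)]),
             nResected = b1@nResected, nMetastatic = b1@nMetastatic,
             y = b1@y, rho = b1@rho, stageTrue = b1@stageTrue,
             enrollOrder = 1L)
  scd <- scoreBag(m, dup)
  scb <- scoreBag(m, b1)
  expect_equal(scd$pMax, scb$pMax)
  expect_equal(scd$pAvg,
               (sum(scb$probs) + max(scb$probs)) / (length(scb$probs) + 1))
})

test_that("backpropagated gradients match finite differences", {
  ns <- asNamespace("milstage")
  set.seed(42)
  H <- 8
  X <- matrix(rnorm(3 * H * H), 3, H * H)
  net <- ns$.initNet(2L, 3L)
  net$WA2 <- matrix(rnorm(length(net$WA2), 0, 0.1), nrow(net$WA2))
  net$WB2 <- matrix(rnorm(length(net$WB2), 0, 0.1), nrow(net$WB2))
  g <- ns$.net_bag_grad_cpp(net, X, 1, 0.4, 1, 1, H, H)
  lossAt <- function(w) ns$.net_bag_grad_cpp(w, X, 1, 0.4, 1, 1, H, H)$loss
  for (nm in names(net)) for (k in 1:3) {
    i <- sample(length(net[[nm]]), 1)
    eps <- 1e-5
    wp <- net; wp[[nm]][i] <- wp[[nm]][i] + eps
    wm <- net; wm[[nm]][i] <- wm[[nm]][i] - eps
    num <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
    expect_lt(abs(num - g$grads[[nm]][i]),
              1e-6 * max(1, abs(num)))
  }
})

test_that("the staging map is total, monotone and partitions the counts", {
  expect_identical(countToStage(0), "N0")
  expect_identical(countToStage(1), "N1")
  expect_identical(countToStage(3), "N1")
  expect_identical(countToStage(4), "N2")
  expect_identical(countToStage(35), "N2")
  ks <- 0:40
  st <- countToStage(ks)
  ord <- as.integer(factor(st, levels = c("N0", "N1", "N2")))
  expect_true(all(diff(ord) >= 0))
  expect_true(all(st %in% c("N0", "N1", "N2")))
  expect_error(countToStage(-1), "nonnegative")
  expect_error(countToStage(2.5), "nonnegative")
})

test_that("the patient decision rule counts and stages correctly", {
  dec <- stageFromProbs(c(0.9, 0.8, 0.7, 0.2), tau = 0.5)
  expect_identical(dec$kHat, 3L)
  expect_identical(dec$stagePred, "N1")
  expect_equal(dec$patientScore, 0.9)
  expect_identical(stageFromProbs(c(0.1, 0.2), 0.5)$kHat, 0L)
  expect_identical(stageFromProbs(c(0.1, 0.2), 0.5)$stagePred, "N0")
  # threshold monotonicity
  set.seed(12)
  p <- runif(20)
  taus <- sort(runif(6, 0.05, 0.95))
  ks <- vapply(taus, function(t) stageFromProbs(p, t)$kHat, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("predictPatient is consistent with scoreBag and the threshold", {
  co <- simulateCohort(cohortParams(nPatients = 4, seed = 6))
  m <- randomInitModel(seed = 2)
  for (b in bags(co)) {
    pr <- predictPatient(m, b)
    sc <- scoreBag(m, b)
    expect_identical(pr$kHat, as.integer(sum(sc$probs >= m@tau)))
    expect_equal(pr$patientScore, sc$pMax)
    expect_identical(pr$stagePred, countToStage(pr$kHat))
  }
})

test_that("identity fusion reproduces the intensity probabilities", {
  co <- simulateCohort(cohortParams(nPatients = 3, seed = 13))
  mi <- randomInitModel(seed = 3)
  mis <- new("NodeModel", variant = "M_IS", net = mi@net,
             fusion = list(W1 = matrix(0, 4, 8), b1 = rep(0, 8),
                           w2 = rep(0, 8), b2 = 0),
             featNames = milstage:::.fusionFeatNames("M_IS"),
             featCenter = c(0.3, 8, 5, 0.6), featScale = c(1.7, 3, 2, 0.2),
             tau = 0.5, config = list(), history = data.frame())
  misId <- identityFusion(mis)
  for (b in bags(co)) {
    expect_equal(scoreBag(misId, b)$probs, scoreBag(mi, b)$probs,
                 tolerance = 1e-6)
  }
})

test_that("variant feature contracts are enforced", {
  co <- simulateCohort(cohortParams(nPatients = 3, seed = 14))
  b <- bags(co)[[1]]
  n1 <- b@nodes[[1]]; n1@meanAdc <- NA_real_
  b@nodes[[1]] <- n1
  mi <- randomInitModel(seed = 4)
  misa <- new("NodeModel", variant = "M_ISA", net = mi@net,
              fusion = list(W1 = matrix(0, 5, 8), b1 = rep(0, 8),
                            w2 = rep(0, 8), b2 = 0),
              featNames = milstage:::.fusionFeatNames("M_ISA"),
              featCenter = rep(0, 5), featScale = rep(1, 5),
              tau = 0.5, config = list(), history = data.frame())
  expect_error(scoreBag(misa, b), "ADC")
})

test_that("short weakly supervised training reduces the bag loss", {
  co <- simulateCohort(cohortParams(nPatients = 50, textureEffect = 3,
                                    seed = 71))
  m <- trainIntensityModel(co, modelConfig(epochs = 8L, nStarts = 1L,
                                           warmupEpochs = 2L, seed = 1))
  h <- trainingHistory(m)
  expect_gt(nrow(h), 3)
  expect_lt(min(h$valLoss), h$valLoss[1] + 1e-8)
  expect_true(threshold(m) > 0 && threshold(m) < 1)
  # degenerate supervision warns
  co0 <- simulateCohort(cohortParams(nPatients = 6, patientLnmRate = 0,
                                     seed = 72))
  expect_warning(trainIntensityModel(
    co0, modelConfig(epochs = 2L, nStarts = 1L, warmupEpochs = 1L)),
    "degenerate")
})

test_that("LLP calibration pressure makes mean(pAvg) track mean(rho)", {
  tr <- simulateCohort(cohortParams(nPatients = 80, textureEffect = 3,
                                    seed = 81))
  te <- simulateCohort(cohortParams(nPatients = 40, textureEffect = 3,
                                    seed = 82))
  m <- trainIntensityModel(tr, modelConfig(epochs = 12L, nStarts = 2L,
                                           warmupEpochs = 4L, seed = 2))
  pAvg <- vapply(bags(te), function(b) scoreBag(m, b)$pAvg, numeric(1))
  rho <- vapply(bags(te), function(b) b@rho, numeric(1))
  expect_lt(abs(mean(pAvg) - mean(rho)), 0.1)
})
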