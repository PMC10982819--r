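test_that("AUC handles separation, ties and matches the pair oracle", {
  expect_equal(rocAUC(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1),
                      nBoot = 0)$auc, 1)
  expect_equal(rocAUC(rep(0.5, 8), c(0, 1, 0, 1, 0, 1, 0, 1),
                      nBoot = 0)$auc, 0.5)
  s8 <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.9, 0.5, 0.2)
  l8 <- c(0, 0, 1, 1, 0, 1, 1, 0)
  expect_equal(rocAUC(s8, l8, nBoot = 0)$auc, bruteAUC(s8, l8))
  set.seed(10)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE) # force ties
    expect_identical(rocAUC(sc, lab, nBoot = 0)$auc, bruteAUC(sc, lab))
  }
  expect_error(rocAUC(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC complement identity holds for tie-free scores", {
  set.seed(11)
  sc <- rnorm(40)
  lab <- rbinom(40, 1, 0.5); lab[1:2] <- c(0, 1)
  expect_equal(rocAUC(sc, lab, nBoot = 0)$auc +
                 rocAUC(-sc, lab, nBoot = 0)$auc, 1)
})

test_that("bootstrap CI brackets the point estimate and is seed-stable", {
  set.seed(12)
  sc <- c(rnorm(40), rnorm(40, 1.3))
  lab <- rep(c(0, 1), each = 40)
  r1 <- rocAUC(sc, lab, nBoot = 200, seed = 7)
  r2 <- rocAUC(sc, lab, nBoot = 200, seed = 7)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$auc)
  expect_gte(r1$ci[2], r1$auc)
})

test_that("the DeLong test is degenerate-safe, symmetric and consistent", {
  set.seed(13)
  lab <- rbinom(60, 1, 0.4); lab[1:2] <- c(0, 1)
  a <- rnorm(60) + lab
  d0 <- delongTest(a, a, lab)
  expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)
  expect_true(d0$degenerate)
  b <- rnorm(60) + 0.5 * lab
  d1 <- delongTest(a, b, lab)
  expect_equal(d1$aucA, rocAUC(a, lab, nBoot = 0)$auc)
  expect_equal(d1$aucB, rocAUC(b, lab, nBoot = 0)$auc)
  d2 <- delongTest(b, a, lab)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p, d2$p)
  expect_gt(d1$p, 0)
  expect_lte(d1$p, 1)
})

test_that("DeLong agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:5) {
    lab <- rbinom(50, 1, 0.5); lab[1:2] <- c(0, 1)
    u <- rnorm(50)
    a <- u + rnorm(50) + lab
    b <- u + rnorm(50) + 0.6 * lab
    ours <- delongTest(a, b, lab)
    ref <- pROC::roc.test(
      pROC::roc(lab, a, quiet = TRUE, direction = "<", levels = c(0, 1)),
      pROC::roc(lab, b, quiet = TRUE, direction = "<", levels = c(0, 1)),
      method = "delong")
    expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-8)
  }
})

test_that("count MAE matches hand arithmetic and the shift property", {
  expect_equal(countMAE(c(1, 2, 3), c(1, 2, 3), nBoot = 0)$mae, 0)
  expect_equal(countMAE(c(0, 2, 5), c(1, 2, 3), nBoot = 0)$mae, 1)
  k <- c(4, 5, 9); tr <- c(1, 2, 3)
  expect_equal(countMAE(k + 1, tr, nBoot = 0)$mae,
               countMAE(k, tr, nBoot = 0)$mae + 1)
  expect_error(countMAE(1:3, 1:4), "length")
})

test_that("the ordinal C index matches the exhaustive pair oracle", {
  expect_equal(cIndexOrdinal(c(0, 1, 2, 5), c("N0", "N1", "N1", "N2"))$cIndex,
               1)
  expect_equal(cIndexOrdinal(c(5, 3, 1), c("N0", "N1", "N2"))$cIndex, 0)
  p10 <- c(0, 2, 2, 1, 4, 0, 3, 2, 5, 1)
  t10 <- c(0, 1, 1, 0, 2, 1, 1, 2, 2, 0)
  expect_equal(cIndexOrdinal(p10, t10)$cIndex, bruteCIndex(p10, t10))
  set.seed(15)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    tr <- c(0, 1, sample(0:2, n - 2, replace = TRUE))
    pr <- sample(0:6, n, replace = TRUE)
    expect_identical(cIndexOrdinal(pr, tr)$cIndex, bruteCIndex(pr, tr))
  }
  expect_error(cIndexOrdinal(1:3, c(1, 1, 1)), "identical")
})

test_that("binary C index reduces to the ROC AUC", {
  set.seed(16)
  sc <- rnorm(40)
  lab <- rbinom(40, 1, 0.5); lab[1:2] <- c(0, 1)
  expect_equal(cIndexOrdinal(sc, lab)$cIndex, rocAUC(sc, lab, nBoot = 0)$auc)
})

test_that("agreement metrics reproduce closed-form kappa and F1", {
  perfect <- c("N0", "N1", "N2", "N1", "N0")
  ag <- agreementMetrics(perfect, perfect)
  expect_equal(ag$kappa, 1)
  expect_equal(unname(ag$f1), c(1, 1, 1))
  expect_equal(ag$accuracy, 1)
  # printed 2x2 table: a = 40, b = 10, c = 10, d = 40 -> kappa = 0.6
  pred <- c(rep("N0", 40), rep("N1", 10), rep("N0", 10), rep("N1", 40))
  truth <- c(rep("N0", 50), rep("N1", 50))
  ag2 <- agreementMetrics(pred, truth, levels = c("N0", "N1"))
  expect_equal(ag2$kappa, 0.6)
  expect_equal(sum(ag2$confusion), 100)
  # independent labels give kappa near zero
  set.seed(17)
  a <- sample(c("N0", "N1", "N2"), 4000, replace = TRUE)
  b <- sample(c("N0", "N1", "N2"), 4000, replace = TRUE)
  expect_lt(abs(agreementMetrics(a, b)$kappa), 0.05)
  expect_error(agreementMetrics(character(0), character(0)), "non-empty")
})

test_that("decision curves reproduce the closed forms and bounds", {
  set.seed(18)
  labels <- c(rep(1, 39), rep(0, 61))
  # all-negative model: net benefit identically zero
  dc0 <- decisionCurve(rep(0, 100), labels)
  expect_true(all(dc0$netBenefit == 0))
  expect_true(all(dc0$treatNone == 0))
  # treat-all closed form at prevalence 0.39, threshold 0.2
  row <- dc0[abs(dc0$threshold - 0.2) < 1e-9, ]
  expect_equal(row$treatAll, 0.39 - 0.61 * 0.25)
  # perfect model attains the prevalence bound everywhere
  dcp <- decisionCurve(labels, labels + 0)
  expect_true(all(abs(dcp$netBenefit - 0.39) < 1e-12))
  # no model exceeds the prevalence bound
  for (i in 1:5) {
    pr <- runif(100)
    expect_true(all(decisionCurve(pr, labels)$netBenefit <= mean(labels)))
  }
  expect_warning(decisionCurve(runif(10), rbinom(10, 1, 0.5),
                               thresholds = c(0, 0.5, 1)), "excluded")
})

test_that("calibration tables partition the data", {
  set.seed(19)
  p <- runif(500)
  y <- rbinom(500, 1, p)
  tab <- calibrationTable(p, y, nBins = 10)
  expect_equal(sum(tab$n), 500)
  expect_equal(nrow(tab), 10)
  # simulated-calibrated probabilities: observed near predicted per bin
  for (i in seq_len(nrow(tab))) if (tab$n[i] >= 30) {
    se <- sqrt(tab$meanPredicted[i] * (1 - tab$meanPredicted[i]) / tab$n[i])
    expect_lt(abs(tab$observedRate[i] - tab$meanPredicted[i]), 4 * se + 0.02)
  }
  # degenerate probabilities land in the extreme bins
  tab2 <- calibrationTable(c(rep(0, 5), rep(1, 5)),
                           c(rep(0, 5), rep(1, 5)), nBins = 5)
  expect_equal(tab2$observedRate[1], 0)
  expect_equal(tab2$observedRate[5], 1)
  expect_equal(sum(tab2$n), 10)
  expect_error(calibrationTable(runif(5), rbinom(5, 1, 0.5), nBins = 1),
               "nBins")
})

test_that("evaluateStaging assembles a coherent report", {
  set.seed(20)
  n <- 120
  kTrue <- rpois(n, 1.2)
  kHat <- pmax(0, kTrue + sample(c(-1, 0, 0, 1), n, replace = TRUE))
  pred <- data.frame(
    score = plogis(kHat + rnorm(n, 0, 0.5)),
    k_hat = kHat, stage_pred = countToStage(kHat),
    y = as.integer(kTrue > 0), n_metastatic = kTrue,
    stage_true = countToStage(kTrue))
  rep <- evaluateStaging(pred, nBoot = 100, seed = 3)
  expect_s4_class(rep, "EvalReport")
  expect_true(rep@auc >= 0 && rep@auc <= 1)
  expect_equal(sum(rep@confusion), n)
  expect_true(rep@kappa >= -1 && rep@kappa <= 1)
  expect_equal(rep@mae, mean(abs(kHat - kTrue)))
  expect_identical(
    rep@sensitivity, mean(kHat[kTrue > 0] >= 1))
  out <- capture.output(show(rep))
  expect_true(any(grepl("C index", out)))
})
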