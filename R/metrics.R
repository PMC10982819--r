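# percentile bootstrap CI over patients, optionally stratified by a binary
# label so both classes stay present in every resample
.bootCI <- function(stat, n, nBoot, seed, strata = NULL, conf = 0.95) {
  if (nBoot <= 0) return(c(NA_real_, NA_real_))
  vals <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      idx <- if (is.null(strata)) sample.int(n, n, replace = TRUE)
      else c(sample(which(strata == 1), sum(strata == 1), replace = TRUE),
             sample(which(strata == 0), sum(strata == 0), replace = TRUE))
      stat(idx)
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  stats::quantile(vals, c(a, 1 - a), names = FALSE, na.rm = TRUE)
}

.aucPoint <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores) # midranks give half credit to ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC computed by the midrank (Mann-Whitney) formula, equal to
#' \eqn{P(s^+ > s^-) + \frac{1}{2} P(s^+ = s^-)} over all positive/negative
#' pairs, with a stratified percentile-bootstrap CI.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), both classes present.
#' @param nBoot bootstrap resamples (0 skips the CI).
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return list with `auc` and `ci` (length 2).
#' @export
rocAUC <- function(scores, labels, nBoot = 2000L, seed = 1L, conf = 0.95) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2)
    stop("AUC undefined: both classes must be present")
  auc <- .aucPoint(scores, labels)
  ci <- .bootCI(function(idx) .aucPoint(scores[idx], labels[idx]),
                length(scores), nBoot, seed, strata = labels, conf = conf)
  list(auc = auc, ci = ci)
}

# placement values: for each positive, the fraction of negatives it beats
# (ties half credit), and vice versa
.placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg))
  rPos <- rank(pos); rNeg <- rank(neg)
  v10 <- (r[seq_len(n1)] - rPos) / n0
  v01 <- 1 - (r[n1 + seq_len(n0)] - rNeg) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated ROC curves
#'
#' Nonparametric comparison of the AUCs of two paired score sets on the
#' same cases, using the placement-value covariance estimator, with a
#' two-sided normal p value. Identical scores (zero-variance difference)
#' return p = 1 with a degeneracy flag.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels binary labels (0/1), both classes present.
#' @return list with `aucA`, `aucB`, `z`, `p`, `degenerate`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  labels <- as.integer(labels)
  if (length(scoresA) != length(labels) || length(scoresB) != length(labels))
    stop("scores and labels must be paired on identical cases")
  if (length(unique(labels)) < 2)
    stop("AUC undefined: both classes must be present")
  pa <- .placements(scoresA, labels)
  pb <- .placements(scoresB, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (!is.finite(varDiff) || varDiff < 1e-14)
    return(list(aucA = pa$auc, aucB = pb$auc, z = 0, p = 1,
                degenerate = TRUE))
  z <- (pa$auc - pb$auc) / sqrt(varDiff)
  list(aucA = pa$auc, aucB = pb$auc, z = z,
       p = min(1, 2 * stats::pnorm(-abs(z))), degenerate = FALSE)
}

#' Mean absolute error of metastatic-node counts
#'
#' @param kHat predicted counts per patient.
#' @param kTrue pathology-confirmed counts.
#' @param nBoot,seed,conf bootstrap CI settings.
#' @return list with `mae` and `ci`.
#' @export
countMAE <- function(kHat, kTrue, nBoot = 2000L, seed = 1L, conf = 0.95) {
  if (length(kHat) != length(kTrue)) stop("length mismatch")
  err <- abs(kHat - kTrue)
  ci <- .bootCI(function(idx) mean(err[idx]), length(err), nBoot, seed,
                conf = conf)
  list(mae = mean(err), ci = ci)
}

.cIndexPoint <- function(pred, truth) {
  dp <- outer(pred, pred, "-")
  dt <- outer(truth, truth, "-")
  comp <- upper.tri(dt) & dt != 0
  nComp <- sum(comp)
  if (nComp == 0) stop("C index undefined: all true stages identical")
  credit <- sum(dp[comp] * dt[comp] > 0) + 0.5 * sum(dp[comp] == 0)
  credit / nComp
}

#' Concordance index for ordinal staging
#'
#' Over all patient pairs with different true stages, the fraction ordered
#' consistently by the prediction, with half credit for tied predictions.
#' The predicted ordinal score is typically the predicted metastatic count
#' `kHat` (the default elsewhere in the package), but any ordinal score
#' works.
#'
#' @param pred per-patient ordinal predictions (numeric, or staging
#'   strings which are converted to their ordinal index).
#' @param truth per-patient true stages (same encodings accepted).
#' @param nBoot,seed,conf bootstrap CI settings (`nBoot = 0` skips).
#' @return list with `cIndex` and `ci`.
#' @export
cIndexOrdinal <- function(pred, truth, nBoot = 0L, seed = 1L, conf = 0.95) {
  toOrd <- function(x) if (is.character(x) || is.factor(x))
    as.numeric(factor(x, levels = c("N0", "N1", "N2"))) else as.numeric(x)
  p <- toOrd(pred); t <- toOrd(truth)
  if (length(p) != length(t)) stop("length mismatch")
  ci <- .bootCI(function(idx) tryCatch(.cIndexPoint(p[idx], t[idx]),
                                       error = function(e) NA_real_),
                length(p), nBoot, seed, conf = conf)
  list(cIndex = .cIndexPoint(p, t), ci = ci)
}

#' Ternary staging agreement metrics
#'
#' Confusion matrix (rows = truth), Cohen's kappa with marginal-product
#' expected agreement, per-class and macro F1 (zero convention for empty
#' classes), and accuracy.
#'
#' @param stagePred,stageTrue character vectors of stages
#'   (`"N0"`/`"N1"`/`"N2"`).
#' @param levels stage levels, in order.
#' @return list with `confusion`, `kappa`, `f1`, `f1Macro`, `accuracy`.
#' @export
agreementMetrics <- function(stagePred, stageTrue,
                             levels = c("N0", "N1", "N2")) {
  if (length(stagePred) != length(stageTrue) || length(stagePred) == 0)
    stop("stage vectors must be non-empty and of equal length")
  tp <- factor(stageTrue, levels = levels)
  pp <- factor(stagePred, levels = levels)
  cm <- table(truth = tp, predicted = pp)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) ifelse(po >= 1, 1, 0)
           else (po - pe) / (1 - pe)
  f1 <- vapply(seq_along(levels), function(i) {
    prec <- if (sum(cm[, i]) > 0) cm[i, i] / sum(cm[, i]) else 0
    rec <- if (sum(cm[i, ]) > 0) cm[i, i] / sum(cm[i, ]) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  names(f1) <- levels
  list(confusion = unclass(cm), kappa = kappa, f1 = f1,
       f1Macro = mean(f1), accuracy = po)
}

#' Decision curve analysis
#'
#' Net benefit of treating patients with predicted probability at or above
#' each threshold \eqn{p_t}:
#' \eqn{NB(p_t) = TP/n - (FP/n) \, p_t / (1 - p_t)}, together with the
#' treat-all curve \eqn{\pi - (1 - \pi) p_t / (1 - p_t)} at prevalence
#' \eqn{\pi} and the treat-none reference (identically zero).
#'
#' @param probs predicted probabilities.
#' @param labels binary outcome labels.
#' @param thresholds decision thresholds in (0, 1); endpoints are dropped
#'   with a warning.
#' @return data.frame with columns `threshold`, `netBenefit`, `treatAll`,
#'   `treatNone`.
#' @export
decisionCurve <- function(probs, labels,
                          thresholds = seq(0.05, 0.95, by = 0.05)) {
  bad <- thresholds <= 0 | thresholds >= 1
  if (any(bad)) {
    warning("thresholds in {0, 1} excluded from the decision curve")
    thresholds <- thresholds[!bad]
  }
  labels <- as.integer(labels)
  n <- length(labels)
  pi0 <- mean(labels)
  rows <- lapply(thresholds, function(pt) {
    pred <- probs >= pt
    tp <- sum(pred & labels == 1) / n
    fp <- sum(pred & labels == 0) / n
    w <- pt / (1 - pt)
    data.frame(threshold = pt, netBenefit = tp - fp * w,
               treatAll = pi0 - (1 - pi0) * w, treatNone = 0)
  })
  do.call(rbind, rows)
}

#' Calibration table
#'
#' Equal-width probability bins with per-bin mean predicted probability,
#' observed positive rate and count; empty bins are emitted with count 0.
#'
#' @param probs predicted probabilities.
#' @param labels binary outcome labels.
#' @param nBins number of bins (>= 2).
#' @return data.frame with columns `bin`, `lower`, `upper`,
#'   `meanPredicted`, `observedRate`, `n`.
#' @export
calibrationTable <- function(probs, labels, nBins = 10L) {
  if (nBins < 2) stop("nBins must be >= 2")
  labels <- as.integer(labels)
  breaks <- seq(0, 1, length.out = nBins + 1)
  bin <- findInterval(probs, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  rows <- lapply(seq_len(nBins), function(b) {
    sel <- bin == b
    data.frame(bin = b, lower = breaks[b], upper = breaks[b + 1],
               meanPredicted = if (any(sel)) mean(probs[sel]) else NA_real_,
               observedRate = if (any(sel)) mean(labels[sel]) else NA_real_,
               n = sum(sel))
  })
  do.call(rbind, rows)
}
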