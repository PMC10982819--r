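#' Evaluate staging predictions against pathology truth
#'
#' Assembles the full per-cohort metric suite into an
#' [EvalReport-class]: binary-staging ROC AUC of the max-pooled patient
#' score, sensitivity/specificity at the training-derived threshold
#' (positive = predicted count >= 1; never re-optimized on test data),
#' mean absolute error of the metastatic-node count, the ordinal
#' concordance index of the predicted count against the true ternary
#' stage, the staging confusion matrix with Cohen's kappa / F1, and
#' calibration and decision-curve tables.
#'
#' @param pred data.frame as returned by [predictCohort()] (columns
#'   `score`, `k_hat`, `stage_pred`, `y`, `n_metastatic`, `stage_true`).
#' @param nBoot,seed bootstrap settings for the CIs.
#' @return an [EvalReport-class].
#' @export
evaluateStaging <- function(pred, nBoot = 2000L, seed = 1L) {
  stopifnot(all(c("score", "k_hat", "stage_pred", "y", "n_metastatic",
                  "stage_true") %in% names(pred)))
  roc <- rocAUC(pred$score, pred$y, nBoot = nBoot, seed = seed)
  predPos <- pred$k_hat >= 1
  sens <- if (any(pred$y == 1)) mean(predPos[pred$y == 1]) else NA_real_
  spec <- if (any(pred$y == 0)) mean(!predPos[pred$y == 0]) else NA_real_
  mae <- countMAE(pred$k_hat, pred$n_metastatic, nBoot = nBoot, seed = seed)
  cidx <- cIndexOrdinal(pred$k_hat, pred$stage_true, nBoot = nBoot,
                        seed = seed)
  agr <- agreementMetrics(pred$stage_pred, pred$stage_true)
  new("EvalReport",
      auc = roc$auc, aucCI = roc$ci,
      sensitivity = sens, specificity = spec,
      mae = mae$mae, maeCI = mae$ci,
      cIndex = cidx$cIndex, cIndexCI = cidx$ci,
      confusion = agr$confusion, kappa = agr$kappa,
      f1 = agr$f1, f1Macro = agr$f1Macro, accuracy = agr$accuracy,
      calibration = calibrationTable(pred$score, pred$y),
      decision = decisionCurve(pred$score, pred$y))
}

#' Flatten an evaluation report to a named list
#'
#' @param report an [EvalReport-class].
#' @return named list of scalar metrics (tables omitted), convenient for
#'   JSON serialization.
#' @export
reportMetrics <- function(report) {
  list(auc = report@auc, auc_lo = report@aucCI[1], auc_hi = report@aucCI[2],
       sensitivity = report@sensitivity, specificity = report@specificity,
       mae = report@mae, mae_lo = report@maeCI[1], mae_hi = report@maeCI[2],
       c_index = report@cIndex, kappa = report@kappa,
       f1_macro = report@f1Macro, accuracy = report@accuracy)
}
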