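#' Map a metastatic-node count to the ternary N stage
#'
#' N0 for no metastatic nodes, N1 for one to three, N2 for four or more.
#'
#' @param k vector of nonnegative integer counts.
#' @return character vector of stages in `{"N0", "N1", "N2"}`.
#' @examples
#' countToStage(c(0, 1, 3, 4, 10))
#' @export
countToStage <- function(k) {
  if (any(!is.finite(k)) || any(k < 0) || any(abs(k - round(k)) > 1e-8))
    stop("k must be nonnegative integers")
  ifelse(k == 0, "N0", ifelse(k <= 3, "N1", "N2"))
}

#' Threshold node probabilities into a count, stage and patient score
#'
#' The patient-level decision rule: the predicted metastatic count is the
#' number of nodes with probability at least `tau`, the ternary stage
#' follows from [countToStage()], and the patient score used for ROC
#' analysis is the max-pooled probability (consistent with the MIL head).
#'
#' @param probs per-node probabilities.
#' @param tau decision threshold in (0, 1).
#' @return list with `kHat`, `stagePred`, `patientScore`.
#' @examples
#' stageFromProbs(c(0.9, 0.8, 0.7, 0.2), tau = 0.5)
#' @export
stageFromProbs <- function(probs, tau) {
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  kHat <- sum(probs >= tau)
  list(kHat = as.integer(kHat), stagePred = countToStage(kHat),
       patientScore = max(probs))
}

#' Score a bag of nodes
#'
#' Computes per-node metastatic probabilities for one patient under the
#' model's variant (intensity network alone for M_I; fusion of the
#' intensity probability with size and optionally ADC features for
#' M_IS/M_ISA), plus their max and mean pooled summaries. Scoring is
#' deterministic and order-preserving.
#'
#' @param model a trained [NodeModel-class].
#' @param bag a [PatientBag-class].
#' @return a [bagScores()] object.
#' @export
setGeneric("scoreBag", function(model, bag) standardGeneric("scoreBag"))

#' @rdname scoreBag
#' @export
setMethod("scoreBag", signature("NodeModel", "PatientBag"),
  function(model, bag) {
    st <- .stackPatches(list(bag))
    probsInt <- .netProbs(model@net, st$X, st$px)
    if (model@variant == "M_I") return(bagScores(probsInt))
    feats <- .fusionFeatures(list(bag), probsInt, model@variant)
    Z <- sweep(sweep(feats, 2, model@featCenter), 2, model@featScale, "/")
    bagScores(.sigmoid(.fusionLogits(model@fusion, Z)))
  })

#' Patient-level prediction
#'
#' Scores every node of the bag and applies the decision rule: nodes at or
#' above the fitted threshold count as metastatic, giving the predicted
#' count, the ternary stage and the max-pooled patient score.
#'
#' @param model a trained [NodeModel-class].
#' @param bag a [PatientBag-class].
#' @return list with `probs`, `kHat`, `patientScore`, `stagePred`.
#' @export
setGeneric("predictPatient", function(model, bag)
  standardGeneric("predictPatient"))

#' @rdname predictPatient
#' @export
setMethod("predictPatient", signature("NodeModel", "PatientBag"),
  function(model, bag) {
    sc <- scoreBag(model, bag)
    dec <- stageFromProbs(sc$probs, model@tau)
    list(probs = sc$probs, kHat = dec$kHat,
         patientScore = dec$patientScore, stagePred = dec$stagePred)
  })

#' Predict an entire cohort
#'
#' @param model a trained [NodeModel-class].
#' @param cohort an [LNCohort-class].
#' @return data.frame with one row per patient: id, max-pooled score,
#'   predicted count and stage, plus the pathology truth columns.
#' @export
predictCohort <- function(model, cohort) {
  rows <- lapply(bags(cohort), function(b) {
    pr <- predictPatient(model, b)
    data.frame(patient_id = b@patientId, score = pr$patientScore,
               k_hat = pr$kHat, stage_pred = pr$stagePred,
               y = b@y, n_metastatic = b@nMetastatic,
               stage_true = b@stageTrue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# stacked node probabilities for a list of bags (used by evaluation and
# tests); returns probs plus 0-based offsets
.scoreBagSet <- function(model, bagList) {
  st <- .stackPatches(bagList)
  probsInt <- .netProbs(model@net, st$X, st$px)
  if (model@variant == "M_I") probs <- probsInt
  else {
    feats <- .fusionFeatures(bagList, probsInt, model@variant)
    Z <- sweep(sweep(feats, 2, model@featCenter), 2, model@featScale, "/")
    probs <- .sigmoid(.fusionLogits(model@fusion, Z))
  }
  list(probs = probs, start = st$start, len = st$len)
}
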