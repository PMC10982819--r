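#' Accessors for cohort, bag and model objects
#'
#' Small accessor layer over the S4 containers: `bags()` returns the list
#' of patient bags of a cohort, `nodes()` the lymph nodes of a bag,
#' `patientId()` / `trueStage()` / `bagLabel()` patient-level fields,
#' `variant()` and `threshold()` model metadata, and `trainingHistory()`
#' the per-epoch loss table.
#'
#' @param object a [LNCohort-class], [PatientBag-class] or
#'   [NodeModel-class] object as appropriate.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bags", function(object) standardGeneric("bags"))
#' @rdname accessors
#' @export
setGeneric("nodes", function(object) standardGeneric("nodes"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("bagLabel", function(object) standardGeneric("bagLabel"))
#' @rdname accessors
#' @export
setGeneric("trueStage", function(object) standardGeneric("trueStage"))
#' @rdname accessors
#' @export
setGeneric("variant", function(object) standardGeneric("variant"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))

#' @rdname accessors
#' @export
setMethod("bags", "LNCohort", function(object) object@bags)
#' @rdname accessors
#' @export
setMethod("nodes", "PatientBag", function(object) object@nodes)
#' @rdname accessors
#' @export
setMethod("patientId", "PatientBag", function(object) object@patientId)
#' @rdname accessors
#' @export
setMethod("bagLabel", "PatientBag", function(object) object@y)
#' @rdname accessors
#' @export
setMethod("trueStage", "PatientBag", function(object) object@stageTrue)
#' @rdname accessors
#' @export
setMethod("variant", "NodeModel", function(object) object@variant)
#' @rdname accessors
#' @export
setMethod("threshold", "NodeModel", function(object) object@tau)
#' @rdname accessors
#' @export
setMethod("trainingHistory", "NodeModel", function(object) object@history)

setMethod("show", "CohortParams", function(object) {
  cat("CohortParams:", object@nPatients, "patients, LNM rate",
      object@patientLnmRate, "\n")
  cat("  visible nodes ~", object@visibleLnMean, "+/-", object@visibleLnSd,
      "(trunc 5-50); met count mean", object@metCountMean,
      "dispersion", object@metCountDispersion, "\n")
  cat("  effects: size x", object@sizeEffect, ", ADC +", object@adcEffect,
      ", texture", object@textureEffect,
      "; hidden-node rate", object@hiddenNodeRate, "\n")
  cat("  patch", object@patchPx, "px @", object@pixelSpacing,
      "mm/px; seed", object@seed, "\n")
})

setMethod("show", "PatientBag", function(object) {
  cat("PatientBag", object@patientId, ":", length(object@nodes),
      "visible nodes;", object@nMetastatic, "of", object@nResected,
      "resected nodes metastatic; y =", object@y,
      "; stage", object@stageTrue, "\n")
})

setMethod("show", "LNCohort", function(object) {
  n <- length(object@bags)
  pos <- sum(vapply(object@bags, function(b) b@y, integer(1)))
  nn <- sum(vapply(object@bags, function(b) length(b@nodes), integer(1)))
  cat("LNCohort:", n, "patients (", pos, "LN-positive ),", nn,
      "visible nodes\n")
})

setMethod("show", "NodeModel", function(object) {
  cat("NodeModel variant", object@variant, "; tau =",
      format(object@tau, digits = 4), "\n")
  if (nrow(object@history))
    cat("  trained", nrow(object@history), "epochs; final val loss",
        format(utils::tail(object@history$valLoss, 1), digits = 4), "\n")
})

setMethod("show", "NodeHeatmap", function(object) {
  cat("NodeHeatmap", paste(dim(object@map), collapse = "x"),
      "; hotspot:", object@hotspotLabel, "\n")
})

setMethod("show", "EvalReport", function(object) {
  cat("Staging evaluation\n")
  cat(sprintf("  binary AUC %.3f (95%% CI %.3f-%.3f); sens %.3f spec %.3f\n",
              object@auc, object@aucCI[1], object@aucCI[2],
              object@sensitivity, object@specificity))
  cat(sprintf("  count MAE %.3f (%.3f-%.3f); ternary C index %.3f (%.3f-%.3f)\n",
              object@mae, object@maeCI[1], object@maeCI[2],
              object@cIndex, object@cIndexCI[1], object@cIndexCI[2]))
  cat(sprintf("  kappa %.3f; macro F1 %.3f; accuracy %.3f\n",
              object@kappa, object@f1Macro, object@accuracy))
})
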