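#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Simulation parameters for a synthetic lymph-node cohort
#'
#' Population parameters of the synthetic cohort generator. Defaults follow
#' the cohort statistics the package targets: about 14 +/- 5 resected nodes
#' per patient (truncated to 5--50), a 39\% patient-level metastasis rate,
#' and a heavy-tailed metastatic-node count (1.6 +/- 3.2 overall, range
#' 0--35), obtained from a zero-truncated negative binomial for positive
#' patients.
#'
#' @slot nPatients number of patients to simulate.
#' @slot patientLnmRate probability that a patient harbours any metastatic
#'   node.
#' @slot visibleLnMean,visibleLnSd mean and SD of the per-patient visible
#'   node count before truncation to \code{[5, 50]}.
#' @slot metCountMean mean metastatic-node count among positive patients.
#' @slot metCountDispersion negative-binomial size (dispersion) parameter of
#'   the metastatic count; counts are truncated to \code{[1, 35]} for
#'   positive patients.
#' @slot sizeEffect multiplicative shift of metastatic-node diameters.
#' @slot adcEffect additive shift of metastatic-node mean ADC, in
#'   10^-3 mm^2/s.
#' @slot textureEffect contrast of the intranodal/perinodal texture blob in
#'   rendered metastatic patches; 0 removes all image-level signal.
#' @slot hiddenNodeRate expected fraction of resected nodes not visible at
#'   MRI.
#' @slot patchPx patch side length in pixels (>= 16, divisible by 4).
#' @slot pixelSpacing pixel spacing in mm/pixel.
#' @slot seed integer seed driving the hierarchical per-patient/per-node
#'   random streams.
#' @seealso [cohortParams()], [simulateCohort()]
#' @export
setClass("CohortParams",
  representation(
    nPatients = "integer",
    patientLnmRate = "numeric",
    visibleLnMean = "numeric",
    visibleLnSd = "numeric",
    metCountMean = "numeric",
    metCountDispersion = "numeric",
    sizeEffect = "numeric",
    adcEffect = "numeric",
    textureEffect = "numeric",
    hiddenNodeRate = "numeric",
    patchPx = "integer",
    pixelSpacing = "numeric",
    seed = "integer"
  )
)

setValidity("CohortParams", function(object) {
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(length(object@nPatients) == 1 && object@nPatients >= 1L,
      "nPatients: must be a positive integer")
  chk(length(object@patientLnmRate) == 1 &&
        object@patientLnmRate >= 0 && object@patientLnmRate <= 1,
      "patientLnmRate: must lie in [0, 1]")
  chk(object@visibleLnMean >= 5 && object@visibleLnMean <= 50,
      "visibleLnMean: must lie in [5, 50]")
  chk(object@visibleLnSd > 0, "visibleLnSd: must be positive")
  chk(object@metCountMean > 0, "metCountMean: must be positive")
  chk(object@metCountDispersion > 0, "metCountDispersion: must be positive")
  chk(object@sizeEffect > 0, "sizeEffect: must be positive")
  chk(object@textureEffect >= 0, "textureEffect: must be nonnegative")
  chk(object@hiddenNodeRate >= 0 && object@hiddenNodeRate < 1,
      "hiddenNodeRate: must lie in [0, 1)")
  chk(object@patchPx >= 16L && object@patchPx %% 4L == 0L,
      "patchPx: must be >= 16 and divisible by 4")
  chk(object@pixelSpacing > 0, "pixelSpacing: must be positive")
  if (length(bad)) bad else TRUE
})

#' One MRI-visible lymph node
#'
#' Holds the extracted T2-like patch, its binary mask, an optional ADC
#' patch, the per-node morphometric features and (for synthetic nodes) the
#' latent metastatic truth.
#'
#' @slot nodeId node identifier.
#' @slot patch numeric matrix, normalized T2-like intensities.
#' @slot mask binary (0/1) numeric matrix on the same grid.
#' @slot adcPatch numeric matrix in 10^-3 mm^2/s, or NULL when diffusion
#'   imaging is absent.
#' @slot longDiamMm,shortDiamMm long- and short-axis diameters in mm.
#' @slot diamRatio short/long diameter ratio, in (0, 1].
#' @slot meanAdc mean ADC over the mask, or NA.
#' @slot latentMet latent metastatic status (synthetic truth only), or NA.
#' @slot prob predicted metastatic probability once scored, or NA.
#' @export
setClass("LymphNode",
  representation(
    nodeId = "character",
    patch = "matrix",
    mask = "matrix",
    adcPatch = "matrixOrNULL",
    longDiamMm = "numeric",
    shortDiamMm = "numeric",
    diamRatio = "numeric",
    meanAdc = "numeric",
    latentMet = "logical",
    prob = "numeric"
  ),
  prototype(adcPatch = NULL, meanAdc = NA_real_, latentMet = NA,
            prob = NA_real_)
)

setValidity("LymphNode", function(object) {
  bad <- character(0)
  if (!all(dim(object@patch) == dim(object@mask)))
    bad <- c(bad, "patch and mask must share a grid")
  if (sum(object@mask > 0.5) < 1) bad <- c(bad, "mask must be non-empty")
  if (!is.na(object@shortDiamMm) && !is.na(object@longDiamMm) &&
      object@shortDiamMm > object@longDiamMm + 1e-9)
    bad <- c(bad, "shortDiamMm must not exceed longDiamMm")
  if (!is.na(object@diamRatio) &&
      (object@diamRatio <= 0 || object@diamRatio > 1 + 1e-9))
    bad <- c(bad, "diamRatio must lie in (0, 1]")
  if (!is.na(object@prob) && (object@prob < 0 || object@prob > 1))
    bad <- c(bad, "prob must lie in [0, 1]")
  if (length(bad)) bad else TRUE
})

#' A patient's bag of lymph nodes with patient-level pathology labels
#'
#' The weak-supervision unit: all MRI-visible nodes of one patient together
#' with the pathology report quantities (resected and metastatic node
#' counts), from which the binary label, the metastatic proportion and the
#' true ternary N stage derive.
#'
#' @slot patientId patient identifier.
#' @slot nodes list of [LymphNode-class] objects (MRI-visible nodes).
#' @slot nResected number of resected nodes (pathology denominator); may
#'   exceed the number of visible nodes.
#' @slot nMetastatic number of pathology-confirmed metastatic nodes.
#' @slot y binary metastasis label, \code{1L} iff \code{nMetastatic > 0}.
#' @slot rho metastatic proportion \code{nMetastatic / nResected}.
#' @slot stageTrue true ternary stage, one of \code{"N0"}, \code{"N1"},
#'   \code{"N2"}.
#' @slot enrollOrder integer enrollment rank used for chronological splits.
#' @export
setClass("PatientBag",
  representation(
    patientId = "character",
    nodes = "list",
    nResected = "integer",
    nMetastatic = "integer",
    y = "integer",
    rho = "numeric",
    stageTrue = "character",
    enrollOrder = "integer"
  )
)

setValidity("PatientBag", function(object) {
  bad <- character(0)
  if (length(object@nodes) < 1) bad <- c(bad, "bag must contain >= 1 node")
  if (object@nMetastatic < 0L || object@nMetastatic > object@nResected)
    bad <- c(bad, "need 0 <= nMetastatic <= nResected")
  if (object@rho < 0 || object@rho > 1) bad <- c(bad, "rho must lie in [0, 1]")
  if (abs(object@rho - object@nMetastatic / object@nResected) > 1e-8)
    bad <- c(bad, "rho must equal nMetastatic / nResected")
  if (object@y != as.integer(object@nMetastatic > 0L))
    bad <- c(bad, "y must equal (nMetastatic > 0)")
  if (!identical(object@stageTrue, countToStage(object@nMetastatic)))
    bad <- c(bad, "stageTrue inconsistent with nMetastatic")
  if (length(bad)) bad else TRUE
})

#' A cohort of patient bags
#'
#' @slot bags list of [PatientBag-class] objects.
#' @slot params the [CohortParams-class] used to generate the cohort, or
#'   NULL for cohorts assembled from real data.
#' @export
setClass("LNCohort",
  representation(bags = "list", params = "ANY"),
  prototype(params = NULL)
)

setValidity("LNCohort", function(object) {
  if (!all(vapply(object@bags, is, logical(1), "PatientBag")))
    return("bags must all be PatientBag objects")
  TRUE
})

#' A trained weakly supervised node classifier
#'
#' Wraps the residual convolutional intensity scorer, the optional fusion
#' perceptron (for the intensity+size and intensity+size+ADC variants), the
#' feature standardization statistics frozen on the training split, the
#' decision threshold tau fitted on training bags, and the training history.
#'
#' @slot variant one of \code{"M_I"} (intensity only), \code{"M_IS"}
#'   (+ size) or \code{"M_ISA"} (+ size and ADC).
#' @slot net list of convolutional network weight matrices.
#' @slot fusion list of fusion perceptron weights, or empty for M_I.
#' @slot featNames,featCenter,featScale fusion feature names and the
#'   training-split standardization statistics.
#' @slot tau decision threshold for per-node positivity, fitted on training
#'   bags only.
#' @slot config resolved training configuration.
#' @slot history per-epoch training and validation losses.
#' @export
setClass("NodeModel",
  representation(
    variant = "character",
    net = "list",
    fusion = "list",
    featNames = "character",
    featCenter = "numeric",
    featScale = "numeric",
    tau = "numeric",
    config = "list",
    history = "data.frame"
  ),
  prototype(fusion = list(), featNames = character(0),
            featCenter = numeric(0), featScale = numeric(0), tau = 0.5)
)

setValidity("NodeModel", function(object) {
  if (!object@variant %in% c("M_I", "M_IS", "M_ISA"))
    return("variant must be one of M_I, M_IS, M_ISA")
  if (object@tau <= 0 || object@tau >= 1)
    return("tau must lie in (0, 1)")
  if (object@variant != "M_I" && length(object@fusion) == 0)
    return("fusion weights required for variants M_IS / M_ISA")
  TRUE
})

#' Grad-CAM heatmap for one node patch
#'
#' @slot map relevance map aligned to the patch grid, min-max normalized to
#'   \code{[0, 1]}.
#' @slot hotspotLabel one of \code{"intranodal"}, \code{"perinodal"},
#'   \code{"outside"}, \code{"none"}.
#' @slot hotspotFractions named fractions of supra-threshold pixels falling
#'   in the intranodal / perinodal / outside regions.
#' @export
setClass("NodeHeatmap",
  representation(map = "matrix", hotspotLabel = "character",
                 hotspotFractions = "numeric")
)

setValidity("NodeHeatmap", function(object) {
  if (any(object@map < -1e-9) || any(object@map > 1 + 1e-9))
    return("map values must lie in [0, 1]")
  if (!object@hotspotLabel %in% c("intranodal", "perinodal", "outside", "none"))
    return("invalid hotspot label")
  if (sum(object@hotspotFractions) > 1 + 1e-9)
    return("hotspot fractions must sum to <= 1")
  TRUE
})

#' Staging evaluation report
#'
#' Per-cohort metric suite: binary-staging ROC AUC with bootstrap CI,
#' sensitivity/specificity at the training-derived threshold, mean absolute
#' error of the metastatic-node count, ordinal concordance index for
#' ternary staging, the 3x3 staging confusion matrix with Cohen's kappa and
#' F1 scores, and calibration / decision-curve tables.
#'
#' @slot auc,aucCI binary-staging AUC and 95\% bootstrap CI.
#' @slot sensitivity,specificity operating point at the fitted threshold.
#' @slot mae,maeCI count mean absolute error and CI.
#' @slot cIndex,cIndexCI ternary-staging concordance index and CI.
#' @slot confusion 3x3 confusion matrix, rows = true stage.
#' @slot kappa Cohen's kappa for the ternary staging.
#' @slot f1 per-class F1 scores; \code{f1Macro} their unweighted mean.
#' @slot f1Macro macro-averaged F1.
#' @slot accuracy ternary staging accuracy.
#' @slot calibration calibration table (bin, mean predicted, observed, n).
#' @slot decision decision-curve table (threshold, model / treat-all /
#'   treat-none net benefit).
#' @export
setClass("EvalReport",
  representation(
    auc = "numeric", aucCI = "numeric",
    sensitivity = "numeric", specificity = "numeric",
    mae = "numeric", maeCI = "numeric",
    cIndex = "numeric", cIndexCI = "numeric",
    confusion = "matrix", kappa = "numeric",
    f1 = "numeric", f1Macro = "numeric", accuracy = "numeric",
    calibration = "data.frame", decision = "data.frame"
  )
)
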