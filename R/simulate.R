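#' Construct simulation parameters for a synthetic cohort
#'
#' Builds a validated [CohortParams-class] object. The defaults emulate the
#' population structure the weak-supervision training assumes: roughly 14
#' +/- 5 visible nodes per patient (truncated to 5--50), a 39\% patient
#' metastasis rate, and a heavy-tailed metastatic count drawn from a
#' zero-truncated negative binomial whose positive-patient mean (4.1) and
#' dispersion (1.4) give an overall mean near 1.6 and SD near 3.2 with
#' range capped at 35. Metastatic nodes have diameters scaled by
#' `sizeEffect`, mean ADC shifted by `adcEffect` (10^-3 mm^2/s) and, when
#' `textureEffect > 0`, an intranodal or perinodal high-contrast blob in
#' the rendered patch.
#'
#' @param nPatients number of patients.
#' @param patientLnmRate probability a patient is LN-positive.
#' @param visibleLnMean,visibleLnSd visible node count distribution
#'   (normal, rounded, truncated to 5--50).
#' @param metCountMean,metCountDispersion positive-patient metastatic count
#'   distribution (zero-truncated negative binomial, capped at 35).
#' @param sizeEffect multiplicative diameter shift for metastatic nodes.
#' @param adcEffect additive mean-ADC shift for metastatic nodes.
#' @param textureEffect amplitude of the metastatic texture blob; 0 removes
#'   all image-level signal.
#' @param hiddenNodeRate expected fraction of resected nodes invisible at
#'   MRI (0 gives exact visible/resected agreement).
#' @param patchPx patch side in pixels.
#' @param pixelSpacing mm per pixel.
#' @param seed integer master seed.
#' @return a [CohortParams-class] object.
#' @examples
#' p <- cohortParams(nPatients = 5, seed = 1)
#' cohort <- simulateCohort(p)
#' @export
cohortParams <- function(nPatients = 100L,
                         patientLnmRate = 0.39,
                         visibleLnMean = 14,
                         visibleLnSd = 5,
                         metCountMean = 4.1,
                         metCountDispersion = 1.4,
                         sizeEffect = 1.6,
                         adcEffect = 0.25,
                         textureEffect = 1,
                         hiddenNodeRate = 0,
                         patchPx = 32L,
                         pixelSpacing = 0.5,
                         seed = 1L) {
  new("CohortParams",
      nPatients = as.integer(nPatients),
      patientLnmRate = patientLnmRate,
      visibleLnMean = visibleLnMean,
      visibleLnSd = visibleLnSd,
      metCountMean = metCountMean,
      metCountDispersion = metCountDispersion,
      sizeEffect = sizeEffect,
      adcEffect = adcEffect,
      textureEffect = textureEffect,
      hiddenNodeRate = hiddenNodeRate,
      patchPx = as.integer(patchPx),
      pixelSpacing = pixelSpacing,
      seed = as.integer(seed))
}

# rejection-sampled truncated normal, rounded to integer counts
.rTruncCount <- function(mean, sd, lo, hi) {
  repeat {
    x <- round(stats::rnorm(1, mean, sd))
    if (x >= lo && x <= hi) return(as.integer(x))
  }
}

# zero-truncated negative binomial capped at `hi`
.rZTNB <- function(mu, size, hi) {
  repeat {
    k <- stats::rnbinom(1, mu = mu, size = size)
    if (k >= 1 && k <= hi) return(as.integer(k))
  }
}

#' Render one synthetic node patch
#'
#' Rasterizes a rotated ellipse mask at the requested diameters and renders
#' a T2-like intensity patch (background noise plus nodal signal) together
#' with an ADC patch. Metastatic nodes additionally receive an intranodal
#' (probability 0.6) or perinodal high-contrast Gaussian blob whose
#' amplitude is proportional to `textureEffect`; at `textureEffect = 0`
#' metastatic and benign patches are drawn from identical image
#' distributions, so any label signal is carried by size/ADC features only.
#' Draws come from R's current RNG stream; seed beforehand for
#' reproducibility.
#'
#' @param latentMet logical, latent metastatic status.
#' @param longDiamMm,shortDiamMm requested diameters in mm; the rasterized
#'   mask reproduces them within about one pixel.
#' @param textureEffect blob amplitude multiplier.
#' @param spacing mm per pixel.
#' @param patchPx patch side in pixels.
#' @param adcMean mean ADC inside the node (10^-3 mm^2/s).
#' @return list with `patch`, binary `mask` and `adcPatch` matrices.
#' @examples
#' set.seed(7)
#' pm <- renderPatch(TRUE, 10, 5, textureEffect = 2)
#' @export
renderPatch <- function(latentMet, longDiamMm, shortDiamMm,
                        textureEffect = 1, spacing = 0.5, patchPx = 32L,
                        adcMean = 1.0) {
  P <- as.integer(patchPx)
  a <- (longDiamMm / 2) / spacing
  b <- (shortDiamMm / 2) / spacing
  if (2 * a > P - 2)
    stop("node larger than patch: long diameter ", longDiamMm,
         " mm does not fit in ", P, " px at ", spacing, " mm/px")
  theta <- stats::runif(1, 0, pi)
  ctr <- (P - 1) / 2
  maxOff <- max(0, min(1, ctr - a - 0.5))
  cr <- ctr + stats::runif(1, -maxOff, maxOff)
  cc <- ctr + stats::runif(1, -maxOff, maxOff)
  rr <- matrix(0:(P - 1), P, P) - cr
  cols <- matrix(0:(P - 1), P, P, byrow = TRUE) - cc
  u <- cols * cos(theta) + rr * sin(theta)
  v <- -cols * sin(theta) + rr * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask <- matrix(as.numeric(inside), P, P)
  if (sum(mask) == 0) { # degenerate sub-pixel node: keep the center pixel
    mask[round(cr) + 1, round(cc) + 1] <- 1
    inside <- mask > 0.5
  }
  patch <- matrix(0.40 + stats::rnorm(P * P, 0, 0.12), P, P)
  nodeInt <- 0.25 + stats::rnorm(1, 0, 0.04)
  patch[inside] <- patch[inside] + nodeInt
  if (isTRUE(latentMet) && textureEffect > 0) {
    ang <- stats::runif(1, 0, 2 * pi)
    if (stats::runif(1) < 0.6) rad <- sqrt(stats::runif(1)) * 0.6
    else rad <- stats::runif(1, 1.05, 1.35)
    u0 <- rad * a * cos(ang)
    v0 <- rad * b * sin(ang)
    r0 <- cr + u0 * sin(theta) + v0 * cos(theta)
    c0 <- cc + u0 * cos(theta) - v0 * sin(theta)
    sig <- max(1.2, b / 3)
    d2 <- (matrix(0:(P - 1), P, P) - r0)^2 +
      (matrix(0:(P - 1), P, P, byrow = TRUE) - c0)^2
    patch <- patch + 0.3 * textureEffect * exp(-d2 / (2 * sig^2))
  }
  adcPatch <- matrix(1.4 + stats::rnorm(P * P, 0, 0.10), P, P)
  adcPatch[inside] <- adcMean + stats::rnorm(sum(inside), 0, 0.05)
  list(patch = patch, mask = mask, adcPatch = adcPatch)
}

# Draw one visible node conditionally on its latent metastatic status.
# Patches emulate the extraction stage's output: a crop of twice the
# node's bounding box resampled to a fixed grid, so the rendered node
# always spans about half the patch and absolute size is carried by the
# diameter features (in mm), not by the image. The per-node effective
# pixel spacing follows from that zoom.
.simulateNode <- function(params, met, nodeId, render = TRUE) {
  shortMm <- stats::rlnorm(1, log(4.2), 0.35) *
    (if (met) params@sizeEffect else 1)
  ratio <- 0.35 + 0.6 * stats::rbeta(1, 4, 2)
  shortMm <- max(shortMm, 1)
  longMm <- shortMm / ratio
  adcTrue <- max(0.3, stats::rnorm(1, 1.0 + (if (met) params@adcEffect else 0),
                                   0.15))
  if (render) {
    spacingNode <- 2 * longMm / params@patchPx
    pm <- renderPatch(met, longMm, shortMm, params@textureEffect,
                      spacingNode, params@patchPx, adcTrue)
    dm <- computeDiameters(pm$mask, spacingNode)
    new("LymphNode", nodeId = nodeId, patch = pm$patch, mask = pm$mask,
        adcPatch = pm$adcPatch,
        longDiamMm = dm[["longDiamMm"]], shortDiamMm = dm[["shortDiamMm"]],
        diamRatio = dm[["diamRatio"]],
        meanAdc = meanADC(pm$mask, pm$adcPatch),
        latentMet = met)
  } else {
    ph <- matrix(0, 4, 4)
    new("LymphNode", nodeId = nodeId, patch = ph,
        mask = matrix(1, 4, 4), adcPatch = NULL,
        longDiamMm = longMm, shortDiamMm = shortMm,
        diamRatio = shortMm / longMm, meanAdc = adcTrue, latentMet = met)
  }
}

#' Simulate a synthetic patient cohort
#'
#' Generates patient bags with the statistical structure the weak
#' supervision assumes: per-patient visible node counts, a Bernoulli
#' patient metastasis label, a zero-truncated negative-binomial metastatic
#' count for positive patients, optional hidden (resected but MRI-
#' invisible) nodes, and per-node features/patches drawn conditionally on
#' the latent metastatic status. A single master seed drives hierarchical
#' per-patient and per-node substreams, so cohorts are reproducible and
#' order-independent; the caller's RNG state is left untouched.
#'
#' @param params a [CohortParams-class] object.
#' @param render if `FALSE`, skip patch rendering and store the drawn
#'   feature values with placeholder patches; useful for fast statistical
#'   checks on cohort-level quantities.
#' @return an [LNCohort-class] object.
#' @examples
#' cohort <- simulateCohort(cohortParams(nPatients = 4, seed = 42))
#' cohort
#' @export
simulateCohort <- function(params, render = TRUE) {
  validObject(params)
  bagsOut <- vector("list", params@nPatients)
  .withSeed(params@seed, {
    for (i in seq_len(params@nPatients)) {
      set.seed(.mixSeed(params@seed, 11, i))
      nVis <- .rTruncCount(params@visibleLnMean, params@visibleLnSd, 5, 50)
      pos <- stats::runif(1) < params@patientLnmRate
      h <- params@hiddenNodeRate
      nHidden <- if (h > 0) stats::rpois(1, nVis * h / (1 - h)) else 0L
      nRes <- nVis + as.integer(nHidden)
      K <- if (pos) .rZTNB(params@metCountMean, params@metCountDispersion, 35)
           else 0L
      K <- min(K, nRes)
      metIds <- if (K > 0) sample.int(nRes, K) else integer(0)
      pid <- sprintf("P%04d", i)
      nodesOut <- vector("list", nVis)
      for (j in seq_len(nVis)) {
        set.seed(.mixSeed(params@seed, 13, i, j))
        nodesOut[[j]] <- .simulateNode(params, j %in% metIds,
                                       sprintf("%s_N%02d", pid, j), render)
      }
      bagsOut[[i]] <- new("PatientBag", patientId = pid, nodes = nodesOut,
                          nResected = as.integer(nRes),
                          nMetastatic = as.integer(K),
                          y = as.integer(K > 0), rho = K / nRes,
                          stageTrue = countToStage(K),
                          enrollOrder = as.integer(i))
    }
  })
  new("LNCohort", bags = bagsOut, params = params)
}
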