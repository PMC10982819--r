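#' Bag-level score summary
#'
#' Wraps per-node probabilities with their max and mean, the two pooled
#' quantities the weak supervision matches to the patient label and the
#' metastatic proportion.
#'
#' @param probs numeric vector of per-node probabilities in `[0, 1]`.
#' @return object of class `BagScores` with elements `probs`, `pMax`,
#'   `pAvg`.
#' @export
bagScores <- function(probs) {
  if (length(probs) < 1 || any(probs < 0 | probs > 1))
    stop("probs must be a non-empty vector of probabilities")
  structure(list(probs = probs, pMax = max(probs), pAvg = mean(probs)),
            class = "BagScores")
}

.bce <- function(p, t, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(t * log(p) + (1 - t) * log(1 - p))
}

#' Weak supervision loss for one bag
#'
#' The two-head loss that couples node-level probabilities to patient-level
#' pathology: a multiple-instance learning term matching the max-pooled
#' probability to the binary metastasis label, plus a learning-from-label-
#' proportions term matching the average-pooled probability to the
#' metastatic proportion among resected nodes:
#' \deqn{L = \lambda_{mil} \, BCE(p^{max}, y) +
#'       \lambda_{llp} \, BCE(p^{avg}, \rho)}
#' with soft-target binary cross-entropy
#' \eqn{BCE(p, t) = -[t \log p + (1 - t) \log(1 - p)]} and probability
#' clamping at 1e-7.
#'
#' @param scores a [bagScores()] object (or any list with `pMax`, `pAvg`).
#' @param y binary patient label.
#' @param rho metastatic proportion target in `[0, 1]`; must be 0 when
#'   `y = 0`.
#' @param lambdaMil,lambdaLlp nonnegative head weights, not both zero.
#' @return nonnegative scalar loss.
#' @examples
#' weakSupervisionLoss(bagScores(c(0.5)), y = 1, rho = 0.5,
#'                     lambdaMil = 1, lambdaLlp = 0) # log(2)
#' @export
weakSupervisionLoss <- function(scores, y, rho, lambdaMil = 1,
                                lambdaLlp = 1) {
  if (lambdaMil < 0 || lambdaLlp < 0 || lambdaMil + lambdaLlp <= 0)
    stop("head weights must be nonnegative and not both zero")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (y == 0 && rho > 0) stop("rho must be 0 for label-negative bags")
  lambdaMil * .bce(scores$pMax, y) + lambdaLlp * .bce(scores$pAvg, rho)
}
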