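# Independent oracles and small fixture builders used across the suite.

# exhaustive pairwise AUC with half credit for ties
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive pairwise concordance index (numeric ordinal truth)
bruteCIndex <- function(pred, truth) {
  credit <- 0
  comp <- 0
  n <- length(pred)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (truth[i] == truth[j]) next
    comp <- comp + 1
    d <- (pred[i] - pred[j]) * (truth[i] - truth[j])
    credit <- credit + (d > 0) + 0.5 * (d == 0)
  }
  credit / comp
}

# caliper-scan diameter oracle on mask pixel corners: long axis = max
# pairwise corner distance, short axis = min projection width over an
# exhaustive 0.5-degree angle scan
caliperDiameters <- function(mask, spacing) {
  fg <- which(mask > 0.5, arr.ind = TRUE)
  y <- rep(fg[, 1], each = 4) + c(-0.5, -0.5, 0.5, 0.5)
  x <- rep(fg[, 2], each = 4) + c(-0.5, 0.5, -0.5, 0.5)
  pts <- cbind(x * spacing, y * spacing)
  hull <- pts[chull(pts), , drop = FALSE]
  long <- max(dist(hull))
  th <- seq(0, pi, by = 0.5 * pi / 180)
  widths <- vapply(th, function(a) {
    pr <- hull %*% c(cos(a), sin(a))
    max(pr) - min(pr)
  }, numeric(1))
  c(long = long, short = min(widths))
}

# rasterized rotated ellipse mask (pixel centers, 0-based geometry)
ellipseMask <- function(n, aPx, bPx, theta = 0, cr = NULL, cc = NULL) {
  if (is.null(cr)) cr <- (n - 1) / 2
  if (is.null(cc)) cc <- (n - 1) / 2
  rr <- matrix(0:(n - 1), n, n) - cr
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE) - cc
  u <- cols * cos(theta) + rr * sin(theta)
  v <- -cols * sin(theta) + rr * cos(theta)
  matrix(as.numeric((u / aPx)^2 + (v / bPx)^2 <= 1), n, n)
}

# an untrained (random-weight) intensity model, enough for scoring paths
randomInitModel <- function(seed = 1, C0 = 4L, C1 = 6L) {
  set.seed(seed)
  new("NodeModel", variant = "M_I", net = milstage:::.initNet(C0, C1),
      tau = 0.5, config = list(), history = data.frame())
}

# fast feature-only cohort (placeholder patches)
statCohort <- function(n, seed, ...) {
  simulateCohort(cohortParams(nPatients = n, seed = seed, ...),
                 render = FALSE)
}

latentTruth <- function(cohort) {
  unlist(lapply(bags(cohort), function(b)
    vapply(b@nodes, function(nd) nd@latentMet, logical(1))))
}

bagY <- function(cohort) vapply(bags(cohort), function(b) b@y, integer(1))

nodeAUCvsLatent <- function(model, cohort) {
  sc <- milstage:::.scoreBagSet(model, bags(cohort))
  rocAUC(sc$probs, as.integer(latentTruth(cohort)), nBoot = 0)$auc
}

patientAUC <- function(model, cohort) {
  sc <- vapply(bags(cohort), function(b) scoreBag(model, b)$pMax, numeric(1))
  rocAUC(sc, bagY(cohort), nBoot = 0)$auc
}
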