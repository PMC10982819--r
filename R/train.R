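#' Training configuration
#'
#' Resolved hyperparameters for the weakly supervised training loop.
#' Mini-batches are whole bags; optimization is Adam with global
#' gradient-norm clipping at 5; early stopping monitors the validation
#' bag loss with the given patience and the best-validation weights are
#' kept. The decision threshold tau is fitted on training bags only, by
#' maximizing Youden's J of the max-pooled bag score against the binary
#' label, and is then reused for per-node counting.
#'
#' @param variant model variant: `"M_I"` (intensity), `"M_IS"` (+ size),
#'   `"M_ISA"` (+ size + ADC).
#' @param lambdaMil,lambdaLlp weights of the MIL (max-pooling) and LLP
#'   (average-pooling) loss heads.
#' @param channels channel widths `c(C0, C1)` of the two convolutional
#'   stages.
#' @param epochs,lr,valFraction,patience,clip optimizer schedule: maximum
#'   epochs, Adam learning rate, fraction of bags held out for validation,
#'   early-stopping patience (epochs), gradient-norm clip.
#' @param nStarts,warmupEpochs number of random initializations probed for
#'   `warmupEpochs` epochs each; the start with the best validation loss is
#'   then trained to completion. Multiple starts guard against the
#'   occasional initialization that never escapes the constant-probability
#'   plateau of the weakly supervised loss.
#' @param lrDecay multiplicative learning-rate decay applied after 75\% of
#'   the epochs.
#' @param fusionHidden,fusionEpochs,fusionLr fusion perceptron size and
#'   schedule (variants M_IS / M_ISA).
#' @param seed integer seed for weight initialization, the train/validation
#'   split and epoch shuffling.
#' @return a named list of class `ModelConfig`.
#' @export
modelConfig <- function(variant = c("M_I", "M_IS", "M_ISA"),
                        lambdaMil = 1, lambdaLlp = 1,
                        channels = c(8L, 16L),
                        epochs = 30L, lr = 5e-3, valFraction = 0.2,
                        patience = 12L, clip = 5,
                        nStarts = 3L, warmupEpochs = 6L, lrDecay = 0.3,
                        fusionHidden = 8L, fusionEpochs = 300L,
                        fusionLr = 5e-3,
                        seed = 1L) {
  variant <- match.arg(variant)
  if (lambdaMil < 0 || lambdaLlp < 0 || lambdaMil + lambdaLlp <= 0)
    stop("lambdaMil + lambdaLlp must be positive")
  structure(list(variant = variant, lambdaMil = lambdaMil,
                 lambdaLlp = lambdaLlp, channels = as.integer(channels),
                 epochs = as.integer(epochs), lr = lr,
                 valFraction = valFraction, patience = as.integer(patience),
                 clip = clip, nStarts = as.integer(nStarts),
                 warmupEpochs = as.integer(warmupEpochs), lrDecay = lrDecay,
                 fusionHidden = as.integer(fusionHidden),
                 fusionEpochs = as.integer(fusionEpochs),
                 fusionLr = fusionLr, seed = as.integer(seed)),
            class = "ModelConfig")
}

# mean weak-supervision loss over bags, from stacked per-node probabilities
.bagSetLoss <- function(probs, start, len, y, rho, lambdaMil, lambdaLlp) {
  tot <- 0
  for (b in seq_along(len)) {
    p <- probs[(start[b] + 1):(start[b] + len[b])]
    tot <- tot + lambdaMil * .bce(max(p), y[b]) +
      lambdaLlp * .bce(mean(p), rho[b])
  }
  tot / length(len)
}

# Youden-optimal threshold of scores against binary labels, evaluated at
# midpoints of consecutive distinct scores
.fitThreshold <- function(scores, labels) {
  u <- sort(unique(scores))
  if (length(u) < 2) return(min(max(0.5, 1e-3), 1 - 1e-3))
  cand <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(cand, function(th) {
    pred <- scores >= th
    tpr <- if (any(labels == 1)) mean(pred[labels == 1]) else 0
    fpr <- if (any(labels == 0)) mean(pred[labels == 0]) else 0
    tpr - fpr
  }, numeric(1))
  tau <- cand[which.max(j)]
  min(max(tau, 1e-6), 1 - 1e-6)
}

.bagField <- function(bagList, f) vapply(bagList, function(b) slot(b, f),
                                         numeric(1))

#' Train the intensity diagnostic network
#'
#' Trains the residual convolutional instance scorer from patient-level
#' labels only, using the two-head weak supervision loss
#' ([weakSupervisionLoss()]): the max-pooled node probability is matched to
#' the binary metastasis label (MIL head) and the average-pooled
#' probability to the metastatic proportion among resected nodes (LLP
#' head). Each mini-batch is one whole bag. Training is reproducible for a
#' fixed `config$seed`.
#'
#' @param cohort an [LNCohort-class] of training bags.
#' @param config a [modelConfig()]; the variant is forced to `"M_I"`.
#' @return a trained [NodeModel-class] (variant M_I) with fitted threshold
#'   and loss history.
#' @export
trainIntensityModel <- function(cohort, config = modelConfig()) {
  bagList <- bags(cohort)
  if (length(bagList) < 2) stop("need at least two bags")
  y <- .bagField(bagList, "y")
  rho <- .bagField(bagList, "rho")
  if (length(unique(y)) == 1)
    warning("degenerate supervision: all patient labels identical")
  .withSeed(config$seed, {
    nVal <- max(1L, round(config$valFraction * length(bagList)))
    valIdx <- sample.int(length(bagList), nVal)
    trIdx <- setdiff(seq_along(bagList), valIdx)
    tr <- .stackPatches(bagList[trIdx])
    va <- .stackPatches(bagList[valIdx])
    valLossOf <- function(net) {
      vaProbs <- .netProbs(net, va$X, va$px)
      .bagSetLoss(vaProbs, va$start, va$len, y[valIdx], rho[valIdx],
                  config$lambdaMil, config$lambdaLlp)
    }
    runEpochs <- function(state, nEp, epOffset) {
      for (ep in seq_len(nEp)) {
        epGlobal <- epOffset + ep
        lrEp <- config$lr *
          if (epGlobal > 0.75 * config$epochs) config$lrDecay else 1
        ord <- sample.int(length(trIdx)) - 1L
        up <- .net_train_epoch_cpp(state$net, state$m, state$v, state$t,
                                   tr$X, as.integer(tr$start),
                                   as.integer(tr$len), as.integer(ord),
                                   y[trIdx], rho[trIdx],
                                   config$lambdaMil, config$lambdaLlp,
                                   lrEp, 0.9, 0.999, 1e-8, config$clip,
                                   tr$px, tr$px)
        state$net <- up$w; state$m <- up$m; state$v <- up$v; state$t <- up$t
        vl <- valLossOf(state$net)
        state$hist <- rbind(state$hist,
                            data.frame(epoch = epGlobal, trainLoss = up$loss,
                                       valLoss = vl))
        if (vl < state$best$loss - 1e-6) {
          state$best <- list(loss = vl, net = state$net)
          state$bad <- 0L
        } else state$bad <- state$bad + 1L
        if (state$bad >= config$patience) break
      }
      state
    }
    newState <- function() {
      net <- .initNet(config$channels[1], config$channels[2])
      list(net = net, m = .zerosLike(net), v = .zerosLike(net), t = 0L,
           best = list(loss = Inf, net = net), bad = 0L,
           hist = data.frame(epoch = integer(0), trainLoss = numeric(0),
                             valLoss = numeric(0)))
    }
    # probe several initializations briefly, then train the best one out
    warm <- min(config$warmupEpochs, config$epochs)
    states <- lapply(seq_len(max(1L, config$nStarts)), function(k)
      runEpochs(newState(), warm, 0L))
    state <- states[[which.min(vapply(states, function(s) s$best$loss,
                                      numeric(1)))]]
    state$bad <- 0L
    state <- runEpochs(state, config$epochs - warm, warm)
    net <- state$best$net
    hist <- state$hist
    # operating threshold from training bags only
    trProbs <- .netProbs(net, tr$X, tr$px)
    pMax <- vapply(seq_along(trIdx), function(b)
      max(trProbs[(tr$start[b] + 1):(tr$start[b] + tr$len[b])]), numeric(1))
    tau <- .fitThreshold(pMax, y[trIdx])
    cfg <- config; cfg$variant <- "M_I"
    new("NodeModel", variant = "M_I", net = net, tau = tau,
        config = unclass(cfg), history = hist)
  })
}

# ---- fusion perceptron (variants M_IS / M_ISA) ------------------------------

.fusionFeatNames <- function(variant) {
  c("pLogit", "longDiamMm", "shortDiamMm", "diamRatio",
    if (variant == "M_ISA") "meanAdc")
}

# raw (unstandardized) fusion features for a list of bags, given intensity
# probabilities stacked over the same bags
.fusionFeatures <- function(bagList, probsInt, variant) {
  eps <- 1e-7
  pl <- stats::qlogis(pmin(pmax(probsInt, eps), 1 - eps))
  long <- unlist(lapply(bagList, function(b)
    vapply(b@nodes, function(n) n@longDiamMm, numeric(1))))
  short <- unlist(lapply(bagList, function(b)
    vapply(b@nodes, function(n) n@shortDiamMm, numeric(1))))
  ratio <- unlist(lapply(bagList, function(b)
    vapply(b@nodes, function(n) n@diamRatio, numeric(1))))
  X <- cbind(pLogit = pl, longDiamMm = long, shortDiamMm = short,
             diamRatio = ratio)
  if (variant == "M_ISA") {
    adc <- unlist(lapply(bagList, function(b)
      vapply(b@nodes, function(n) n@meanAdc, numeric(1))))
    if (anyNA(adc))
      stop("variant M_ISA requires a mean ADC value for every node")
    X <- cbind(X, meanAdc = adc)
  }
  X
}

.initFusion <- function(d, hidden) {
  list(W1 = matrix(stats::rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden),
       b1 = rep(0, hidden),
       w2 = stats::rnorm(hidden, 0, sqrt(1 / hidden)),
       b2 = 0)
}

.fusionLogits <- function(fw, X) {
  H <- X %*% fw$W1
  H <- sweep(H, 2, fw$b1, "+")
  H[H < 0] <- 0
  drop(H %*% fw$w2 + fw$b2)
}

# Adam-trained fusion MLP under the identical bag loss. Weights are
# selected by the loss on held-out validation bags (Xv and companions),
# evaluated every few epochs; several random starts guard against bad
# initializations.
# identity pass-through weights: reproduce the intensity probability
# exactly from the standardized logit feature (column 1)
.idFusionWeights <- function(d, hidden, scale1, center1) {
  fw <- list(W1 = matrix(0, d, hidden), b1 = rep(0, hidden),
             w2 = rep(0, hidden), b2 = center1)
  fw$W1[1, 1] <- 1; fw$W1[1, 2] <- -1
  fw$w2[1] <- scale1; fw$w2[2] <- -scale1
  fw
}

.trainFusion <- function(X, start, len, y, rho, config,
                         Xv = NULL, startV = NULL, lenV = NULL,
                         yV = NULL, rhoV = NULL, idFw = NULL) {
  inits <- lapply(seq_len(max(1L, config$nStarts)), function(k) NULL)
  # one candidate is warm-started at the identity (pure intensity model);
  # the untrained identity itself also competes, so fusion can only match
  # or improve on the intensity model under the selection loss
  if (!is.null(idFw)) inits[[1]] <- idFw
  runs <- lapply(inits, function(init)
    .trainFusionOnce(X, start, len, y, rho, config, Xv, startV, lenV,
                     yV, rhoV, init))
  if (!is.null(idFw))
    runs <- c(runs, list(.evalFusion(idFw, X, start, len, y, rho, config,
                                     Xv, startV, lenV, yV, rhoV)))
  runs[[which.min(vapply(runs, function(r) r$loss, numeric(1)))]]$fw
}

.fusionSelLoss <- function(fw, X, start, len, y, rho, config,
                           Xv, startV, lenV, yV, rhoV) {
  if (is.null(Xv)) {
    probs <- .sigmoid(.fusionLogits(fw, X))
    .bagSetLoss(probs, start, len, y, rho,
                config$lambdaMil, config$lambdaLlp)
  } else {
    probs <- .sigmoid(.fusionLogits(fw, Xv))
    .bagSetLoss(probs, startV, lenV, yV, rhoV,
                config$lambdaMil, config$lambdaLlp)
  }
}

.evalFusion <- function(fw, X, start, len, y, rho, config,
                        Xv, startV, lenV, yV, rhoV) {
  list(loss = .fusionSelLoss(fw, X, start, len, y, rho, config,
                             Xv, startV, lenV, yV, rhoV), fw = fw)
}

.trainFusionOnce <- function(X, start, len, y, rho, config,
                             Xv, startV, lenV, yV, rhoV, init = NULL) {
  d <- ncol(X)
  fw <- if (is.null(init)) .initFusion(d, config$fusionHidden) else init
  m <- lapply(fw, function(p) p * 0)
  v <- lapply(fw, function(p) p * 0)
  t <- 0
  nBags <- length(len)
  selLoss <- function(fw) .fusionSelLoss(fw, X, start, len, y, rho, config,
                                         Xv, startV, lenV, yV, rhoV)
  best <- list(loss = selLoss(fw), fw = fw)
  for (ep in seq_len(config$fusionEpochs)) {
    ord <- sample.int(nBags)
    for (b in ord) {
      rows <- (start[b] + 1):(start[b] + len[b])
      Xb <- X[rows, , drop = FALSE]
      Hb <- sweep(Xb %*% fw$W1, 2, fw$b1, "+")
      act <- Hb > 0
      Hb[!act] <- 0
      z <- drop(Hb %*% fw$w2 + fw$b2)
      p <- .sigmoid(z)
      n <- length(p)
      imax <- which.max(p)
      pmax <- p[imax]; pavg <- mean(p)
      dz <- rep(0, n)
      if (config$lambdaMil > 0)
        dz[imax] <- dz[imax] + config$lambdaMil * (pmax - y[b])
      if (config$lambdaLlp > 0) {
        common <- config$lambdaLlp * (pavg - rho[b]) /
          max(pavg * (1 - pavg), 1e-12) / n
        dz <- dz + common * p * (1 - p)
      }
      g <- list(W1 = NULL, b1 = NULL, w2 = drop(t(Hb) %*% dz), b2 = sum(dz))
      dH <- outer(dz, fw$w2) * act
      g$W1 <- t(Xb) %*% dH
      g$b1 <- colSums(dH)
      nrm <- sqrt(sum(unlist(g)^2))
      if (config$clip > 0 && nrm > config$clip)
        g <- lapply(g, function(x) x * config$clip / nrm)
      t <- t + 1
      for (k in names(fw)) {
        m[[k]] <- 0.9 * m[[k]] + 0.1 * g[[k]]
        v[[k]] <- 0.999 * v[[k]] + 0.001 * g[[k]]^2
        fw[[k]] <- fw[[k]] - config$fusionLr *
          (m[[k]] / (1 - 0.9^t)) / (sqrt(v[[k]] / (1 - 0.999^t)) + 1e-8)
      }
    }
    if (ep %% 10 == 0 || ep == config$fusionEpochs) {
      l <- selLoss(fw)
      if (l < best$loss - 1e-7) best <- list(loss = l, fw = fw)
    }
  }
  best
}

#' Train an integrated (fusion) diagnostic model
#'
#' Trains the multilayer-perceptron fusion scorer that combines the
#' intensity-based metastatic probability with the size features
#' (long/short diameters and their ratio) and, for variant `"M_ISA"`, the
#' mean ADC value, under the identical weak supervision loss. The
#' intensity probability enters on the logit scale, and all features are
#' standardized with statistics fitted on the training bags only.
#'
#' @param cohort an [LNCohort-class] of training bags.
#' @param intensityModel a trained variant-`"M_I"` [NodeModel-class].
#' @param config a [modelConfig()] with `variant` `"M_IS"` or `"M_ISA"`.
#' @return a trained fusion [NodeModel-class].
#' @export
trainIntegratedModel <- function(cohort, intensityModel,
                                 config = modelConfig(variant = "M_IS")) {
  if (!config$variant %in% c("M_IS", "M_ISA"))
    stop("config$variant must be M_IS or M_ISA for the integrated model")
  if (variant(intensityModel) != "M_I")
    stop("intensityModel must be a trained M_I model")
  bagList <- bags(cohort)
  y <- .bagField(bagList, "y")
  rho <- .bagField(bagList, "rho")
  .withSeed(config$seed + 1L, {
    st <- .stackPatches(bagList)
    probsInt <- .netProbs(intensityModel@net, st$X, st$px)
    feats <- .fusionFeatures(bagList, probsInt, config$variant)
    nVal <- max(1L, round(config$valFraction * length(bagList)))
    valIdx <- sample.int(length(bagList), nVal)
    trIdx <- setdiff(seq_along(bagList), valIdx)
    trRows <- unlist(lapply(trIdx, function(b)
      (st$start[b] + 1):(st$start[b] + st$len[b])))
    ctr <- colMeans(feats[trRows, , drop = FALSE])
    scl <- apply(feats[trRows, , drop = FALSE], 2, stats::sd)
    scl[scl < 1e-8] <- 1
    Z <- sweep(sweep(feats, 2, ctr), 2, scl, "/")
    # re-index the training and validation rows as compact stacked sets
    trLen <- st$len[trIdx]
    trStart <- cumsum(c(0L, trLen[-length(trLen)]))
    vaRows <- unlist(lapply(valIdx, function(b)
      (st$start[b] + 1):(st$start[b] + st$len[b])))
    vaLen <- st$len[valIdx]
    vaStart <- cumsum(c(0L, vaLen[-length(vaLen)]))
    fw <- .trainFusion(Z[trRows, , drop = FALSE], trStart, trLen,
                       y[trIdx], rho[trIdx], config,
                       Xv = Z[vaRows, , drop = FALSE], startV = vaStart,
                       lenV = vaLen, yV = y[valIdx], rhoV = rho[valIdx],
                       idFw = .idFusionWeights(ncol(Z), config$fusionHidden,
                                               scl[1], ctr[1]))
    probsAll <- .sigmoid(.fusionLogits(fw, Z))
    pMaxTr <- vapply(seq_along(trIdx), function(b) {
      rows <- (trStart[b] + 1):(trStart[b] + trLen[b])
      max(probsAll[trRows][rows])
    }, numeric(1))
    tau <- .fitThreshold(pMaxTr, y[trIdx])
    new("NodeModel", variant = config$variant, net = intensityModel@net,
        fusion = fw, featNames = .fusionFeatNames(config$variant),
        featCenter = ctr, featScale = scl, tau = tau,
        config = unclass(config), history = intensityModel@history)
  })
}

#' Replace a fusion scorer by an exact pass-through of the intensity
#' probability
#'
#' Builds fusion weights that reproduce the intensity probability exactly
#' (two ReLU units implementing the identity on the standardized logit
#' feature), so the fused model's bag scores coincide with the intensity
#' model's. Mainly a reference point for testing and ablation.
#'
#' @param model a fusion [NodeModel-class] (variant M_IS or M_ISA).
#' @return the model with identity fusion weights.
#' @export
identityFusion <- function(model) {
  if (variant(model) == "M_I") stop("model has no fusion scorer")
  d <- length(model@featNames)
  hidden <- max(2L, length(model@fusion$b1))
  model@fusion <- .idFusionWeights(d, hidden, model@featScale[1],
                                   model@featCenter[1])
  model
}
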