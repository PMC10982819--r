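#' Grad-CAM relevance map for a node patch
#'
#' Gradient-weighted class activation mapping over the intensity network's
#' last convolutional feature maps: each channel is weighted by the
#' spatial mean of the gradient of the metastasis logit with respect to
#' that channel, the weighted sum is rectified (ReLU), bilinearly
#' upsampled to the patch grid and min-max normalized to `[0, 1]`. A map
#' that is zero everywhere before normalization stays all-zero. The fusion
#' perceptron contributes no spatial map; heatmaps always come from the
#' convolutional intensity path.
#'
#' @param model a [NodeModel-class] whose `net` slot holds the
#'   convolutional scorer.
#' @param patch raw (unnormalized) intensity patch; the same robust
#'   normalization used for scoring is applied internally.
#' @return numeric matrix of the patch size with values in `[0, 1]`.
#' @export
gradCAM <- function(model, patch) {
  if (is(model, "NodeModel")) {
    if (length(model@net) == 0)
      stop("model has no convolutional feature maps (fusion-only path)")
    net <- model@net
  } else if (is.list(model) && !is.null(model$W0)) net <- model
  else stop("model has no convolutional feature maps (fusion-only path)")
  px <- nrow(patch)
  x <- as.numeric(normalizeIntensity(patch))
  fm <- .net_maps_cpp(net, x, px, px)
  # channel weights: spatial mean of d logit / d featuremap
  alpha <- rowMeans(fm$grad)
  cam <- drop(t(fm$maps) %*% alpha)          # length H4*W4
  cam[cam < 0] <- 0
  camM <- matrix(cam, fm$H4, fm$W4, byrow = TRUE) # spatial index s = r*W + c
  up <- .resample(camM, px, bilinear = TRUE)
  up[up < 0] <- 0
  mx <- max(up)
  if (mx <= 0) return(matrix(0, px, px))
  up / mx
}

#' Classify the hotspot region of a heatmap
#'
#' Thresholds the heatmap at `level` times its maximum and asks where the
#' supra-threshold pixels fall: inside the node mask (intranodal), in a
#' morphological dilation ring of `ringPx` pixels around it (perinodal),
#' or outside both. The label is the region holding the largest share of
#' supra-threshold pixels (ties broken intranodal > perinodal > outside);
#' an everywhere-zero map gets label `"none"`. The rule is invariant to
#' monotone rescaling of the heatmap.
#'
#' @param map relevance map.
#' @param mask binary node mask on the same grid.
#' @param ringPx ring width in pixels (>= 1); the default used elsewhere in
#'   the package is 3 mm converted at the pixel spacing.
#' @param level fraction of the map maximum defining "highlighted".
#' @return list with `label` and named `fractions`
#'   (intranodal/perinodal/outside shares of supra-threshold pixels).
#' @export
classifyHotspot <- function(map, mask, ringPx = 6L, level = 0.5) {
  if (!all(dim(map) == dim(mask)))
    stop("map and mask must share a grid")
  if (ringPx < 1) stop("ringPx must be >= 1")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  mx <- max(map)
  frac <- c(intranodal = 0, perinodal = 0, outside = 0)
  if (mx <= 0)
    return(list(label = "none", fractions = frac))
  hot <- map >= level * mx
  core <- mask > 0.5
  brush <- EBImage::makeBrush(2L * as.integer(ringPx) + 1L, shape = "disc")
  dil <- EBImage::dilate(EBImage::Image(mask), brush) > 0.5
  dil <- matrix(as.logical(dil), nrow(mask), ncol(mask))
  ring <- dil & !core
  n <- sum(hot)
  frac <- c(intranodal = sum(hot & core) / n,
            perinodal = sum(hot & ring) / n,
            outside = sum(hot & !core & !ring) / n)
  label <- c("intranodal", "perinodal", "outside")[which.max(frac)]
  list(label = label, fractions = frac)
}

#' Explain one node
#'
#' Convenience wrapper: Grad-CAM map plus hotspot classification, returned
#' as a [NodeHeatmap-class].
#'
#' @param model a trained [NodeModel-class].
#' @param node a [LymphNode-class].
#' @param spacing mm per pixel of the patch grid; sets the default ring
#'   width of 3 mm.
#' @param ringPx override the ring width in pixels.
#' @param level hotspot threshold as a fraction of the map maximum.
#' @return a [NodeHeatmap-class].
#' @export
explainNode <- function(model, node, spacing = 0.5, ringPx = NULL,
                        level = 0.5) {
  if (is.null(ringPx)) ringPx <- as.integer(ceiling(3 / spacing))
  map <- gradCAM(model, node@patch)
  hs <- classifyHotspot(map, node@mask, ringPx = ringPx, level = level)
  new("NodeHeatmap", map = map, hotspotLabel = hs$label,
      hotspotFractions = hs$fractions)
}
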