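#' Long/short axis diameters of a node mask
#'
#' Computes the radiological long- and short-axis diameters of a binary
#' mask as the two edge lengths of a rotated bounding rectangle of the
#' foreground, found by rotating calipers over the convex hull of the
#' foreground pixel corners. Pixel coordinates are
#' converted to mm before any geometry, so anisotropic spacing is handled
#' exactly; using pixel corners (not centers) makes an axis-aligned
#' \eqn{40 \times 10} pixel rectangle measure exactly 40 x 10 pixels.
#'
#' A single-pixel mask yields both diameters equal to one pixel's mm
#' extent (degenerate convention).
#'
#' Two axis conventions are provided. The default, `"rectangle"`, reports
#' the edges of the rotated bounding rectangle oriented along the minimum
#' caliper width of the mask (for a rectangular or elongated convex mask
#' this is the minimum-area rotated rectangle, but the minimum-width
#' orientation is far more stable under rasterization, where min-area
#' boxes of mid-eccentricity ellipses snap to diagonal orientations and
#' misstate the axes by several pixels). The alternative, `"caliper"`,
#' reports the maximum pairwise distance between boundary points (maximum
#' Feret diameter) and the minimum caliper width. The two agree within a
#' pixel on elongated shapes.
#'
#' @param mask binary matrix (foreground = values > 0.5).
#' @param spacing mm per pixel; scalar for isotropic grids or
#'   `c(rowSpacing, colSpacing)`.
#' @param method axis convention, `"rectangle"` (default) or `"caliper"`.
#' @return named numeric vector `longDiamMm`, `shortDiamMm`, `diamRatio`
#'   (= short/long, in (0, 1]).
#' @examples
#' m <- matrix(0, 20, 50); m[6:15, 6:45] <- 1
#' computeDiameters(m, 0.5) # 20 x 5 mm
#' @export
computeDiameters <- function(mask, spacing,
                             method = c("rectangle", "caliper")) {
  method <- match.arg(method)
  sp <- if (length(spacing) == 1) c(spacing, spacing) else spacing[1:2]
  if (any(sp <= 0)) stop("spacing must be strictly positive")
  fg <- which(mask > 0.5, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty mask: no foreground pixels to measure")
  bd <- .boundaryPixels(mask, fg)
  # corners of each boundary pixel, in mm
  y <- rep(bd[, 1], each = 4) + c(-0.5, -0.5, 0.5, 0.5)
  x <- rep(bd[, 2], each = 4) + c(-0.5, 0.5, -0.5, 0.5)
  pts <- cbind(x * sp[2], y * sp[1])
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(hull) < 3) { # collinear degenerate case
    ext <- sqrt(sum((apply(hull, 2, max) - apply(hull, 2, min))^2))
    long <- max(ext, min(sp))
    return(c(longDiamMm = long, shortDiamMm = min(sp),
             diamRatio = min(sp) / long))
  }
  nh <- nrow(hull)
  if (method == "caliper") {
    long <- max(stats::dist(hull))
    short <- Inf
    for (i in seq_len(nh)) { # min width is perpendicular to a hull edge
      e <- hull[if (i == nh) 1 else i + 1, ] - hull[i, ]
      len <- sqrt(sum(e^2))
      if (len < 1e-12) next
      d <- e / len
      pr <- hull %*% c(-d[2], d[1])
      short <- min(short, max(pr) - min(pr))
    }
    short <- min(short, long)
    return(c(longDiamMm = long, shortDiamMm = short,
             diamRatio = short / long))
  }
  # rectangle oriented to the minimum caliper width (achieved flush with
  # a hull edge); its two edge lengths are the reported axes
  best <- c(Inf, NA)
  for (i in seq_len(nh)) {
    e <- hull[if (i == nh) 1 else i + 1, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    d <- e / len
    pr1 <- hull %*% d
    pr2 <- hull %*% c(-d[2], d[1])
    w <- max(pr1) - min(pr1)   # extent along the edge
    h <- max(pr2) - min(pr2)   # width perpendicular to the edge
    if (h < best[1]) best <- c(h, w)
  }
  long <- max(best)
  short <- min(best)
  c(longDiamMm = long, shortDiamMm = short, diamRatio = short / long)
}

# foreground pixels with at least one 4-neighbor outside the mask
.boundaryPixels <- function(mask, fg) {
  nr <- nrow(mask); nc <- ncol(mask)
  inm <- mask > 0.5
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- inm
  core <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  b <- which(inm & !core, arr.ind = TRUE)
  if (nrow(b) == 0) fg else b
}

#' Mean ADC over a node mask
#'
#' Arithmetic mean of the ADC patch over foreground pixels, in
#' 10^-3 mm^2/s.
#'
#' @param mask binary matrix.
#' @param adcPatch ADC matrix on the same grid.
#' @return scalar mean ADC.
#' @export
meanADC <- function(mask, adcPatch) {
  if (!all(dim(mask) == dim(adcPatch)))
    stop("mask and ADC patch must share a grid")
  sel <- mask > 0.5
  if (!any(sel)) stop("empty mask: no foreground pixels to average")
  mean(adcPatch[sel])
}

#' Extract a model-ready patch around a node
#'
#' Crops a square window centered on the mask's bounding-box center with
#' side `marginFactor` times the longer bounding-box side (so perinodal
#' tissue stays visible), pads by edge replication where the window leaves
#' the image, and resamples to `outPx` x `outPx` (bilinear for the image,
#' nearest-neighbor for the mask). When the crop side already equals
#' `outPx`, the raw crop is returned unresampled.
#'
#' @param image 2-D intensity matrix.
#' @param mask binary matrix on the same grid.
#' @param marginFactor window side as a multiple of the bounding-box long
#'   side.
#' @param outPx output side length in pixels.
#' @return list with `patch`, `croppedMask`, the pre-resampling crop side
#'   `cropPx`, and `scale` (= cropPx / outPx, the factor by which pixel
#'   spacing grows under the resampling).
#' @export
extractPatch <- function(image, mask, marginFactor = 2, outPx = 32L) {
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must share a grid")
  fg <- which(mask > 0.5, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty mask: nothing to extract")
  r0 <- min(fg[, 1]); r1 <- max(fg[, 1])
  c0 <- min(fg[, 2]); c1 <- max(fg[, 2])
  side <- max(1L, as.integer(ceiling(marginFactor * max(r1 - r0 + 1,
                                                        c1 - c0 + 1))))
  rc <- round((r0 + r1) / 2)
  cc <- round((c0 + c1) / 2)
  rs <- seq.int(rc - floor((side - 1) / 2), length.out = side)
  cs <- seq.int(cc - floor((side - 1) / 2), length.out = side)
  if (min(rs) < 1 || max(rs) > nrow(image) ||
      min(cs) < 1 || max(cs) > ncol(image))
    warning("crop window exceeds image bounds; edge padding applied")
  rs <- pmin(pmax(rs, 1L), nrow(image))
  cs <- pmin(pmax(cs, 1L), ncol(image))
  crop <- image[rs, cs, drop = FALSE]
  mcrop <- mask[rs, cs, drop = FALSE]
  if (side != outPx) {
    crop <- .resample(crop, outPx, bilinear = TRUE)
    mcrop <- .resample(mcrop, outPx, bilinear = FALSE)
  }
  mcrop <- matrix(as.numeric(mcrop > 0.5), outPx, outPx)
  list(patch = crop, croppedMask = mcrop, cropPx = side,
       scale = side / outPx)
}

.resample <- function(m, outPx, bilinear = TRUE) {
  out <- EBImage::resize(m, w = outPx, h = outPx,
                         filter = if (bilinear) "bilinear" else "none")
  matrix(as.numeric(out), outPx, outPx)
}

#' Robust intensity normalization
#'
#' Robust z-score of an intensity image: subtract the median, divide by
#' the interquartile range rescaled to a normal-consistent sigma
#' (IQR / 1.349), clip to \code{[-5, 5]}. Invariant to affine intensity
#' transforms with positive gain; a constant image maps to all zeros
#' (scale floor).
#'
#' @param image numeric matrix with finite values.
#' @return normalized matrix.
#' @export
normalizeIntensity <- function(image) {
  if (!all(is.finite(image))) stop("image must be finite")
  med <- stats::median(image)
  sc <- stats::IQR(image) / 1.349
  if (sc < 1e-8) return(matrix(0, nrow(image), ncol(image)))
  z <- (image - med) / sc
  z[z > 5] <- 5
  z[z < -5] <- -5
  z
}

#' Per-node feature table of a cohort
#'
#' @param cohort an [LNCohort-class] object.
#' @return data.frame with one row per visible node: patient and node ids,
#'   diameters, ratio, mean ADC, latent truth (if synthetic) and, when the
#'   nodes have been scored, the predicted probability.
#' @export
nodeFeatureTable <- function(cohort) {
  rows <- lapply(bags(cohort), function(b) {
    data.frame(
      patient_id = b@patientId,
      node_id = vapply(b@nodes, function(n) n@nodeId, character(1)),
      long_diam_mm = vapply(b@nodes, function(n) n@longDiamMm, numeric(1)),
      short_diam_mm = vapply(b@nodes, function(n) n@shortDiamMm, numeric(1)),
      diam_ratio = vapply(b@nodes, function(n) n@diamRatio, numeric(1)),
      mean_adc = vapply(b@nodes, function(n) n@meanAdc, numeric(1)),
      latent_met = vapply(b@nodes, function(n) n@latentMet, logical(1)),
      prob = vapply(b@nodes, function(n) n@prob, numeric(1)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
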