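# Weight initialization for the residual convolutional instance scorer.
# Architecture (patch side P, divisible by 4):
#   conv3x3 1->C0 + ReLU; avgpool2; residual block at C0;
#   conv3x3 C0->C1 + ReLU; avgpool2; residual block at C1;
#   global average pooling; linear C1->1 logit.
# The second conv of each residual block starts at zero so every block is
# initially the identity. The first two stem filters are seeded with a
# center-surround (blob) kernel and an identity kernel -- focal
# high-contrast structure and raw intensity are the image primitives the
# task rests on, and seeding them makes the weakly supervised optimization
# escape its constant-probability plateau much more reliably; the remaining
# filters are random (He). Draws come from R's current RNG stream.
.initNet <- function(C0 = 6L, C1 = 12L) {
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
  zeros <- function(nr, nc = 1L) matrix(0, nr, nc)
  W0 <- he(C0, 9L)
  W0[1, ] <- 0.25 * c(-1, -1, -1, -1, 8, -1, -1, -1, -1) / sqrt(8)
  if (C0 >= 2) W0[2, ] <- 0.5 * c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  list(
    W0 = W0, b0 = zeros(C0),
    WA1 = he(C0, C0 * 9L), bA1 = zeros(C0),
    WA2 = zeros(C0, C0 * 9L), bA2 = zeros(C0),
    W1 = he(C1, C0 * 9L), b1 = zeros(C1),
    WB1 = he(C1, C1 * 9L), bB1 = zeros(C1),
    WB2 = zeros(C1, C1 * 9L), bB2 = zeros(C1),
    wd = matrix(stats::rnorm(C1, 0, sqrt(1 / C1)), C1, 1), bd = zeros(1L)
  )
}

.zerosLike <- function(w) lapply(w, function(m) matrix(0, nrow(m), ncol(m)))

.sigmoid <- function(z) 1 / (1 + exp(-z))

# per-node metastatic probabilities of the intensity network
# X: nodes x pixels matrix of normalized patches
.netProbs <- function(net, X, px) {
  .sigmoid(as.numeric(.net_logits_cpp(net, X, px, px)))
}

# stack the (robustly normalized) patches of a list of bags; returns the
# matrix plus 0-based bag offsets used by the C++ training loop
.stackPatches <- function(bagList) {
  px <- nrow(bagList[[1]]@nodes[[1]]@patch)
  plist <- lapply(bagList, function(b)
    t(vapply(b@nodes, function(n) as.numeric(normalizeIntensity(n@patch)),
             numeric(px * px))))
  lens <- vapply(plist, nrow, integer(1))
  X <- do.call(rbind, plist)
  list(X = X, start = cumsum(c(0L, lens[-length(lens)])), len = lens,
       px = px)
}
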