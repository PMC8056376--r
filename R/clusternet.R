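# Per-image unsupervised segmentation by differentiable feature clustering.
#
# A small CNN (two 3x3 convolution layers with rectifier + per-channel
# normalization, a 1x1 convolution to q response channels, and batch
# normalization) is optimized on the single target image. Each iteration:
# forward pass -> per-pixel argmax pseudo-labels -> feature-similarity loss
# (cross-entropy of the softmax responses against the pseudo-labels) plus a
# spatial-continuity loss (L1 differences between neighboring response
# vectors) -> backpropagation -> SGD update. The final argmax yields the
# label map.

# Layer spec of the clustering CNN for a given config.
clusterNetSpec <- function(config, inChannels = 1L) {
  layers <- list()
  cin <- inChannels
  for (i in seq_len(config@nConvLayers)) {
    layers <- c(layers, list(
      convSpec(sprintf("trunk%d.conv", i), config@kernelSize, cin, config@p,
               bias = TRUE, padMode = "replicate"),
      actSpec(sprintf("trunk%d.relu", i), "relu"),
      bnSpec(sprintf("trunk%d.bn", i), config@p)))
    cin <- config@p
  }
  layers <- c(layers, list(
    convSpec("resp.conv", 1L, config@p, config@q, bias = TRUE),
    bnSpec("resp.bn", config@q)))
  seqSpec("clusternet", layers)
}

#' Build a freshly initialized clustering network
#'
#' Parameters are seeded fan-in-scaled random draws; a new network is built
#' for every target image (per-image optimization).
#'
#' @param config a \code{\link{clusterNetConfig}}.
#' @param seed integer RNG seed for the initialization.
#' @return an opaque network object accepted by \code{\link{forwardResponses}}.
#' @export
buildClusterNet <- function(config, seed = 1L) {
  newNetwork(clusterNetSpec(config), seed = seed)
}

#' Per-pixel response map of the clustering network
#'
#' Runs the forward pass (batch normalization uses the image's own spatial
#' statistics; only one sample exists in per-image training) and returns the
#' q-channel batch-normalized responses.
#'
#' @param image 2-D numeric matrix (grayscale raster).
#' @param net network from \code{\link{buildClusterNet}}.
#' @return numeric H x W x q array of responses.
#' @export
forwardResponses <- function(image, net) {
  stopIfNot2dImage(image)
  x <- array(image, dim = c(dim(image), 1L, 1L))
  y <- netForward(net, x, training = TRUE)$out
  array(y, dim = dim(y)[1:3])
}

#' Argmax label assignment
#'
#' Each pixel receives the index (0-based) of the maximal component of its
#' response vector; ties break to the lowest channel index.
#'
#' @param responses H x W x q numeric array.
#' @return a \code{\link{LabelMap}}.
#' @export
assignLabels <- function(responses) {
  d <- dim(responses)
  if (length(d) != 3) stop("responses must be an H x W x q array")
  if (any(!is.finite(responses))) stop("responses must be finite")
  m <- matrix(responses, d[1] * d[2], d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  LabelMap(matrix(lab, d[1], d[2]), d[3])
}

# Per-pixel softmax of an H x W x q response array.
softmaxResponses <- function(responses) {
  d <- dim(responses)
  m <- matrix(responses, d[1] * d[2], d[3])
  m <- exp(m - m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))])
  array(m / .rowSums(m, nrow(m), ncol(m)), d)
}

#' Feature-similarity loss
#'
#' Sum over pixels of the negative log-probability assigned to each pixel's
#' own cluster label: \code{sum_n sum_i -delta(i - c_n) ln(y_{n,i})}, where
#' the responses are first converted to per-pixel probability distributions
#' by softmax (batch-normalized responses can be non-positive, so the
#' logarithm is taken on the softmax, which leaves the argmax labels
#' unchanged). An additive epsilon guards \code{ln(0)}.
#'
#' @param responses H x W x q numeric array.
#' @param labels a \code{\link{LabelMap}} (typically the argmax of
#'   \code{responses}).
#' @param probabilities set TRUE if \code{responses} already are per-pixel
#'   probabilities (skips the softmax).
#' @param eps additive guard inside the logarithm.
#' @return non-negative scalar.
#' @export
similarityLoss <- function(responses, labels, probabilities = FALSE, eps = 1e-12) {
  d <- dim(responses)
  stopifnot(is(labels, "LabelMap"), all(dim(labels@labels) == d[1:2]))
  p <- if (probabilities) responses else softmaxResponses(responses)
  pm <- matrix(p, d[1] * d[2], d[3])
  sel <- pm[cbind(seq_len(nrow(pm)), as.vector(labels@labels) + 1L)]
  -sum(log(sel + eps))
}

#' Spatial-continuity loss
#'
#' L1 norm of horizontal and vertical differences of neighboring response
#' vectors, summed over the printed index ranges (both sums run to W-1 and
#' H-1, so differences along the last row and column are excluded).
#'
#' @param responses H x W x q numeric array with H, W >= 2.
#' @return non-negative scalar; zero iff all response vectors inside the
#'   summation footprint equal their right and down neighbors.
#' @export
continuityLoss <- function(responses) {
  d <- dim(responses)
  if (length(d) != 3) stop("responses must be an H x W x q array")
  H <- d[1]; W <- d[2]
  if (H < 2 || W < 2) stop("continuity loss needs H >= 2 and W >= 2")
  horiz <- responses[1:(H - 1), 2:W, , drop = FALSE] -
    responses[1:(H - 1), 1:(W - 1), , drop = FALSE]
  vert <- responses[2:H, 1:(W - 1), , drop = FALSE] -
    responses[1:(H - 1), 1:(W - 1), , drop = FALSE]
  sum(abs(horiz)) + sum(abs(vert))
}

#' Combined clustering loss
#'
#' \code{lambda * similarityLoss + mu * continuityLoss}.
#'
#' @param responses H x W x q numeric array.
#' @param labels a \code{\link{LabelMap}}.
#' @param lambda,mu non-negative loss weights (defaults 4 and 1).
#' @param probabilities passed to \code{\link{similarityLoss}}.
#' @return non-negative scalar.
#' @export
totalLoss <- function(responses, labels, lambda = 4, mu = 1,
                      probabilities = FALSE) {
  if (lambda < 0 || mu < 0) stop("loss weights must be non-negative")
  lambda * similarityLoss(responses, labels, probabilities = probabilities) +
    mu * continuityLoss(responses)
}

# Loss value and gradient w.r.t. the responses, for given (fixed) labels.
# Cross-entropy is evaluated via log-sum-exp for stability; the continuity
# gradient is the subgradient sign(d), zero at exact ties. `a` and `b` scale
# the similarity and continuity terms respectively.
clusterLossGrad <- function(responses, labels, a, b) {
  d <- dim(responses)
  H <- d[1]; W <- d[2]; q <- d[3]
  m <- matrix(responses, H * W, q)
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  ex <- exp(m - mx)
  Z <- .rowSums(ex, nrow(ex), q)
  p <- ex / Z
  sel <- cbind(seq_len(nrow(m)), as.vector(labels@labels) + 1L)
  lsim <- -sum(m[sel] - mx - log(Z))
  gm <- p
  gm[sel] <- gm[sel] - 1
  grad <- array(a * gm, d)

  horiz <- responses[1:(H - 1), 2:W, , drop = FALSE] -
    responses[1:(H - 1), 1:(W - 1), , drop = FALSE]
  vert <- responses[2:H, 1:(W - 1), , drop = FALSE] -
    responses[1:(H - 1), 1:(W - 1), , drop = FALSE]
  lcon <- sum(abs(horiz)) + sum(abs(vert))
  sh <- b * sign(horiz)
  sv <- b * sign(vert)
  grad[1:(H - 1), 2:W, ] <- grad[1:(H - 1), 2:W, , drop = FALSE] + sh
  grad[1:(H - 1), 1:(W - 1), ] <- grad[1:(H - 1), 1:(W - 1), , drop = FALSE] - sh
  grad[2:H, 1:(W - 1), ] <- grad[2:H, 1:(W - 1), , drop = FALSE] + sv
  grad[1:(H - 1), 1:(W - 1), ] <- grad[1:(H - 1), 1:(W - 1), , drop = FALSE] - sv

  list(loss = a * lsim + b * lcon, lsim = lsim, lcon = lcon, grad = grad)
}

# Nearest-neighbor upscale of an integer label matrix to (H, W).
resizeLabelsNearest <- function(labels, H, W) {
  r <- pmin(nrow(labels), pmax(1L, round((seq_len(H) - 0.5) * nrow(labels) / H + 0.5)))
  c <- pmin(ncol(labels), pmax(1L, round((seq_len(W) - 0.5) * ncol(labels) / W + 0.5)))
  labels[r, c, drop = FALSE]
}

#' Unsupervised per-image segmentation
#'
#' Optimizes a freshly initialized clustering network on the target image
#' for exactly \code{nIterations} iterations of forward pass, argmax label
#' assignment, loss evaluation, backpropagation, and SGD update (momentum
#' 0.9, learning rate 0.1 by default), then returns the final label map.
#' For optimization the two loss terms are rescaled to per-pixel /
#' per-element means so the stated learning rate is well conditioned at any
#' resolution; the gradient direction is unchanged and \code{lambdaSim} /
#' \code{muCon} keep their roles. Images larger than the working size are
#' downscaled for clustering and the label map is upscaled back by nearest
#' neighbor. Reproducible for a fixed seed.
#'
#' @param image 2-D numeric matrix; intensities are rescaled to [0, 1].
#' @param config a \code{\link{clusterNetConfig}}.
#' @param seed RNG seed for the network initialization.
#' @return a \code{\link{LabelMap}} matching the input's spatial dimensions.
#' @export
segmentImage <- function(image, config = clusterNetConfig(), seed = 1L) {
  stopIfNot2dImage(image)
  H0 <- nrow(image); W0 <- ncol(image)
  rng <- range(image)
  if (rng[2] > rng[1]) image <- (image - rng[1]) / (rng[2] - rng[1])

  if (max(H0, W0) > config@workingSize) {
    f <- config@workingSize / max(H0, W0)
    img <- EBImage::resize(EBImage::Image(t(image)),
                           w = max(2L, round(W0 * f)), h = max(2L, round(H0 * f)))
    image <- t(as.array(img))
  }
  H <- nrow(image); W <- ncol(image)
  if (H < 2 || W < 2) stop("image too small to segment")

  x <- array(image, dim = c(H, W, 1L, 1L))
  net <- buildClusterNet(config, seed = seed)
  velocity <- list()
  # per-pixel mean for the similarity term; per-element mean for each of the
  # two continuity direction terms (the usual convention for this loss family)
  a <- config@lambdaSim / (H * W)
  b <- config@muCon / ((H - 1) * (W - 1) * config@q)

  for (it in seq_len(config@nIterations)) {
    fw <- netForward(net, x, training = TRUE)
    resp <- array(fw$out, dim = c(H, W, config@q))
    labels <- assignLabels(resp)
    lg <- clusterLossGrad(resp, labels, a, b)
    if (!is.finite(lg$loss))
      stop(sprintf("non-finite clustering loss at iteration %d", it))
    bw <- netBackward(net, fw$ctx, array(lg$grad, dim = c(H, W, config@q, 1L)))
    step <- sgdStep(net$params, bw$grads, velocity, config@lr, config@momentum)
    net$params <- step$params
    velocity <- step$velocity
    net$state <- as.list(fw$ctx$state)
  }

  fw <- netForward(net, x, training = TRUE)
  labels <- assignLabels(array(fw$out, dim = c(H, W, config@q)))
  lab <- labels@labels
  if (H != H0 || W != W0) lab <- resizeLabelsNearest(lab, H0, W0)
  LabelMap(lab, config@q)
}
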