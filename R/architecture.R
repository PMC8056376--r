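# Gender-embedded bone-age regression network.
#
# Backbone: MobileNetV3-Large-style stack (inverted-residual bottlenecks
# with depthwise separable convolutions, squeeze-and-excitation gates and
# h-swish), adaptive average pooling, and a 1x1 projection (no batch norm)
# to a 1280-dim image feature. The binary gender flag passes through a
# rectified linear embedding of width 24 and is concatenated to a 1304-dim
# fused feature; a one-hidden-layer MLP (1304 neurons, ReLU) outputs one
# standardized-age scalar.

#' Hard swish activation
#'
#' \code{hSwish(x) = x * ReLU6(x + 3) / 6}, the piecewise-linear
#' approximation of swish used throughout the backbone.
#'
#' @param x numeric vector/array.
#' @return elementwise h-swish.
#' @export
hSwish <- function(x) x * pmin.int(pmax.int(x + 3, 0), 6) / 6

# Round channel counts to multiples of 8 (never below 90% of the request),
# the convention used for squeeze-and-excitation bottleneck widths.
makeDivisible <- function(v, divisor = 8L) {
  new_v <- max(divisor, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

#' Backbone block table
#'
#' The bottleneck stack of the backbone: per row the input channels, kernel
#' size, expansion width, output channels, squeeze-and-excitation flag,
#' nonlinearity (\code{RE}/\code{HS}) and stride. Expansion widths and the
#' squeeze-and-excitation bottleneck rule follow the published
#' MobileNetV3-Large design.
#'
#' @return data.frame with one row per bottleneck block.
#' @export
mobileNetV3Spec <- function() {
  data.frame(
    cin    = c(16L, 16L, 24L, 24L, 40L, 40L, 40L, 80L, 80L, 80L, 80L, 112L, 112L, 160L, 160L),
    kernel = c(3L, 3L, 3L, 5L, 5L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 5L, 5L, 5L),
    exp    = c(16L, 64L, 72L, 72L, 120L, 120L, 240L, 200L, 184L, 184L, 480L, 672L, 672L, 960L, 960L),
    out    = c(16L, 24L, 24L, 40L, 40L, 40L, 80L, 80L, 80L, 80L, 112L, 112L, 160L, 160L, 160L),
    se     = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    nl     = c("RE", "RE", "RE", "RE", "RE", "RE", "HS", "HS", "HS", "HS", "HS", "HS", "HS", "HS", "HS"),
    stride = c(1L, 2L, 1L, 2L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L))
}

# One inverted-residual bottleneck as a layer-spec tree: 1x1 expansion
# (skipped when exp == cin) -> depthwise -> optional SE -> 1x1 projection;
# residual connection iff stride 1 and cin == cout.
bottleneckSpec <- function(name, cin, exp, cout, kernel, stride, useSe, nl) {
  act <- if (nl == "HS") "hswish" else "relu"
  children <- list()
  if (exp != cin) {
    children <- c(children, list(
      convSpec(paste0(name, ".expand"), 1L, cin, exp),
      bnSpec(paste0(name, ".expand.bn"), exp),
      actSpec(paste0(name, ".expand.act"), act)))
  }
  children <- c(children, list(
    dwconvSpec(paste0(name, ".dw"), kernel, exp, stride),
    bnSpec(paste0(name, ".dw.bn"), exp),
    actSpec(paste0(name, ".dw.act"), act)))
  if (useSe)
    children <- c(children, list(seSpec(paste0(name, ".se"), exp, makeDivisible(exp %/% 4L))))
  children <- c(children, list(
    convSpec(paste0(name, ".project"), 1L, exp, cout),
    bnSpec(paste0(name, ".project.bn"), cout)))
  if (stride == 1L && cin == cout) resSpec(name, children) else seqSpec(name, children)
}

# Full backbone spec: 3x3 stride-2 stem (16 ch, h-swish), the bottleneck
# table, and the final 1x1 convolution to 960 channels.
backboneSpec <- function(table = mobileNetV3Spec()) {
  prev <- 16L
  blocks <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    if (row$cin != prev)
      stop(sprintf("backbone table row %d: input channels %d do not chain (previous out %d)",
                   i, row$cin, prev))
    if (!row$stride %in% c(1L, 2L) || !row$kernel %in% c(1L, 3L, 5L))
      stop(sprintf("backbone table row %d: invalid stride/kernel", i))
    blocks[[i]] <- bottleneckSpec(sprintf("bneck%02d", i), row$cin, row$exp,
                                  row$out, row$kernel, row$stride, row$se, row$nl)
    prev <- row$out
  }
  seqSpec("backbone", c(
    list(convSpec("stem", 3L, 3L, 16L, stride = 2L),
         bnSpec("stem.bn", 16L),
         actSpec("stem.act", "hswish")),
    blocks,
    list(convSpec("last", 1L, prev, 960L),
         bnSpec("last.bn", 960L),
         actSpec("last.act", "hswish"))))
}

#' Assemble the bone-age regression model
#'
#' @param inputSize square input side in pixels (224, 500 or 700 in the
#'   reference protocol; any size >= 32 works, adaptive pooling keeps the
#'   feature width at 1280).
#' @param useGender include the 24-dim gender-embedding branch (fused
#'   feature 1304) or not (image feature 1280 only).
#' @param seed RNG seed for initialization.
#' @param table backbone block table, defaults to \code{\link{mobileNetV3Spec}}.
#' @return a \code{\link{BoneAgeModel}}.
#' @export
buildBoneAgeModel <- function(inputSize = 224L, useGender = TRUE, seed = 1L,
                              table = mobileNetV3Spec()) {
  spec <- backboneSpec(table)
  withSeed(seed, {
    net <- newNetwork(spec)
    he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
    fusedWidth <- 1280L + if (useGender) 24L else 0L
    head <- list(
      fc.w = he(1280L, 960L), fc.b = numeric(1280L),
      mlp1.w = he(1304L, fusedWidth), mlp1.b = numeric(1304L),
      mlp2.w = he(1L, 1304L), mlp2.b = numeric(1L))
    if (useGender) {
      head$gender.w <- matrix(stats::rnorm(24L, sd = 1), 24L, 1L)
      head$gender.b <- stats::rnorm(24L, sd = 0.5)
    }
    new("BoneAgeModel", arch = table, net = net, head = head,
        inputSize = as.integer(inputSize), useGender = useGender,
        standardizer = NULL)
  })
}

#' Gender embedding
#'
#' Rectified affine map of the binary gender flag (male = 1, female = 0) to
#' a 24-vector: \code{ReLU(w * g + b)}.
#'
#' @param g numeric vector of 0/1 gender flags.
#' @param w,b embedding weights (24 x 1 matrix) and bias (length 24); taken
#'   from \code{model} when supplied.
#' @param model optionally a \code{\link{BoneAgeModel}} with a gender branch.
#' @return 24 x length(g) matrix with non-negative entries.
#' @export
embedGender <- function(g, w = NULL, b = NULL, model = NULL) {
  if (!is.null(model)) {
    if (!model@useGender) stop("model has no gender branch")
    w <- model@head$gender.w
    b <- model@head$gender.b
  }
  if (!all(g %in% c(0, 1))) stop("gender flags must be 0 (female) or 1 (male)")
  u <- w %*% matrix(as.numeric(g), nrow = 1) + b
  u * (u > 0)
}

# Forward pass of the full model. images: (H, W, 3, N) array; gender:
# numeric 0/1 of length N. Returns prediction vector plus caches when
# training.
modelForward <- function(model, images, gender = NULL, training = FALSE) {
  fw <- netForward(model@net, images, training = training)
  d <- dim(fw$out)
  hw <- d[1] * d[2]
  pooled <- matrix(.colSums(fw$out, hw, d[3] * d[4]), d[3], d[4]) / hw # 960 x N
  u1 <- model@head$fc.w %*% pooled + model@head$fc.b
  feat <- hSwish(u1) # 1280 x N
  if (model@useGender) {
    if (is.null(gender)) stop("model expects a gender flag per image")
    gemb <- embedGender(gender, model@head$gender.w, model@head$gender.b)
    fused <- rbind(feat, gemb) # 1304 x N
  } else {
    fused <- feat
  }
  u2 <- model@head$mlp1.w %*% fused + model@head$mlp1.b
  hidden <- u2 * (u2 > 0)
  yhat <- as.vector(model@head$mlp2.w %*% hidden + model@head$mlp2.b)
  list(yhat = yhat, ctx = fw$ctx, outDim = d,
       cache = if (training) list(pooled = pooled, u1 = u1, feat = feat,
                                  fused = fused, u2 = u2, hidden = hidden,
                                  gender = gender))
}

# Backward pass from d(loss)/d(yhat); returns gradients for head and
# backbone parameters.
modelBackward <- function(model, fwd, gy) {
  cc <- fwd$cache
  N <- length(gy)
  grads <- list()
  ghid <- crossprod(model@head$mlp2.w, matrix(gy, 1)) * (cc$u2 > 0) # 1304 x N
  grads$mlp2.w <- matrix(gy, 1) %*% t(cc$hidden)
  grads$mlp2.b <- sum(gy)
  grads$mlp1.w <- ghid %*% t(cc$fused)
  grads$mlp1.b <- .rowSums(ghid, nrow(ghid), N)
  gfused <- crossprod(model@head$mlp1.w, ghid)
  if (model@useGender) {
    gfeat <- gfused[1:1280, , drop = FALSE]
    gemb <- gfused[1281:1304, , drop = FALSE]
    act <- model@head$gender.w %*% matrix(as.numeric(cc$gender), 1) + model@head$gender.b
    gu <- gemb * (act > 0)
    grads$gender.w <- gu %*% matrix(as.numeric(cc$gender), ncol = 1)
    grads$gender.b <- .rowSums(gu, 24, N)
  } else {
    gfeat <- gfused
  }
  gu1 <- gfeat * hswishGrad(cc$u1)
  grads$fc.w <- gu1 %*% t(cc$pooled)
  grads$fc.b <- .rowSums(gu1, nrow(gu1), N)
  gpooled <- crossprod(model@head$fc.w, gu1) # 960 x N
  d <- fwd$outDim
  hw <- d[1] * d[2]
  gout <- array(bcChan(as.vector(gpooled) / hw, hw), dim = d)
  bw <- netBackward(model@net, fwd$ctx, gout)
  list(head = grads, net = bw$grads)
}

#' Predict standardized or month-scale bone age
#'
#' Runs the model in inference mode. When the model carries an
#' \code{\link{AgeStandardizer}} (after training) predictions are returned
#' in months unless \code{standardized = TRUE}.
#'
#' @param model a \code{\link{BoneAgeModel}}.
#' @param images one H x W matrix, or an (H, W, 3, N) array; grayscale
#'   inputs are replicated to 3 channels.
#' @param male logical (or 0/1) vector of gender flags.
#' @param standardized return the raw network output instead of months.
#' @return numeric vector of predictions, one per image.
#' @export
predictAge <- function(model, images, male = NULL, standardized = FALSE) {
  x <- asModelInput(images, model@inputSize)
  n <- dim(x)[4]
  g <- if (!is.null(male)) as.numeric(male) else NULL
  if (model@useGender) {
    if (is.null(g)) stop("model expects a gender flag per image")
    if (length(g) == 1) g <- rep(g, n)
    if (length(g) != n) stop("gender flags must match the number of images")
  }
  yhat <- modelForward(model, x, g, training = FALSE)$yhat
  if (standardized || is.null(model@standardizer)) yhat
  else destandardizeAge(yhat, model@standardizer)
}

# Coerce user input (matrix, list of matrices, 3-D or 4-D array) into the
# (H, W, 3, N) tensor the backbone expects, resizing to `size` if needed.
asModelInput <- function(images, size) {
  if (is.list(images)) {
    arr <- array(0, dim = c(size, size, 3L, length(images)))
    for (i in seq_along(images)) {
      m <- images[[i]]
      if (nrow(m) != size || ncol(m) != size) m <- resizeBilinear(m, size, size)
      arr[, , , i] <- array(rep(m, 3), dim = c(size, size, 3L))
    }
    return(arr)
  }
  if (is.matrix(images)) return(asModelInput(list(images), size))
  d <- dim(images)
  if (length(d) == 4) return(images)
  if (length(d) == 3 && d[3] == 3) return(array(images, dim = c(d, 1L)))
  stop("unsupported image input; give a matrix, list of matrices, or (H,W,3,N) array")
}

#' Count learnable parameters
#'
#' Total number of learnable scalars of the assembled model (backbone
#' convolutions and batch-norm affine terms, squeeze-and-excitation
#' bottlenecks, the 1280-dim projection, the gender embedding and the MLP
#' head). Batch-norm running statistics are not learnable and are excluded.
#'
#' @param model a \code{\link{BoneAgeModel}} (or a raw network list).
#' @return integer count.
#' @export
countParameters <- function(model) {
  if (is(model, "BoneAgeModel"))
    sum(vapply(model@net$params, length, 1L)) +
      sum(vapply(model@head, length, 1L))
  else
    sum(vapply(model$params, length, 1L))
}

#' Per-block output shapes of the backbone
#'
#' Forwards an input through the backbone one top-level block at a time and
#' records each block's output dimensions (H, W, C) — the shape chain of the
#' block table.
#'
#' @param model a \code{\link{BoneAgeModel}}.
#' @param inputSize input side length (defaults to the model's).
#' @return data.frame with columns \code{block}, \code{outH}, \code{outW},
#'   \code{outC}.
#' @export
backboneShapes <- function(model, inputSize = model@inputSize) {
  x <- array(0, dim = c(inputSize, inputSize, 3L, 1L))
  ctx <- new.env(parent = emptyenv())
  ctx$params <- model@net$params
  ctx$state <- model@net$state
  ctx$training <- FALSE
  ctx$caches <- list()
  blocks <- model@net$spec$children
  out <- data.frame(block = character(0), outH = integer(0),
                    outW = integer(0), outC = integer(0))
  for (ch in blocks) {
    x <- layerForward(ch, x, ctx)
    d <- dim(x)
    out <- rbind(out, data.frame(block = ch$name, outH = d[1],
                                 outW = d[2], outC = d[3]))
  }
  out
}

## ---- standalone building-block operations --------------------------------

#' Depthwise separable convolution (single sample)
#'
#' A depthwise spatial convolution (one filter per input channel, channel
#' multiplier 1) followed by a 1x1 pointwise convolution mixing channels.
#' Parameter count without biases is \code{k^2 * Cin + Cin * Cout}.
#'
#' @param input H x W x Cin numeric array.
#' @param dw (k, k, Cin) depthwise filter array.
#' @param pw (Cin, Cout) pointwise mixing matrix.
#' @param bias optional length-Cout bias.
#' @param stride stride of the depthwise stage.
#' @return H' x W' x Cout array.
#' @export
depthwiseSeparable <- function(input, dw, pw, bias = NULL, stride = 1L) {
  d <- dim(input)
  if (dim(dw)[3] != d[3]) stop("depthwise filter count must match input channels")
  if (nrow(pw) != d[3]) stop("pointwise rows must match input channels")
  x <- array(input, dim = c(d, 1L))
  y <- cpp_dwconv2d_fw(x, dw, numeric(0), as.integer(stride),
                       as.integer((dim(dw)[1] - 1L) %/% 2L))
  dy <- dim(y)
  m <- matrix(y, dy[1] * dy[2], dy[3]) %*% pw
  if (!is.null(bias)) m <- sweep(m, 2, bias, "+")
  array(m, dim = c(dy[1], dy[2], ncol(pw)))
}

#' Squeeze-and-excitation gate (single sample)
#'
#' Global average pooling per channel, a two-layer fully connected
#' bottleneck (ReLU between, sigmoid-family gate after), and per-channel
#' rescaling of the input by the resulting weights in (0, 1).
#'
#' @param input H x W x C numeric array.
#' @param w1,b1 squeeze FC (squeeze x C matrix, length-squeeze bias).
#' @param w2,b2 excite FC (C x squeeze matrix, length-C bias).
#' @param gate \code{"sigmoid"} (the classic gate) or \code{"hsigmoid"}
#'   (the hard variant used inside the backbone).
#' @return gated array, same dims as input; elementwise
#'   \code{|out| <= |in|}.
#' @export
squeezeExcite <- function(input, w1, b1, w2, b2, gate = c("sigmoid", "hsigmoid")) {
  gate <- match.arg(gate)
  d <- dim(input)
  s <- .colSums(matrix(input, d[1] * d[2], d[3]), d[1] * d[2], d[3]) / (d[1] * d[2])
  z <- as.vector(w1 %*% s + b1)
  z <- z * (z > 0)
  u <- as.vector(w2 %*% z + b2)
  g <- if (gate == "sigmoid") 1 / (1 + exp(-u)) else pmin.int(pmax.int(u + 3, 0), 6) / 6
  input * bcChan(g, d[1] * d[2])
}

#' Inverted residual block (single sample)
#'
#' Builds a seeded bottleneck block (1x1 expansion, depthwise, optional
#' squeeze-and-excitation, 1x1 projection) and applies it in inference mode.
#' The residual addition is applied iff \code{stride == 1} and the channel
#' counts match.
#'
#' @param input H x W x Cin numeric array.
#' @param expansion expanded channel width.
#' @param outChannels output channels.
#' @param stride 1 or 2.
#' @param useSe include a squeeze-and-excitation gate.
#' @param nonlinearity \code{"RE"} or \code{"HS"}.
#' @param kernel depthwise kernel size.
#' @param seed RNG seed for the block parameters.
#' @param zeroWeights set all convolution weights to zero (the block then
#'   reduces to the skip path when one exists).
#' @return output array.
#' @export
invertedResidual <- function(input, expansion, outChannels, stride = 1L,
                             useSe = FALSE, nonlinearity = "RE", kernel = 3L,
                             seed = 1L, zeroWeights = FALSE) {
  d <- dim(input)
  spec <- bottleneckSpec("block", d[3], as.integer(expansion),
                         as.integer(outChannels), as.integer(kernel),
                         as.integer(stride), useSe, nonlinearity)
  net <- newNetwork(spec, seed = seed)
  if (zeroWeights)
    for (nm in names(net$params))
      if (grepl("\\.(w|w1|w2)$", nm) && !grepl("(gamma|beta)$", nm))
        net$params[[nm]] <- net$params[[nm]] * 0
  y <- netForward(net, array(input, dim = c(d, 1L)), training = FALSE)$out
  array(y, dim = dim(y)[1:3])
}
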