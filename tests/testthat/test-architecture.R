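# Architecture: activations, building blocks, backbone assembly, gender
# embedding, prediction head, parameter accounting.

test_that("h-swish matches its closed form and is continuous", {
  expect_identical(hSwish(0), 0)
  expect_identical(hSwish(3), 3)
  expect_identical(hSwish(-3), 0)
  expect_identical(hSwish(-5), 0)
  grid <- seq(-6, 6, by = 1e-3)
  v <- hSwish(grid)
  expect_lt(max(abs(diff(v))), 2e-3) # no jumps at the hinge points
  pos <- grid[grid >= 0]
  expect_true(all(hSwish(pos) >= 0 & hSwish(pos) <= pos + 1e-12))
  expect_true(all(hSwish(grid[grid <= 0]) <= 0))
})

test_that("depthwise separable convolution composes the two stages", {
  set.seed(41)
  x <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  # identity construction: unit-impulse depthwise + identity pointwise
  dw <- array(0, c(3, 3, 3)); dw[2, 2, ] <- 1
  pw <- diag(3)
  expect_equal(depthwiseSeparable(x, dw, pw), x, tolerance = 1e-12)
  # equals an explicit composition oracle on a toy input
  dw2 <- array(rnorm(27), c(3, 3, 3))
  pw2 <- matrix(rnorm(3 * 4), 3, 4)
  out <- depthwiseSeparable(x, dw2, pw2)
  xp <- array(0, c(7, 7, 3)); xp[2:6, 2:6, ] <- x
  stage1 <- array(0, c(5, 5, 3))
  for (c in 1:3) for (r in 1:5) for (cc in 1:5)
    stage1[r, cc, c] <- sum(dw2[, , c] * xp[r:(r + 2), cc:(cc + 2), c])
  oracle <- array(0, c(5, 5, 4))
  for (o in 1:4) oracle[, , o] <- stage1[, , 1] * pw2[1, o] +
    stage1[, , 2] * pw2[2, o] + stage1[, , 3] * pw2[3, o]
  expect_equal(out, oracle, tolerance = 1e-10)
  expect_error(depthwiseSeparable(x, array(0, c(3, 3, 2)), pw), "channels")
})

test_that("squeeze-and-excitation gates channels within (0, 1)", {
  set.seed(42)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  # bias trick: zero weights + large excite bias forces gate ~ 1
  w1 <- matrix(0, 2, 4); w2 <- matrix(0, 4, 2)
  expect_equal(squeezeExcite(x, w1, rep(0, 2), w2, rep(100, 4)), x,
               tolerance = 1e-10)
  # hard gate saturates exactly
  expect_identical(squeezeExcite(x, w1, rep(0, 2), w2, rep(10, 4),
                                 gate = "hsigmoid"), x)
  # constant-per-channel input: squeeze equals those constants, so a
  # pass-through excite (zero weights, zero bias) gates by sigmoid(0) = 1/2
  xc <- array(rep(c(1, 2, -1, 0.5), each = 36), c(6, 6, 4))
  expect_equal(squeezeExcite(xc, w1, rep(0, 2), w2, rep(0, 4)), xc / 2,
               tolerance = 1e-12)
  # boundedness with arbitrary weights
  w1r <- matrix(rnorm(8), 2, 4); w2r <- matrix(rnorm(8), 4, 2)
  out <- squeezeExcite(x, w1r, rnorm(2), w2r, rnorm(4))
  expect_true(all(abs(out) <= abs(x) + 1e-12))
})

test_that("inverted residual applies the skip rule and stride contract", {
  set.seed(43)
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  # zero weights + matching channels + stride 1 -> pure skip
  expect_equal(invertedResidual(x, expansion = 32L, outChannels = 16L,
                                stride = 1L, zeroWeights = TRUE), x,
               tolerance = 1e-9)
  # stride 2 halves spatial dims, no skip
  y <- invertedResidual(x, expansion = 32L, outChannels = 24L, stride = 2L)
  expect_equal(dim(y), c(4L, 4L, 24L))
  # the 28x28x40 -> 14x14x80 stride-2 block row
  x2 <- array(rnorm(28 * 28 * 40), c(28, 28, 40))
  y2 <- invertedResidual(x2, expansion = 240L, outChannels = 80L, stride = 2L,
                         nonlinearity = "HS")
  expect_equal(dim(y2), c(14L, 14L, 80L))
})

test_that("backbone table chains and bad tables are rejected by row", {
  tab <- mobileNetV3Spec()
  expect_equal(nrow(tab), 15L)
  expect_true(all(tab$cin[-1] == tab$out[-nrow(tab)]))
  bad <- tab; bad$cin[5] <- 99L
  expect_error(buildBoneAgeModel(table = bad), "row 5")
})

test_that("the model is finite end-to-end and fuses gender into 1304 features", {
  model <- buildBoneAgeModel(inputSize = 32L, seed = 7L)
  ns <- asNamespace("BoneAgeNet")
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3L, 2L))
  fw <- ns$modelForward(model, x, gender = c(0, 1), training = TRUE)
  expect_equal(nrow(fw$cache$fused), 1304L)
  expect_equal(length(fw$yhat), 2L)
  expect_true(all(is.finite(fw$yhat)))
  # gender rows of the fused feature are non-negative (post-rectifier)
  expect_true(all(fw$cache$fused[1281:1304, ] >= 0))
  # flipping gender changes the fused feature when the embeddings differ
  fw2 <- ns$modelForward(model, x, gender = c(1, 1), training = TRUE)
  expect_false(isTRUE(all.equal(fw$cache$fused[, 1], fw2$cache$fused[, 1])))
  # a batch of 10 images yields 10 scalars
  x10 <- array(runif(32 * 32 * 3 * 10), c(32, 32, 3L, 10L))
  expect_length(ns$modelForward(model, x10, gender = rep(0, 10))$yhat, 10L)
})

test_that("gender embedding is a rectified affine map to 24 dimensions", {
  w <- matrix(1, 24, 1)
  b <- rep(-0.5, 24)
  e1 <- embedGender(1, w, b)
  e0 <- embedGender(0, w, b)
  expect_equal(as.vector(e1), rep(0.5, 24))
  expect_equal(as.vector(e0), rep(0, 24))
  model <- buildBoneAgeModel(inputSize = 32L, seed = 1L)
  expect_equal(nrow(embedGender(c(0, 1), model = model)), 24L)
  # g = 0 uses only the bias
  expect_equal(embedGender(0, model = model)[, 1],
               pmax(model@head$gender.b, 0))
  expect_error(embedGender(0.5, w, b), "0 \\(female\\) or 1 \\(male\\)")
})

test_that("parameter counts follow the closed forms and ignore input size", {
  model <- buildBoneAgeModel(inputSize = 224L, seed = 1L)
  head <- model@head
  # one-hidden-layer MLP: 1304*1304 + 1304 (hidden) + 1304 + 1 (output)
  expect_identical(length(head$mlp1.w) + length(head$mlp1.b) +
                     length(head$mlp2.w) + length(head$mlp2.b), 1703025L)
  # gender embedding: 1*24 + 24
  expect_identical(length(head$gender.w) + length(head$gender.b), 48L)
  expect_identical(countParameters(model),
                   countParameters(buildBoneAgeModel(inputSize = 96L, seed = 2L)))
  noG <- buildBoneAgeModel(inputSize = 96L, useGender = FALSE, seed = 1L)
  expect_identical(countParameters(model) - countParameters(noG),
                   48L + 24L * 1304L)
})

test_that("model gradients match finite differences on a tiny input", {
  ns <- asNamespace("BoneAgeNet")
  model <- buildBoneAgeModel(inputSize = 16L, seed = 11L)
  set.seed(12)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3L, 2L))
  g <- c(0, 1)
  target <- c(0.3, -0.8)
  lossAt <- function(m) {
    yh <- ns$modelForward(m, x, g, training = TRUE)$yhat
    mean((yh - target)^2)
  }
  fw <- ns$modelForward(model, x, g, training = TRUE)
  gy <- 2 * (fw$yhat - target) / 2
  grads <- ns$modelBackward(model, fw, gy)
  # early backbone layers see gradients of order 1e3 through dozens of
  # batch-norm stages; central differences carry visible truncation error
  # there, so eps is small and the tolerance is percent-level
  check <- function(getp, setp, gmat, k = 6) {
    p <- getp(model)
    idx <- sample(seq_along(p), min(k, length(p)))
    for (i in idx) {
      eps <- 1e-6
      m2 <- setp(model, i, p[i] + eps); l1 <- lossAt(m2)
      m2 <- setp(model, i, p[i] - eps); l2 <- lossAt(m2)
      fd <- (l1 - l2) / (2 * eps)
      expect_lt(abs(fd - gmat[i]) / max(1e-3, abs(fd), abs(gmat[i])), 2e-2)
    }
  }
  check(function(m) m@head$mlp2.w,
        function(m, i, v) { m@head$mlp2.w[i] <- v; m }, grads$head$mlp2.w)
  check(function(m) m@head$gender.w,
        function(m, i, v) { m@head$gender.w[i] <- v; m }, grads$head$gender.w)
  check(function(m) m@net$params$stem.w,
        function(m, i, v) { m@net$params$stem.w[i] <- v; m },
        grads$net$stem.w)
  check(function(m) m@net$params$bneck04.se.w2,
        function(m, i, v) { m@net$params$bneck04.se.w2[i] <- v; m },
        grads$net$bneck04.se.w2)
})
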