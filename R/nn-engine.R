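# Minimal neural-network engine used by both the per-image clustering
# segmenter and the bone-age regression network.
#
# Activations are dense 4-D arrays with dim (H, W, C, N); convolutions run
# through compiled im2col + BLAS kernels (src/conv.cpp), everything
# pointwise stays vectorized R. Layers are described by plain spec lists
# assembled into a tree ("seq", "residual", leaf layers); parameters live in
# a flat named list so the optimizer and serialization stay trivial.

## ---- spec constructors -------------------------------------------------

convSpec <- function(name, k, cin, cout, stride = 1L, bias = FALSE,
                     padMode = c("zero", "replicate")) {
  padMode <- match.arg(padMode)
  list(kind = "conv", name = name, kh = as.integer(k), kw = as.integer(k),
       cin = as.integer(cin), cout = as.integer(cout),
       stride = as.integer(stride), pad = as.integer((k - 1L) %/% 2L),
       bias = bias, padMode = if (padMode == "zero") 0L else 1L)
}

dwconvSpec <- function(name, k, c, stride = 1L) {
  list(kind = "dwconv", name = name, kh = as.integer(k), kw = as.integer(k),
       c = as.integer(c), stride = as.integer(stride),
       pad = as.integer((k - 1L) %/% 2L))
}

bnSpec <- function(name, c) list(kind = "bn", name = name, c = as.integer(c))

actSpec <- function(name, fun = c("relu", "hswish")) {
  list(kind = "act", name = name, fun = match.arg(fun))
}

seSpec <- function(name, c, squeeze) {
  list(kind = "se", name = name, c = as.integer(c), squeeze = as.integer(squeeze))
}

seqSpec <- function(name, children) list(kind = "seq", name = name, children = children)

resSpec <- function(name, children) list(kind = "residual", name = name, children = children)

## ---- parameter initialization ------------------------------------------

# Kaiming (He) fan-in scaled normal initialization for all filter weights;
# batch-norm starts at the identity transform.
initSpecParams <- function(spec, params = list(), state = list()) {
  he <- function(dims, fan_in) array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
  switch(spec$kind,
    conv = {
      params[[paste0(spec$name, ".w")]] <-
        he(c(spec$kh, spec$kw, spec$cin, spec$cout), spec$kh * spec$kw * spec$cin)
      if (spec$bias) params[[paste0(spec$name, ".b")]] <- numeric(spec$cout)
    },
    dwconv = {
      params[[paste0(spec$name, ".w")]] <- he(c(spec$kh, spec$kw, spec$c), spec$kh * spec$kw)
    },
    bn = {
      params[[paste0(spec$name, ".gamma")]] <- rep(1, spec$c)
      params[[paste0(spec$name, ".beta")]] <- rep(0, spec$c)
      state[[paste0(spec$name, ".rmean")]] <- rep(0, spec$c)
      state[[paste0(spec$name, ".rvar")]] <- rep(1, spec$c)
    },
    se = {
      params[[paste0(spec$name, ".w1")]] <- matrix(
        stats::rnorm(spec$squeeze * spec$c, sd = sqrt(2 / spec$c)), spec$squeeze, spec$c)
      params[[paste0(spec$name, ".b1")]] <- numeric(spec$squeeze)
      params[[paste0(spec$name, ".w2")]] <- matrix(
        stats::rnorm(spec$c * spec$squeeze, sd = sqrt(2 / spec$squeeze)), spec$c, spec$squeeze)
      params[[paste0(spec$name, ".b2")]] <- numeric(spec$c)
    },
    seq = ,
    residual = {
      for (ch in spec$children) {
        r <- initSpecParams(ch, params, state)
        params <- r$params
        state <- r$state
      }
    },
    act = NULL,
    stop("unknown layer kind: ", spec$kind)
  )
  list(params = params, state = state)
}

## ---- pointwise helpers --------------------------------------------------

# Per-channel broadcast multiply/add on (H, W, C, N) arrays: `v` has length
# C (or C*N); exact recycling makes this allocation-light.
bcChan <- function(v, hw) rep.int(v, rep.int(hw, length(v)))

# Per-channel mean/sum over (H, W, N) for a (H, W, C, N) array.
chanSum <- function(x, d) {
  m <- matrix(.colSums(x, d[1] * d[2], d[3] * d[4]), d[3], d[4])
  .rowSums(m, d[3], d[4])
}

reluFw <- function(x) x * (x > 0)

hswishFw <- function(x) x * pmin.int(pmax.int(x + 3, 0), 6) / 6

hswishGrad <- function(x) {
  g <- pmin.int(pmax.int(x + 3, 0), 6) / 6 + x * ((x > -3) & (x < 3)) / 6
  g
}

hsigmoidFw <- function(x) pmin.int(pmax.int(x + 3, 0), 6) / 6

## ---- forward / backward -------------------------------------------------

# ctx: environment with $params, $state, $training, $caches, $grads.
layerForward <- function(spec, x, ctx) {
  nm <- spec$name
  switch(spec$kind,
    conv = {
      w <- ctx$params[[paste0(nm, ".w")]]
      b <- ctx$params[[paste0(nm, ".b")]]
      if (is.null(b)) b <- numeric(0)
      if (ctx$training) ctx$caches[[nm]] <- x
      cpp_conv2d_fw(x, w, b, spec$stride, spec$pad, spec$padMode)
    },
    dwconv = {
      w <- ctx$params[[paste0(nm, ".w")]]
      if (ctx$training) ctx$caches[[nm]] <- x
      cpp_dwconv2d_fw(x, w, numeric(0), spec$stride, spec$pad)
    },
    bn = batchnormForward(spec, x, ctx),
    act = {
      if (ctx$training) ctx$caches[[nm]] <- x
      if (spec$fun == "relu") reluFw(x) else hswishFw(x)
    },
    se = seForward(spec, x, ctx),
    seq = {
      for (ch in spec$children) x <- layerForward(ch, x, ctx)
      x
    },
    residual = {
      x0 <- x
      for (ch in spec$children) x <- layerForward(ch, x, ctx)
      x + x0
    }
  )
}

layerBackward <- function(spec, gy, ctx) {
  nm <- spec$name
  switch(spec$kind,
    conv = {
      x <- ctx$caches[[nm]]
      w <- ctx$params[[paste0(nm, ".w")]]
      r <- cpp_conv2d_bw(x, w, gy, spec$stride, spec$pad, spec$padMode, spec$bias)
      ctx$grads[[paste0(nm, ".w")]] <- r$gw
      if (spec$bias) ctx$grads[[paste0(nm, ".b")]] <- r$gb
      r$gx
    },
    dwconv = {
      x <- ctx$caches[[nm]]
      w <- ctx$params[[paste0(nm, ".w")]]
      r <- cpp_dwconv2d_bw(x, w, gy, spec$stride, spec$pad, FALSE)
      ctx$grads[[paste0(nm, ".w")]] <- r$gw
      r$gx
    },
    bn = batchnormBackward(spec, gy, ctx),
    act = {
      x <- ctx$caches[[nm]]
      if (spec$fun == "relu") gy * (x > 0) else gy * hswishGrad(x)
    },
    se = seBackward(spec, gy, ctx),
    seq = {
      for (ch in rev(spec$children)) gy <- layerBackward(ch, gy, ctx)
      gy
    },
    residual = {
      g <- gy
      for (ch in rev(spec$children)) g <- layerBackward(ch, g, ctx)
      g + gy
    }
  )
}

# Training-mode batch normalization over (H, W, N) per channel, with
# running statistics (momentum 0.1) for inference.
batchnormForward <- function(spec, x, ctx, eps = 1e-5) {
  nm <- spec$name
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- hw * d[4]
  gamma <- ctx$params[[paste0(nm, ".gamma")]]
  beta <- ctx$params[[paste0(nm, ".beta")]]
  if (ctx$training) {
    mu <- chanSum(x, d) / m
    xc <- x - bcChan(rep(mu, d[4]), hw)
    v <- chanSum(xc * xc, d) / m
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * bcChan(rep(invstd, d[4]), hw)
    ctx$caches[[nm]] <- list(xhat = xhat, invstd = invstd, m = m, d = d)
    ctx$state[[paste0(nm, ".rmean")]] <- 0.9 * ctx$state[[paste0(nm, ".rmean")]] + 0.1 * mu
    ctx$state[[paste0(nm, ".rvar")]] <- 0.9 * ctx$state[[paste0(nm, ".rvar")]] + 0.1 * v * m / max(m - 1, 1)
    xhat * bcChan(rep(gamma, d[4]), hw) + bcChan(rep(beta, d[4]), hw)
  } else {
    mu <- ctx$state[[paste0(nm, ".rmean")]]
    v <- ctx$state[[paste0(nm, ".rvar")]]
    scale <- gamma / sqrt(v + eps)
    x * bcChan(rep(scale, d[4]), hw) + bcChan(rep(beta - mu * scale, d[4]), hw)
  }
}

batchnormBackward <- function(spec, gy, ctx) {
  nm <- spec$name
  cc <- ctx$caches[[nm]]
  d <- cc$d
  hw <- d[1] * d[2]
  gamma <- ctx$params[[paste0(nm, ".gamma")]]
  gbeta <- chanSum(gy, d)
  ggamma <- chanSum(gy * cc$xhat, d)
  ctx$grads[[paste0(nm, ".gamma")]] <- ggamma
  ctx$grads[[paste0(nm, ".beta")]] <- gbeta
  k <- gamma * cc$invstd / cc$m
  gy * bcChan(rep(gamma * cc$invstd, d[4]), hw) -
    bcChan(rep(k * gbeta, d[4]), hw) -
    cc$xhat * bcChan(rep(k * ggamma, d[4]), hw)
}

# Squeeze-and-excitation: global average pool -> FC bottleneck (ReLU) ->
# FC -> hard-sigmoid gate -> per-channel rescale.
seForward <- function(spec, x, ctx) {
  nm <- spec$name
  d <- dim(x)
  hw <- d[1] * d[2]
  s <- matrix(.colSums(x, hw, d[3] * d[4]), d[3], d[4]) / hw # C x N
  w1 <- ctx$params[[paste0(nm, ".w1")]]
  b1 <- ctx$params[[paste0(nm, ".b1")]]
  w2 <- ctx$params[[paste0(nm, ".w2")]]
  b2 <- ctx$params[[paste0(nm, ".b2")]]
  u1 <- w1 %*% s + b1
  z <- reluFw(u1)
  u2 <- w2 %*% z + b2
  g <- hsigmoidFw(u2)
  if (ctx$training)
    ctx$caches[[nm]] <- list(x = x, s = s, u1 = u1, z = z, u2 = u2, g = g, d = d)
  x * bcChan(as.vector(g), hw)
}

seBackward <- function(spec, gy, ctx) {
  nm <- spec$name
  cc <- ctx$caches[[nm]]
  d <- cc$d
  hw <- d[1] * d[2]
  gg <- matrix(.colSums(gy * cc$x, hw, d[3] * d[4]), d[3], d[4]) # dL/dg, C x N
  gx <- gy * bcChan(as.vector(cc$g), hw)
  gu2 <- gg * ((cc$u2 > -3) & (cc$u2 < 3)) / 6
  w2 <- ctx$params[[paste0(nm, ".w2")]]
  w1 <- ctx$params[[paste0(nm, ".w1")]]
  ctx$grads[[paste0(nm, ".w2")]] <- gu2 %*% t(cc$z)
  ctx$grads[[paste0(nm, ".b2")]] <- .rowSums(gu2, nrow(gu2), ncol(gu2))
  gz <- crossprod(w2, gu2) * (cc$u1 > 0)
  ctx$grads[[paste0(nm, ".w1")]] <- gz %*% t(cc$s)
  ctx$grads[[paste0(nm, ".b1")]] <- .rowSums(gz, nrow(gz), ncol(gz))
  gs <- crossprod(w1, gz) / hw # C x N, spread back over pixels
  gx + bcChan(as.vector(gs), hw)
}

## ---- network container --------------------------------------------------

newNetwork <- function(spec, seed = NULL) {
  if (!is.null(seed)) {
    r <- withSeed(seed, initSpecParams(spec))
  } else {
    r <- initSpecParams(spec)
  }
  list(spec = spec, params = r$params, state = r$state)
}

netForward <- function(net, x, training = TRUE) {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- net$params
  ctx$state <- net$state
  ctx$training <- training
  ctx$caches <- list()
  ctx$grads <- list()
  y <- layerForward(net$spec, x, ctx)
  list(out = y, ctx = ctx)
}

netBackward <- function(net, ctx, gy) {
  gx <- layerBackward(net$spec, gy, ctx)
  list(gin = gx, grads = ctx$grads)
}

# SGD with momentum in the torch convention: v <- mu * v + g; p <- p - lr * v.
sgdStep <- function(params, grads, velocity, lr, momentum) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v <- velocity[[nm]]
    if (is.null(v)) v <- 0 * g
    v <- momentum * v + g
    params[[nm]] <- params[[nm]] - lr * v
    velocity[[nm]] <- v
  }
  list(params = params, velocity = velocity)
}
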