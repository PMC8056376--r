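# Shared internal helpers.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state so
# package functions never perturb the user's random stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Truncated-normal draws by inverse-CDF; deterministic under set.seed.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

stopIfNot2dImage <- function(image, what = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(what, " must be a 2-D numeric matrix (grayscale raster)")
  if (any(!is.finite(image)))
    stop(what, " contains non-finite values")
  invisible(image)
}

# Grayscale matrix from whatever EBImage::readImage returned.
asGrayMatrix <- function(img) {
  a <- as.array(img)
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
  # EBImage stores images x-major (columns are y); transpose to (row, col)
  t(a)
}
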