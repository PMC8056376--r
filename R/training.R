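# Training and evaluation of the bone-age regressor: SGD with momentum on
# mean squared error over standardized bone age; MAE in months for
# evaluation.

#' Fit an age standardizer on training ages
#'
#' @param ages numeric bone ages in months (training split only).
#' @return an \code{\link{AgeStandardizer}}.
#' @export
fitAgeStandardizer <- function(ages) {
  if (length(ages) < 2) stop("need at least 2 ages to fit a standardizer")
  AgeStandardizer(mean(ages), stats::sd(ages))
}

#' Standardize / destandardize bone age
#'
#' \code{standardizeAge} maps months to \code{(Y - mu) / sigma};
#' \code{destandardizeAge} is the exact inverse.
#'
#' @param y numeric vector (months, or standardized units respectively).
#' @param s an \code{\link{AgeStandardizer}}.
#' @return numeric vector.
#' @export
standardizeAge <- function(y, s) {
  validObject(s)
  (y - s@mu) / s@sigma
}

#' @rdname standardizeAge
#' @export
destandardizeAge <- function(y, s) {
  validObject(s)
  y * s@sigma + s@mu
}

#' Mean squared error
#'
#' @param predictions,targets equal-length numeric vectors (length >= 1).
#' @return mean of squared differences.
#' @export
mseLoss <- function(predictions, targets) {
  if (length(predictions) != length(targets))
    stop("predictions and targets must have equal length")
  if (length(predictions) < 1) stop("need at least one element")
  mean((predictions - targets)^2)
}

#' 7:2:1 train/validation/test split
#'
#' Seeded random shuffle followed by a contiguous partition at the 70% and
#' 90% quantile indices: 100 records yield sizes (70, 20, 10). Splits are
#' disjoint and exhaustive.
#'
#' @param n number of records (>= 10), or a \code{\link{RadiographSet}}.
#' @param spec a \code{\link{splitSpec}}.
#' @return list of integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
splitDataset <- function(n, spec = splitSpec()) {
  if (is(n, "RadiographSet")) n <- length(n)
  n <- as.integer(n)
  if (n < 10L) stop("need at least 10 records to split without empty parts")
  withSeed(spec@seed, {
    idx <- sample.int(n)
    # tiny epsilon guards against 0.7 + 0.2 = 0.8999... under binary floats
    ntrain <- floor(spec@trainFraction * n + 1e-9)
    nval <- floor((spec@trainFraction + spec@valFraction) * n + 1e-9) - ntrain
    list(train = idx[seq_len(ntrain)],
         val = idx[ntrain + seq_len(nval)],
         test = idx[(ntrain + nval + 1):n])
  })
}

#' Step learning-rate schedule
#'
#' \code{lr(epoch) = baseLr * factor^(-floor(epoch / every))} with 0-based
#' epochs: the learning rate is divided by \code{factor} every \code{every}
#' epochs (10x every 30 in the reference protocol).
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param baseLr initial learning rate.
#' @param factor,every decay factor and period.
#' @return learning rate(s).
#' @export
lrSchedule <- function(epoch, baseLr = 0.01, factor = 10, every = 30L) {
  baseLr * factor^(-(epoch %/% every))
}

#' Random training-time augmentation
#'
#' Random crop (retaining a uniform fraction of each side) with resize back,
#' rotation, and contrast/brightness jitter, clipped to [0, 1]. Draws from
#' the current RNG stream; with \code{config@enabled == FALSE} the image is
#' returned unchanged.
#'
#' @param image 2-D numeric matrix in [0, 1].
#' @param config an \code{\link{augmentConfig}}.
#' @return augmented matrix, same dimensions.
#' @export
augmentImage <- function(image, config = augmentConfig()) {
  if (!config@enabled) return(image)
  H <- nrow(image); W <- ncol(image)
  f <- stats::runif(1, config@cropFraction[1], config@cropFraction[2])
  ch <- max(2L, round(f * H)); cw <- max(2L, round(f * W))
  r0 <- sample.int(H - ch + 1L, 1); c0 <- sample.int(W - cw + 1L, 1)
  out <- image[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
  if (ch != H || cw != W) out <- resizeBilinear(out, H, W)
  ang <- stats::runif(1, config@rotationDeg[1], config@rotationDeg[2])
  if (abs(ang) > 1e-8) {
    rot <- EBImage::rotate(EBImage::Image(t(out)), ang,
                           output.dim = c(W, H), bg.col = "black")
    out <- t(as.array(rot))
  }
  cmul <- stats::runif(1, config@contrast[1], config@contrast[2])
  badd <- stats::runif(1, config@brightness[1], config@brightness[2])
  clamp01((out - 0.5) * cmul + 0.5 + badd)
}

# Stack matrices into the (H, W, 3, N) model input tensor.
stackGray <- function(mats) {
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  arr <- array(0, dim = c(H, W, 3L, length(mats)))
  for (i in seq_along(mats)) arr[, , , i] <- array(rep(mats[[i]], 3), c(H, W, 3L))
  arr
}

#' Train the bone-age regression model
#'
#' Prepares model inputs (optionally through the full pre-processing
#' pipeline, otherwise pad-to-square + resize), fits the age standardizer on
#' the training split only, and runs SGD with momentum on the mean squared
#' error of standardized bone age. The learning rate follows
#' \code{\link{lrSchedule}}; augmentation applies to training images only;
#' the checkpoint with the best validation MAE is retained.
#'
#' @param set a \code{\link{RadiographSet}}.
#' @param config a \code{\link{trainConfig}}.
#' @param split list of train/val index vectors (from
#'   \code{\link{splitDataset}}); by default all-but-two records train and
#'   two validate for very small sets, else a seeded 7:2:1 split.
#' @param clusterConfig segmentation config used when
#'   \code{config@usePreprocess} is TRUE.
#' @param model optionally a pre-built \code{\link{BoneAgeModel}} (e.g. with
#'   loaded backbone weights); built fresh otherwise.
#' @param verbose print per-epoch losses.
#' @return list with \code{model} (best-validation checkpoint, standardizer
#'   attached) and \code{history} (per-epoch data.frame of lr, train MSE,
#'   validation MSE and MAE).
#' @export
trainModel <- function(set, config = trainConfig(), split = NULL,
                       clusterConfig = clusterNetConfig(), model = NULL,
                       verbose = FALSE) {
  n <- length(set)
  if (is.null(split)) {
    split <- if (n >= 10) splitDataset(n, splitSpec(seed = config@seed))
             else list(train = seq_len(max(1, n - 2)),
                       val = if (n > 2) (n - 1):n else seq_len(n))
  }
  if (!length(split$train)) stop("empty training split")

  prep <- function(i) {
    img <- set@images[[i]]
    if (config@usePreprocess)
      preprocessPipeline(img, clusterConfig, size = config@inputSize,
                         seed = config@seed + i)$image
    else {
      fill <- stats::median(img[c(1, nrow(img)), ])
      resizeBilinear(padToSquare(img, fill), config@inputSize, config@inputSize)
    }
  }
  inputs <- lapply(seq_len(n), prep)

  std <- fitAgeStandardizer(boneAge(set)[split$train])
  targets <- standardizeAge(boneAge(set), std)
  gender <- as.numeric(isMale(set))

  if (is.null(model))
    model <- buildBoneAgeModel(inputSize = config@inputSize,
                               useGender = config@useGender, seed = config@seed)
  model@standardizer <- std

  evalSplit <- function(idx) {
    if (!length(idx)) return(c(NA_real_, NA_real_))
    yh <- modelForward(model, stackGray(inputs[idx]),
                       if (model@useGender) gender[idx], training = FALSE)$yhat
    c(mseLoss(yh, targets[idx]),
      mean(abs(destandardizeAge(yh, std) - boneAge(set)[idx])))
  }

  velH <- list(); velN <- list()
  history <- NULL
  best <- list(mae = Inf, net = model@net$params, head = model@head,
               state = model@net$state)
  withSeed(config@seed, {
    for (epoch in seq_len(config@epochs)) {
      lr <- lrSchedule(epoch - 1L, config@baseLr, config@lrDecayFactor,
                       config@lrDecayEvery)
      order <- sample(split$train)
      nb <- split(order, ceiling(seq_along(order) / config@batchSize))
      epochLoss <- 0
      for (batch in nb) {
        mats <- lapply(inputs[batch], augmentImage, config = config@augment)
        fwd <- modelForward(model, stackGray(mats),
                            if (model@useGender) gender[batch], training = TRUE)
        res <- fwd$yhat - targets[batch]
        loss <- mean(res^2)
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss at epoch %d (batch of %d)",
                       epoch, length(batch)))
        epochLoss <- epochLoss + loss * length(batch)
        gy <- 2 * res / length(batch)
        grads <- modelBackward(model, fwd, gy)
        sh <- sgdStep(model@head, grads$head, velH, lr, config@momentum)
        model@head <- sh$params; velH <- sh$velocity
        sn <- sgdStep(model@net$params, grads$net, velN, lr, config@momentum)
        model@net$params <- sn$params; velN <- sn$velocity
        model@net$state <- as.list(fwd$ctx$state)
      }
      vm <- evalSplit(split$val)
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr,
        trainMSE = epochLoss / length(split$train),
        valMSE = vm[1], valMAE = vm[2]))
      if (verbose)
        message(sprintf("epoch %3d lr %.2e train MSE %.4f val MAE %.2f",
                        epoch, lr, history$trainMSE[epoch], vm[2]))
      if (is.finite(vm[2]) && vm[2] < best$mae)
        best <- list(mae = vm[2], net = model@net$params, head = model@head,
                     state = model@net$state)
    }
  })
  if (is.finite(best$mae)) {
    model@net$params <- best$net
    model@net$state <- best$state
    model@head <- best$head
  }
  list(model = model, history = history)
}

#' Mean absolute error in months
#'
#' Mean over records of the absolute difference between the destandardized
#' prediction and the ground-truth bone age.
#'
#' @param model a trained \code{\link{BoneAgeModel}} (standardizer attached).
#' @param set a \code{\link{RadiographSet}} whose images already match the
#'   model input size, or arbitrary sizes (resized deterministically).
#' @param indices optional subset of records to evaluate.
#' @return MAE in months.
#' @export
evaluateMAE <- function(model, set, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(length(set))
  if (!length(indices)) stop("empty record set")
  if (is.null(model@standardizer)) stop("model has no age standardizer; train first")
  preds <- predictAge(model, images(set)[indices],
                      male = if (model@useGender) isMale(set)[indices])
  mean(abs(preds - boneAge(set)[indices]))
}
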