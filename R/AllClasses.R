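#' @import methods
NULL

## ---- BoundingBox ---------------------------------------------------------

#' Axis-aligned bounding box
#'
#' Pixel coordinates are 0-based and half-open: the box covers rows
#' \code{[rowMin, rowMax)} and columns \code{[colMin, colMax)}. This keeps
#' crop arithmetic unambiguous; conversion to R's 1-based indexing happens
#' inside \code{\link{cropImage}}.
#'
#' @slot rowMin,rowMax,colMin,colMax integer box limits.
#' @export
setClass("BoundingBox",
  representation(rowMin = "integer", rowMax = "integer",
                 colMin = "integer", colMax = "integer"),
  validity = function(object) {
    if (object@rowMin < 0 || object@colMin < 0)
      return("box limits must be non-negative")
    if (object@rowMin >= object@rowMax || object@colMin >= object@colMax)
      return("box must have positive extent (min < max)")
    TRUE
  })

#' @param rowMin,rowMax,colMin,colMax box limits, 0-based half-open.
#' @rdname BoundingBox-class
#' @export
BoundingBox <- function(rowMin, rowMax, colMin, colMax) {
  new("BoundingBox", rowMin = as.integer(rowMin), rowMax = as.integer(rowMax),
      colMin = as.integer(colMin), colMax = as.integer(colMax))
}

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox rows [%d,%d) x cols [%d,%d)  (%d x %d px)\n",
              object@rowMin, object@rowMax, object@colMin, object@colMax,
              object@rowMax - object@rowMin, object@colMax - object@colMin))
})

#' Box width/height and area in pixels
#' @param box a \code{BoundingBox}.
#' @return \code{bboxArea}: integer pixel area.
#' @export
bboxArea <- function(box) {
  (box@rowMax - box@rowMin) * (box@colMax - box@colMin)
}

#' Intersection-over-union of two boxes
#' @param a,b \code{BoundingBox} objects.
#' @return IoU in [0, 1].
#' @export
bboxIoU <- function(a, b) {
  ih <- max(0L, min(a@rowMax, b@rowMax) - max(a@rowMin, b@rowMin))
  iw <- max(0L, min(a@colMax, b@colMax) - max(a@colMin, b@colMin))
  inter <- as.numeric(ih) * iw
  inter / (bboxArea(a) + bboxArea(b) - inter)
}

## ---- SceneSpec -----------------------------------------------------------

#' Synthetic radiograph scene specification
#'
#' Describes one synthetic hand-wrist radiograph: a single bright, connected
#' hand-shaped foreground blob (ellipse palm plus finger ellipses, or a
#' rectangle for degenerate test scenes) on a darker noisy background, with
#' optional small bright distractor blobs. The hand is always the largest
#' connected foreground region, the prerequisite for the maximum-area rule
#' used by the localization pipeline.
#'
#' @slot imageHeight,imageWidth frame size in pixels.
#' @slot handCenter numeric (row, col) center of the hand, in pixels.
#' @slot handScale hand size as a fraction of \code{min(H, W)}.
#' @slot nFingers number of finger lobes (ignored for \code{"rect"} shapes).
#' @slot backgroundLevel,foregroundLevel intensities in [0, 1]; the
#'   foreground must be brighter than the background, matching radiograph
#'   appearance.
#' @slot noiseSd standard deviation of additive Gaussian noise.
#' @slot nDistractors number of small distractor blobs.
#' @slot handShape \code{"hand"} (ellipse palm + fingers) or \code{"rect"}.
#' @slot seed integer RNG seed; rendering is bit-reproducible per seed.
#' @export
setClass("SceneSpec",
  representation(imageHeight = "integer", imageWidth = "integer",
                 handCenter = "numeric", handScale = "numeric",
                 nFingers = "integer", backgroundLevel = "numeric",
                 foregroundLevel = "numeric", noiseSd = "numeric",
                 nDistractors = "integer", handShape = "character",
                 seed = "integer"),
  validity = function(object) {
    if (object@imageHeight < 16L || object@imageWidth < 16L)
      return("frame must be at least 16 x 16 pixels")
    if (object@foregroundLevel <= object@backgroundLevel)
      return("foregroundLevel must exceed backgroundLevel (hand brighter than background)")
    if (object@handScale <= 0 || object@handScale > 1)
      return("handScale must be in (0, 1]")
    if (object@noiseSd < 0) return("noiseSd must be non-negative")
    if (object@nDistractors < 0) return("nDistractors must be non-negative")
    if (!object@handShape %in% c("hand", "rect"))
      return("handShape must be 'hand' or 'rect'")
    TRUE
  })

#' @param imageHeight,imageWidth,handCenter,handScale,nFingers frame and hand
#'   geometry; see slots.
#' @param backgroundLevel,foregroundLevel,noiseSd intensity model.
#' @param nDistractors,handShape,seed see slots.
#' @rdname SceneSpec-class
#' @export
SceneSpec <- function(imageHeight = 128L, imageWidth = 128L,
                      handCenter = c(imageHeight, imageWidth) / 2,
                      handScale = 0.55, nFingers = 5L,
                      backgroundLevel = 0.15, foregroundLevel = 0.75,
                      noiseSd = 0.05, nDistractors = 2L,
                      handShape = "hand", seed = 1L) {
  new("SceneSpec", imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth), handCenter = as.numeric(handCenter),
      handScale = handScale, nFingers = as.integer(nFingers),
      backgroundLevel = backgroundLevel, foregroundLevel = foregroundLevel,
      noiseSd = noiseSd, nDistractors = as.integer(nDistractors),
      handShape = handShape, seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec %dx%d, %s hand (scale %.2f, %d fingers), bg %.2f fg %.2f, noise %.3f, %d distractor(s), seed %d\n",
              object@imageHeight, object@imageWidth, object@handShape,
              object@handScale, object@nFingers, object@backgroundLevel,
              object@foregroundLevel, object@noiseSd, object@nDistractors,
              object@seed))
})

## ---- RadiographSet -------------------------------------------------------

#' A set of (synthetic) hand radiographs with metadata and ground truth
#'
#' Container for radiograph records in the RSNA-style schema: per-record
#' \code{id}, \code{boneage} (months) and \code{male} (logical), plus the
#' grayscale images and, for synthetic data, the ground-truth hand masks and
#' bounding boxes.
#'
#' @slot images list of numeric H x W matrices with intensities in [0, 1].
#' @slot meta data.frame with columns \code{id}, \code{boneage}, \code{male}.
#' @slot masks list of logical H x W ground-truth hand masks (may be empty
#'   for real data).
#' @slot bboxes list of \code{BoundingBox} ground-truth hand boxes.
#' @export
setClass("RadiographSet",
  representation(images = "list", meta = "data.frame",
                 masks = "list", bboxes = "list"),
  validity = function(object) {
    n <- length(object@images)
    if (nrow(object@meta) != n)
      return("metadata rows must match number of images")
    if (!all(c("id", "boneage", "male") %in% names(object@meta)))
      return("meta must have columns id, boneage, male")
    if (anyDuplicated(object@meta$id))
      return("record ids must be unique")
    if (any(object@meta$boneage < 0 | object@meta$boneage > 240))
      return("boneage must lie in [0, 240] months")
    if (!is.logical(object@meta$male))
      return("male must be logical")
    if (length(object@masks) && length(object@masks) != n)
      return("masks, when present, must match number of images")
    TRUE
  })

setMethod("show", "RadiographSet", function(object) {
  n <- length(object@images)
  cat(sprintf("RadiographSet with %d record(s)\n", n))
  if (n) {
    sz <- vapply(object@images, function(im) paste(dim(im), collapse = "x"), "")
    cat(sprintf("  sizes: %s\n", paste(unique(sz), collapse = ", ")))
    cat(sprintf("  bone age: %.0f-%.0f months; male: %d/%d\n",
                min(object@meta$boneage), max(object@meta$boneage),
                sum(object@meta$male), n))
    cat(sprintf("  ground truth: %s\n",
                if (length(object@masks)) "masks + boxes" else "none"))
  }
})

setMethod("length", "RadiographSet", function(x) length(x@images))

#' Accessors for RadiographSet
#' @param x a \code{RadiographSet}.
#' @return \code{images}: list of grayscale matrices; \code{recordMeta}: the
#'   metadata data.frame; \code{handMasks}/\code{handBoxes}: ground truth;
#'   \code{boneAge}: numeric months; \code{isMale}: logical.
#' @rdname RadiographSet-accessors
#' @export
images <- function(x) x@images
#' @rdname RadiographSet-accessors
#' @export
recordMeta <- function(x) x@meta
#' @rdname RadiographSet-accessors
#' @export
handMasks <- function(x) x@masks
#' @rdname RadiographSet-accessors
#' @export
handBoxes <- function(x) x@bboxes
#' @rdname RadiographSet-accessors
#' @export
boneAge <- function(x) x@meta$boneage
#' @rdname RadiographSet-accessors
#' @export
isMale <- function(x) x@meta$male

## ---- LabelMap ------------------------------------------------------------

#' Per-pixel cluster label map
#'
#' Integer raster of cluster assignments produced by
#' \code{\link{segmentImage}} (or \code{\link{assignLabels}}); entries lie in
#' \code{[0, q)} where \code{q} is the maximum number of cluster labels.
#'
#' @slot labels integer H x W matrix of 0-based cluster labels.
#' @slot q upper bound on the number of labels.
#' @export
setClass("LabelMap",
  representation(labels = "matrix", q = "integer"),
  validity = function(object) {
    if (!is.integer(object@labels)) return("labels must be an integer matrix")
    if (any(object@labels < 0L) || any(object@labels >= object@q))
      return("labels must lie in [0, q)")
    TRUE
  })

#' @param labels integer matrix of 0-based labels.
#' @param q label-count upper bound.
#' @rdname LabelMap-class
#' @export
LabelMap <- function(labels, q) {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, q = as.integer(q))
}

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap %d x %d, %d distinct label(s) of at most %d\n",
              nrow(object@labels), ncol(object@labels),
              length(unique(as.vector(object@labels))), object@q))
})

#' @rdname LabelMap-class
#' @param x a \code{LabelMap}.
#' @export
labelMatrix <- function(x) x@labels

#' Number of distinct labels present
#' @param x a \code{LabelMap}.
#' @export
nLabels <- function(x) length(unique(as.vector(x@labels)))

## ---- ClusterNetConfig ----------------------------------------------------

#' Configuration of the per-image clustering network
#'
#' Hyperparameters of the unsupervised localizer: a small CNN is optimized
#' on the single target image with a feature-similarity plus
#' spatial-continuity loss, and the per-pixel argmax over its q output
#' channels yields the segmentation. Defaults follow the reference setting:
#' p = q = 90 channels, 50 iterations of SGD with momentum 0.9 at learning
#' rate 0.1, and loss weights lambda = 4 (similarity), mu = 1 (continuity).
#'
#' @slot p feature channels of the convolutional trunk.
#' @slot q maximum number of cluster labels (output channels).
#' @slot nConvLayers number of 3x3 convolution layers in the trunk.
#' @slot kernelSize spatial kernel size of the trunk convolutions.
#' @slot lr,momentum SGD hyperparameters.
#' @slot nIterations optimization iterations on the target image.
#' @slot lambdaSim,muCon loss weights (lambda, mu).
#' @slot workingSize images whose longest side exceeds this are downscaled
#'   before clustering and the label map is upscaled back (nearest neighbor).
#' @export
setClass("ClusterNetConfig",
  representation(p = "integer", q = "integer", nConvLayers = "integer",
                 kernelSize = "integer", lr = "numeric", momentum = "numeric",
                 nIterations = "integer", lambdaSim = "numeric",
                 muCon = "numeric", workingSize = "integer"),
  validity = function(object) {
    if (object@q < 2L) return("q must be at least 2")
    if (object@p < object@q) return("p must be >= q")
    if (object@nIterations < 1L) return("nIterations must be >= 1")
    if (object@lambdaSim < 0 || object@muCon < 0)
      return("loss weights must be non-negative")
    if (object@nConvLayers < 1L) return("nConvLayers must be >= 1")
    TRUE
  })

#' @param p,q,nConvLayers,kernelSize,lr,momentum,nIterations,lambdaSim,muCon,workingSize
#'   see slots.
#' @rdname ClusterNetConfig-class
#' @export
clusterNetConfig <- function(p = 90L, q = 90L, nConvLayers = 2L,
                             kernelSize = 3L, lr = 0.1, momentum = 0.9,
                             nIterations = 50L, lambdaSim = 4, muCon = 1,
                             workingSize = 256L) {
  new("ClusterNetConfig", p = as.integer(p), q = as.integer(q),
      nConvLayers = as.integer(nConvLayers), kernelSize = as.integer(kernelSize),
      lr = lr, momentum = momentum, nIterations = as.integer(nIterations),
      lambdaSim = lambdaSim, muCon = muCon, workingSize = as.integer(workingSize))
}

setMethod("show", "ClusterNetConfig", function(object) {
  cat(sprintf("ClusterNetConfig p=%d q=%d, %d conv layer(s) %dx%d, %d iteration(s), lr=%g mom=%g, lambda=%g mu=%g, working size %d\n",
              object@p, object@q, object@nConvLayers, object@kernelSize,
              object@kernelSize, object@nIterations, object@lr, object@momentum,
              object@lambdaSim, object@muCon, object@workingSize))
})

## ---- AgeStandardizer -----------------------------------------------------

#' Bone-age standardizer
#'
#' Holds the training-set mean and standard deviation of bone age (months).
#' Regression targets are standardized as \code{(Y - mu) / sigma} and
#' predictions are mapped back to months by the inverse transform.
#'
#' @slot mu training-set mean bone age, months.
#' @slot sigma training-set standard deviation, months; must be positive.
#' @export
setClass("AgeStandardizer",
  representation(mu = "numeric", sigma = "numeric"),
  validity = function(object) {
    if (!is.finite(object@mu)) return("mu must be finite")
    if (!is.finite(object@sigma) || object@sigma <= 0)
      return("sigma must be positive")
    TRUE
  })

#' @param mu,sigma mean and standard deviation in months.
#' @rdname AgeStandardizer-class
#' @export
AgeStandardizer <- function(mu, sigma) new("AgeStandardizer", mu = mu, sigma = sigma)

setMethod("show", "AgeStandardizer", function(object) {
  cat(sprintf("AgeStandardizer mu=%.2f months, sigma=%.2f months\n",
              object@mu, object@sigma))
})

## ---- AugmentConfig / TrainConfig / SplitSpec ------------------------------

#' Training-time augmentation configuration
#'
#' Random crop + resize, rotation, and contrast/brightness jitter applied to
#' training images only. Disabling augmentation yields the identity
#' transform.
#'
#' @slot enabled logical.
#' @slot cropFraction length-2 range of the retained side fraction.
#' @slot rotationDeg length-2 range of rotation angles, degrees.
#' @slot contrast,brightness length-2 multiplicative / additive jitter ranges.
#' @export
setClass("AugmentConfig",
  representation(enabled = "logical", cropFraction = "numeric",
                 rotationDeg = "numeric", contrast = "numeric",
                 brightness = "numeric"),
  validity = function(object) {
    rng <- function(r) length(r) == 2 && all(is.finite(r)) && r[1] <= r[2]
    if (!rng(object@cropFraction) || object@cropFraction[1] <= 0 ||
        object@cropFraction[2] > 1)
      return("cropFraction must be a range within (0, 1]")
    if (!rng(object@rotationDeg) || !rng(object@contrast) || !rng(object@brightness))
      return("rotationDeg, contrast, brightness must be finite low<=high ranges")
    TRUE
  })

#' @param enabled,cropFraction,rotationDeg,contrast,brightness see slots.
#' @rdname AugmentConfig-class
#' @export
augmentConfig <- function(enabled = TRUE, cropFraction = c(0.9, 1),
                          rotationDeg = c(-10, 10), contrast = c(0.9, 1.1),
                          brightness = c(-0.1, 0.1)) {
  new("AugmentConfig", enabled = enabled, cropFraction = as.numeric(cropFraction),
      rotationDeg = as.numeric(rotationDeg), contrast = as.numeric(contrast),
      brightness = as.numeric(brightness))
}

#' Training configuration for the bone-age regressor
#'
#' Mirrors the reference protocol: SGD with momentum 0.9 minimizing mean
#' squared error on standardized bone age, batch size 10, 160 epochs, the
#' learning rate divided by 10 every 30 epochs. The three ablation axes
#' (gender embedding, pre-processing, pre-trained backbone) and the input
#' size (224/500/700) are switches.
#'
#' @slot batchSize,epochs,baseLr,lrDecayFactor,lrDecayEvery,momentum optimizer
#'   schedule; the base learning rate defaults to 0.01 (the published account
#'   leaves it unstated).
#' @slot inputSize square model input size in pixels.
#' @slot useGender,usePreprocess,usePretrained ablation switches.
#' @slot seed RNG seed.
#' @slot augment an \code{AugmentConfig}.
#' @export
setClass("TrainConfig",
  representation(batchSize = "integer", epochs = "integer", baseLr = "numeric",
                 lrDecayFactor = "numeric", lrDecayEvery = "integer",
                 momentum = "numeric", inputSize = "integer",
                 useGender = "logical", usePreprocess = "logical",
                 usePretrained = "logical", seed = "integer",
                 augment = "AugmentConfig"),
  validity = function(object) {
    if (object@batchSize < 1L || object@epochs < 1L || object@lrDecayEvery < 1L)
      return("counts must be >= 1")
    if (object@lrDecayFactor <= 1) return("lrDecayFactor must exceed 1")
    if (object@baseLr <= 0) return("baseLr must be positive")
    TRUE
  })

#' @param batchSize,epochs,baseLr,lrDecayFactor,lrDecayEvery,momentum,inputSize,useGender,usePreprocess,usePretrained,seed,augment
#'   see slots.
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(batchSize = 10L, epochs = 160L, baseLr = 0.01,
                        lrDecayFactor = 10, lrDecayEvery = 30L, momentum = 0.9,
                        inputSize = 224L, useGender = TRUE,
                        usePreprocess = TRUE, usePretrained = FALSE,
                        seed = 1L, augment = augmentConfig()) {
  new("TrainConfig", batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      baseLr = baseLr, lrDecayFactor = lrDecayFactor,
      lrDecayEvery = as.integer(lrDecayEvery), momentum = momentum,
      inputSize = as.integer(inputSize), useGender = useGender,
      usePreprocess = usePreprocess, usePretrained = usePretrained,
      seed = as.integer(seed), augment = augment)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf("TrainConfig: batch %d, %d epoch(s), lr %g /%g every %d, momentum %g, input %dx%d\n",
              object@batchSize, object@epochs, object@baseLr, object@lrDecayFactor,
              object@lrDecayEvery, object@momentum, object@inputSize, object@inputSize))
  cat(sprintf("  gender=%s preprocess=%s pretrained=%s augment=%s seed=%d\n",
              object@useGender, object@usePreprocess, object@usePretrained,
              object@augment@enabled, object@seed))
})

#' Train/validation/test split specification (7:2:1 by default)
#'
#' @slot trainFraction,valFraction,testFraction fractions summing to 1.
#' @slot seed shuffle seed.
#' @export
setClass("SplitSpec",
  representation(trainFraction = "numeric", valFraction = "numeric",
                 testFraction = "numeric", seed = "integer"),
  validity = function(object) {
    f <- c(object@trainFraction, object@valFraction, object@testFraction)
    if (any(f < 0)) return("fractions must be non-negative")
    if (abs(sum(f) - 1) > 1e-8) return("fractions must sum to 1")
    TRUE
  })

#' @param trainFraction,valFraction,testFraction,seed see slots.
#' @rdname SplitSpec-class
#' @export
splitSpec <- function(trainFraction = 0.7, valFraction = 0.2,
                      testFraction = 0.1, seed = 1L) {
  new("SplitSpec", trainFraction = trainFraction, valFraction = valFraction,
      testFraction = testFraction, seed = as.integer(seed))
}

## ---- BoneAgeModel --------------------------------------------------------

#' Gender-embedded bone-age regression network
#'
#' The assembled model: MobileNetV3-style backbone mapping an H x W x 3 image
#' to a 1280-vector (adaptive average pooling makes the width independent of
#' input size), an optional 24-dimension rectified linear embedding of the
#' binary gender flag concatenated into a 1304-vector, and a one-hidden-layer
#' MLP (1304 neurons, ReLU) producing a single standardized-age scalar.
#'
#' @slot arch data.frame describing the backbone block table.
#' @slot net backbone network (spec + parameters + batch-norm state).
#' @slot head named list of head parameters (gender embedding + MLP).
#' @slot inputSize configured square input size.
#' @slot useGender whether the gender branch exists.
#' @slot standardizer an \code{AgeStandardizer}, or NULL before training.
#' @export
setClass("BoneAgeModel",
  representation(arch = "data.frame", net = "list", head = "list",
                 inputSize = "integer", useGender = "logical",
                 standardizer = "ANY"))

setMethod("show", "BoneAgeModel", function(object) {
  cat(sprintf("BoneAgeModel: MobileNetV3-style backbone, input %dx%dx3, gender embedding %s\n",
              object@inputSize, object@inputSize,
              if (object@useGender) "24-d" else "disabled"))
  cat(sprintf("  learnable parameters: %s\n",
              format(countParameters(object), big.mark = ",")))
  if (!is.null(object@standardizer))
    cat(sprintf("  age standardizer: mu=%.1f sigma=%.1f months\n",
                object@standardizer@mu, object@standardizer@sigma))
})
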