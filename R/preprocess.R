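# Image-processing pipeline: raw radiograph + unsupervised label map ->
# cropped, contrast-equalized hand image.
#
# Background removal takes the cluster label owning the most image-border
# pixels as background (radiograph background always touches the frame
# edge); connectivity analysis then keeps the maximum-area foreground
# component as the hand region, whose bounding box drives the crop.

#' Foreground mask from a cluster label map
#'
#' Radiograph background always touches the frame edge, so background is
#' identified on the image border: the cluster label with the largest count
#' of border pixels is background (ties break to the lower label index), and
#' so is every other label owning at least \code{borderShare} of the border
#' — per-image clustering routinely leaves the background split across a few
#' labels, all of them border-heavy, while hand labels stay interior. Every
#' pixel carrying a non-background label is foreground.
#'
#' @param labels a \code{\link{LabelMap}}.
#' @param borderShare minimum fraction of border pixels for a label to count
#'   as background (beyond the always-removed top label).
#' @return logical H x W mask.
#' @export
foregroundMask <- function(labels, borderShare = 0.05) {
  stopifnot(is(labels, "LabelMap"))
  lm <- labels@labels
  if (length(unique(as.vector(lm))) < 2L)
    stop("no foreground separable: label map has a single distinct label")
  H <- nrow(lm); W <- ncol(lm)
  border <- c(lm[1, ], lm[H, ], lm[2:(H - 1), 1], lm[2:(H - 1), W])
  counts <- table(border)
  # names are sorted numerically-as-strings; order by count then label index
  cand <- as.integer(names(counts))
  n <- as.integer(counts)
  bg <- c(cand[order(-n, cand)][1], cand[n >= borderShare * length(border)])
  mask <- !(lm %in% bg)
  dim(mask) <- dim(lm)
  if (!any(mask))
    stop("no foreground separable: all labels are border-dominant")
  mask
}

#' Connected components of a binary mask
#'
#' 8-connected components (configurable), each summarized by label, pixel
#' area, tight bounding box and whether it touches the image border; sorted
#' by area, largest first.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return data.frame with columns \code{label}, \code{area}, \code{rowMin},
#'   \code{rowMax}, \code{colMin}, \code{colMax} (0-based half-open) and
#'   \code{touchesBorder}; zero rows for an empty mask.
#' @export
connectedComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (!is.logical(mask)) mask <- mask != 0
  lab <- cpp_label_components(mask, as.integer(connectivity))
  k <- max(lab)
  out <- data.frame(label = integer(0), area = integer(0),
                    rowMin = integer(0), rowMax = integer(0),
                    colMin = integer(0), colMax = integer(0),
                    touchesBorder = logical(0))
  if (k == 0L) return(out)
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  out <- data.frame(
    label = seq_len(k),
    area = as.integer(tabulate(comp, k)),
    rowMin = as.integer(tapply(rows, comp, min)) - 1L,
    rowMax = as.integer(tapply(rows, comp, max)),
    colMin = as.integer(tapply(cols, comp, min)) - 1L,
    colMax = as.integer(tapply(cols, comp, max)),
    row.names = NULL)
  out$touchesBorder <- out$rowMin == 0L | out$colMin == 0L |
    out$rowMax == H | out$colMax == W
  out[order(-out$area, out$label), , drop = FALSE]
}

#' Hand bounding box: maximum-area component plus margin
#'
#' Selects the largest component (the hand, by the maximum-area rule) and
#' expands its tight box by a margin fraction of each image dimension,
#' clipped to the frame.
#'
#' @param components data.frame from \code{\link{connectedComponents}}.
#' @param frameDim integer (H, W) of the source image.
#' @param margin expansion fraction per side (default 2\%).
#' @return a \code{\link{BoundingBox}}.
#' @export
handBBox <- function(components, frameDim, margin = 0.02) {
  if (is.null(components) || nrow(components) == 0)
    stop("no hand found: component list is empty")
  top <- components[1, ]
  mr <- round(margin * frameDim[1])
  mc <- round(margin * frameDim[2])
  BoundingBox(max(0L, top$rowMin - mr), min(frameDim[1], top$rowMax + mr),
              max(0L, top$colMin - mc), min(frameDim[2], top$colMax + mc))
}

#' Crop an image to a bounding box
#'
#' @param image numeric matrix.
#' @param bbox a \code{\link{BoundingBox}} (0-based half-open) within the
#'   frame.
#' @return the cropped matrix, pixel values untouched.
#' @export
cropImage <- function(image, bbox) {
  H <- nrow(image); W <- ncol(image)
  if (bbox@rowMax > H || bbox@colMax > W)
    stop("bounding box extends outside the image frame")
  image[(bbox@rowMin + 1L):bbox@rowMax, (bbox@colMin + 1L):bbox@colMax, drop = FALSE]
}

#' Global histogram equalization
#'
#' Classic CDF remapping on 8-bit quantized intensities: intensities in
#' [0, 1] are quantized to 0..255, and level v maps to
#' \code{round(255 * (cdf(v) - cdf_min) / (N - cdf_min))}. The mapping is
#' monotone; output values lie in [0, 255] with spatial dims preserved.
#'
#' @param image numeric matrix; values in [0, 1] are scaled to 8-bit first,
#'   values already in [0, 255] are used as-is.
#' @return numeric matrix of equalized 8-bit levels.
#' @export
equalizeHist <- function(image) {
  stopIfNot2dImage(image)
  v <- if (max(image) <= 1) round(image * 255) else round(image)
  v <- pmin.int(pmax.int(v, 0), 255)
  h <- tabulate(as.integer(v) + 1L, 256L)
  cdf <- cumsum(h)
  cdfmin <- cdf[which(h > 0)[1]]
  n <- length(v)
  map <- if (n == cdfmin) seq.int(0L, 255L) # constant image: identity map
         else round(255 * (cdf - cdfmin) / (n - cdfmin))
  matrix(map[as.integer(v) + 1L], nrow(image), ncol(image))
}

# Pad a matrix to square with a fill value, centering the content.
padToSquare <- function(image, fill) {
  H <- nrow(image); W <- ncol(image)
  s <- max(H, W)
  out <- matrix(fill, s, s)
  r0 <- (s - H) %/% 2
  c0 <- (s - W) %/% 2
  out[(r0 + 1):(r0 + H), (c0 + 1):(c0 + W)] <- image
  out
}

resizeBilinear <- function(image, h, w) {
  t(as.array(EBImage::resize(EBImage::Image(t(image)), w = w, h = h)))
}

#' Full pre-processing pipeline
#'
#' Composition: unsupervised segmentation, background removal, connectivity
#' analysis, maximum-area bounding box with margin, crop, histogram
#' equalization, background-level padding to square (preserving aspect
#' ratio) and resize to the configured square input size. With
#' \code{enabled = FALSE} the image passes through untouched except for
#' pad-to-square and the deterministic resize (the "no pre-processing"
#' ablation pathway). Errors are tagged with the failing stage name.
#'
#' @param image 2-D numeric matrix in [0, 1].
#' @param clusterConfig a \code{\link{clusterNetConfig}} for the segmenter.
#' @param size output side length in pixels (model input size).
#' @param margin bounding-box expansion fraction.
#' @param seed seed for the per-image network initialization.
#' @param enabled FALSE for the pass-through ablation.
#' @param saveDir if non-NULL, intermediate artifacts are written there as
#'   \code{<id>.seg.png}, \code{<id>.mask.png}, \code{<id>.bbox.json},
#'   \code{<id>.final.png}.
#' @param id identifier used for intermediate file names.
#' @return list with \code{image} (size x size matrix in [0, 1]) and, when
#'   enabled, \code{labels} (\code{LabelMap}), \code{mask} and \code{bbox}.
#' @export
preprocessPipeline <- function(image, clusterConfig = clusterNetConfig(),
                               size = 224L, margin = 0.02, seed = 1L,
                               enabled = TRUE, saveDir = NULL, id = "image") {
  stopIfNot2dImage(image)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("preprocess stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (!enabled) {
    fill <- stats::median(image[c(1, nrow(image)), ])
    out <- stage("resize", resizeBilinear(padToSquare(image, fill), size, size))
    return(list(image = clamp01(out), labels = NULL, mask = NULL, bbox = NULL))
  }
  labels <- stage("segment", segmentImage(image, clusterConfig, seed = seed))
  mask <- stage("foreground", foregroundMask(labels))
  comps <- stage("components", connectedComponents(mask))
  bbox <- stage("bbox", handBBox(comps, dim(image), margin))
  cropped <- stage("crop", cropImage(image, bbox))
  eq <- stage("equalize", equalizeHist(cropped) / 255)
  # pad with the darkest equalized level: equalization maps the (dark)
  # radiograph background to the bottom of the tone range
  padded <- stage("pad", padToSquare(eq, min(eq)))
  final <- stage("resize", clamp01(resizeBilinear(padded, size, size)))

  if (!is.null(saveDir)) {
    dir.create(saveDir, recursive = TRUE, showWarnings = FALSE)
    wimg <- function(m, f) EBImage::writeImage(EBImage::Image(t(m)), f, type = "png")
    wimg(labels@labels / max(1L, labels@q - 1L), file.path(saveDir, paste0(id, ".seg.png")))
    wimg(mask * 1, file.path(saveDir, paste0(id, ".mask.png")))
    wimg(final, file.path(saveDir, paste0(id, ".final.png")))
    jsonlite::write_json(
      list(rowMin = bbox@rowMin, rowMax = bbox@rowMax,
           colMin = bbox@colMin, colMax = bbox@colMax,
           labelsPresent = sort(unique(as.vector(labels@labels)))),
      file.path(saveDir, paste0(id, ".bbox.json")), auto_unbox = TRUE)
  }
  list(image = final, labels = labels, mask = mask, bbox = bbox)
}

#' Count connected same-label regions of a label map
#'
#' Number of 4-connected (default) components summed over all labels
#' present; used to quantify the spatial-fragmentation pressure of the
#' continuity loss.
#'
#' @param labels a \code{\link{LabelMap}}.
#' @param connectivity 4 or 8.
#' @return integer component count.
#' @export
countLabelComponents <- function(labels, connectivity = 4L) {
  lm <- labels@labels
  total <- 0L
  for (lb in unique(as.vector(lm)))
    total <- total + max(cpp_label_components(lm == lb, as.integer(connectivity)))
  total
}
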