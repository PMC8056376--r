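# Synthetic hand-radiograph generator.
#
# Every downstream stage (localization, preprocessing, regression) is
# exercised on these seeded scenes: a single bright connected hand-like blob
# of maximal area on a darker noisy background, with optional small bright
# distractor blobs, per-record gender and a gender-dependent bone-age label.

#' Tight bounding box of a binary mask
#'
#' @param mask logical matrix.
#' @return a \code{\link{BoundingBox}} (0-based, half-open) covering all
#'   TRUE pixels.
#' @export
maskBBox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (!length(rows)) stop("mask has no foreground pixels")
  BoundingBox(min(rows) - 1L, max(rows), min(cols) - 1L, max(cols))
}

# Hand-shaped mask: ellipse palm + finger ellipses, rotated by `angle`
# (radians) about `center`. All sizes scale with S (hand size in pixels).
handMask <- function(H, W, center, S, nFingers, angle, lenJitter) {
  r <- matrix(seq_len(H), H, W) - center[1]
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  u <- cos(angle) * r + sin(angle) * c
  v <- -sin(angle) * r + cos(angle) * c
  # palm, slightly below hand center
  mask <- ((u - 0.12 * S) / (0.30 * S))^2 + (v / (0.24 * S))^2 <= 1
  # knuckle band joining the finger bases to the palm top
  mask <- mask | ((u + 0.16 * S) / (0.09 * S))^2 + (v / (0.30 * S))^2 <= 1
  if (nFingers > 0) {
    vk <- if (nFingers == 1) 0 else seq(-0.26 * S, 0.26 * S, length.out = nFingers)
    for (k in seq_len(nFingers)) {
      fl <- (0.17 + 0.07 * lenJitter[k]) * S          # finger semi-length
      fw <- max(0.045 * S, 1.6)                       # finger semi-width
      uk <- -0.18 * S - fl * 0.75
      mask <- mask | (((u - uk) / fl)^2 + ((v - vk[k]) / fw)^2 <= 1)
    }
  }
  mask
}

#' Render one synthetic radiograph scene
#'
#' Deterministic for a fixed \code{seed}: two calls with the same spec yield
#' bit-identical images. The rendered hand is a single 8-connected component
#' and is strictly larger than every distractor blob; a hand that would
#' touch or leave the frame rejects the spec with an error.
#'
#' @param spec a \code{\link{SceneSpec}}.
#' @return list with elements \code{image} (H x W numeric matrix in [0, 1]),
#'   \code{id} (NA; assigned by \code{\link{generateDataset}}), \code{mask}
#'   (logical ground-truth hand mask) and \code{bbox} (ground-truth
#'   \code{BoundingBox}).
#' @export
renderScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  H <- spec@imageHeight
  W <- spec@imageWidth
  S <- spec@handScale * min(H, W)
  withSeed(spec@seed, {
    if (spec@handShape == "rect") {
      side <- round(S)
      r0 <- round(spec@handCenter[1] - side / 2)
      c0 <- round(spec@handCenter[2] - side / 2)
      if (r0 < 1 || c0 < 1 || r0 + side - 1 > H || c0 + side - 1 > W)
        stop("hand extends outside the frame; shrink handScale or recenter")
      mask <- matrix(FALSE, H, W)
      mask[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- TRUE
    } else {
      angle <- stats::runif(1, -25, 25) * pi / 180
      lenJitter <- stats::runif(max(spec@nFingers, 1))
      mask <- handMask(H, W, spec@handCenter, S, spec@nFingers, angle, lenJitter)
      if (any(mask[1, ]) || any(mask[H, ]) || any(mask[, 1]) || any(mask[, W]))
        stop("hand extends outside the frame; shrink handScale or recenter")
      lab <- cpp_label_components(mask, 8L)
      if (max(lab) != 1L)
        stop("rendered hand is not a single connected component; adjust spec")
    }
    handArea <- sum(mask)

    img <- matrix(spec@backgroundLevel, H, W)
    img[mask] <- spec@foregroundLevel

    # distractors: small bright discs, disjoint from the (dilated) hand and
    # from each other, each with area well below the hand's
    if (spec@nDistractors > 0) {
      occupied <- mask
      rmax <- max(2, min(0.04 * min(H, W), sqrt(handArea / (8 * pi))))
      rr <- matrix(seq_len(H), H, W)
      cc <- matrix(seq_len(W), H, W, byrow = TRUE)
      placed <- 0L
      tries <- 0L
      while (placed < spec@nDistractors && tries < 200L) {
        tries <- tries + 1L
        rad <- stats::runif(1, 2, rmax)
        ctr <- c(stats::runif(1, rad + 2, H - rad - 1),
                 stats::runif(1, rad + 2, W - rad - 1))
        disc <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2
        # 2-px clearance keeps components separate under 8-connectivity
        near <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= (rad + 3)^2
        if (any(occupied & near)) next
        img[disc] <- spec@foregroundLevel
        occupied <- occupied | disc
        placed <- placed + 1L
      }
    }

    if (spec@noiseSd > 0)
      img <- img + matrix(stats::rnorm(H * W, sd = spec@noiseSd), H, W)
    img <- clamp01(img)

    list(image = img, id = NA_character_, mask = mask, bbox = maskBBox(mask))
  })
}

#' Gender-dependent bone-age distribution
#'
#' Truncated normal per gender; the mean shift between genders makes the
#' gender flag carry signal for the regressor.
#'
#' @param meanMale,meanFemale mean bone age in months per gender.
#' @param sd common standard deviation, months.
#' @param lower,upper truncation bounds, months.
#' @return parameter list consumed by \code{\link{generateDataset}}.
#' @export
ageModel <- function(meanMale = 132, meanFemale = 120, sd = 30,
                     lower = 0, upper = 240) {
  stopifnot(sd > 0, lower < upper)
  list(meanMale = meanMale, meanFemale = meanFemale, sd = sd,
       lower = lower, upper = upper)
}

#' Draw bone ages from the gender-dependent age model
#'
#' @param male logical vector.
#' @param model an \code{\link{ageModel}} parameter list.
#' @return numeric months, same length as \code{male}.
#' @export
sampleBoneAges <- function(male, model = ageModel()) {
  mu <- ifelse(male, model$meanMale, model$meanFemale)
  rtruncnorm(length(male), mu, model$sd, model$lower, model$upper)
}

#' Generate a seeded synthetic radiograph dataset
#'
#' @param n number of records (>= 1).
#' @param genderRatio fraction of male records in expectation; 1 yields all
#'   male, 0 all female.
#' @param model an \code{\link{ageModel}}.
#' @param seed master seed; per-record render seeds derive from it.
#' @param imageSize either a single integer (all frames square of that side)
#'   or a length-2 range from which each frame's side is drawn, emulating the
#'   varying resolutions of real archives.
#' @param nDistractors,noiseSd,handScale scene parameters passed to
#'   \code{\link{SceneSpec}}; \code{handScale} may be a length-2 range.
#' @return a \code{\link{RadiographSet}} with ground-truth masks and boxes.
#' @export
generateDataset <- function(n, genderRatio = 0.5, model = ageModel(),
                            seed = 1L, imageSize = c(112L, 160L),
                            nDistractors = 2L, noiseSd = 0.05,
                            handScale = c(0.5, 0.62)) {
  if (n < 1) stop("n must be at least 1")
  if (genderRatio < 0 || genderRatio > 1) stop("genderRatio must be in [0, 1]")
  withSeed(seed, {
    male <- stats::runif(n) < genderRatio
    ages <- sampleBoneAges(male, model)
    sides <- if (length(imageSize) == 1) rep(as.integer(imageSize), n)
             else sample(seq(imageSize[1], imageSize[2]), n, replace = TRUE)
    scales <- if (length(handScale) == 1) rep(handScale, n)
              else stats::runif(n, handScale[1], handScale[2])
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    centerJitter <- matrix(stats::runif(2 * n, -0.04, 0.04), n, 2)

    images <- vector("list", n)
    masks <- vector("list", n)
    bboxes <- vector("list", n)
    for (i in seq_len(n)) {
      side <- sides[i]
      spec <- SceneSpec(imageHeight = side, imageWidth = side,
                        handCenter = side / 2 + centerJitter[i, ] * side,
                        handScale = scales[i], nFingers = 5L,
                        noiseSd = noiseSd, nDistractors = nDistractors,
                        seed = seeds[i])
      sc <- renderScene(spec)
      images[[i]] <- sc$image
      masks[[i]] <- sc$mask
      bboxes[[i]] <- sc$bbox
    }
    meta <- data.frame(id = sprintf("S%05d", seq_len(n)),
                       boneage = ages, male = male,
                       stringsAsFactors = FALSE)
    new("RadiographSet", images = images, meta = meta,
        masks = masks, bboxes = bboxes)
  })
}

#' Write a radiograph set to disk (PNG images + RSNA-style CSV)
#'
#' Images are quantized to 8-bit PNG; the metadata CSV has the header
#' \code{id,boneage,male} with \code{male} written as \code{True}/\code{False}.
#'
#' @param set a \code{\link{RadiographSet}}.
#' @param dir output directory (created if missing).
#' @param csv metadata file name within \code{dir}.
#' @return invisibly, the CSV path.
#' @export
writeRadiographSet <- function(set, dir, csv = "metadata.csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- recordMeta(set)
  for (i in seq_along(set@images)) {
    img <- round(set@images[[i]] * 255) / 255
    EBImage::writeImage(EBImage::Image(t(img)),
                        file.path(dir, paste0(meta$id[i], ".png")), type = "png")
  }
  out <- meta
  out$male <- ifelse(out$male, "True", "False")
  path <- file.path(dir, csv)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
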