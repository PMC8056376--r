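# Pre-processing: background removal, connectivity analysis, crop,
# histogram equalization, pipeline composition.

test_that("foreground mask removes border-dominant labels", {
  lab <- matrix(0L, 10, 10)
  lab[4:7, 4:7] <- 3L
  lm <- LabelMap(lab, 8L)
  mask <- foregroundMask(lm)
  expect_identical(mask, lab == 3L)
  # a background split across two border-heavy labels is removed entirely
  lab2 <- matrix(0L, 12, 12)
  lab2[, 7:12] <- 5L
  lab2[5:8, 5:8] <- 3L # interior blob
  m2 <- foregroundMask(LabelMap(lab2, 8L))
  expect_identical(m2, lab2 == 3L)
  # a label with a negligible border presence stays foreground
  lab3 <- matrix(0L, 20, 20)
  lab3[10:15, 10:15] <- 2L
  lab3[1, 10] <- 2L # single stray border pixel (< 5% of the border)
  m3 <- foregroundMask(LabelMap(lab3, 8L))
  expect_identical(m3, lab3 == 2L)
  expect_error(foregroundMask(LabelMap(matrix(2L, 5, 5), 8L)),
               "no foreground separable")
  # all labels border-dominant -> nothing separable
  lab4 <- matrix(0L, 10, 10); lab4[, 6:10] <- 1L
  expect_error(foregroundMask(LabelMap(lab4, 4L)), "no foreground separable")
})

test_that("connected components are 8-connected, summarized and area-sorted", {
  mask <- matrix(FALSE, 12, 12)
  mask[2:4, 2:4] <- TRUE  # area 9
  mask[8:9, 8:9] <- TRUE  # area 4
  cc <- connectedComponents(mask)
  expect_equal(nrow(cc), 2L)
  expect_equal(cc$area, c(9L, 4L))
  expect_equal(cc$rowMin[1], 1L)
  expect_equal(cc$rowMax[1], 4L)
  full <- connectedComponents(matrix(TRUE, 5, 7))
  expect_equal(nrow(full), 1L)
  expect_equal(c(full$rowMin, full$rowMax, full$colMin, full$colMax),
               c(0L, 5L, 0L, 7L))
  expect_true(full$touchesBorder)
  expect_equal(nrow(connectedComponents(matrix(FALSE, 3, 3))), 0L)
  # diagonal touch merges under 8-connectivity
  diagm <- matrix(FALSE, 4, 4); diagm[1, 1] <- diagm[2, 2] <- TRUE
  expect_equal(nrow(connectedComponents(diagm)), 1L)
  expect_equal(nrow(connectedComponents(diagm, connectivity = 4L)), 2L)
})

test_that("component analysis agrees with a flood-fill oracle on random masks", {
  set.seed(123)
  for (i in 1:40) {
    mask <- matrix(runif(24 * 24) < 0.35, 24, 24)
    cc <- connectedComponents(mask)
    lab <- oracleFloodFill(mask, 8L)
    k <- max(lab)
    expect_equal(nrow(cc), k)
    if (k == 0) next
    areas <- tabulate(lab[lab > 0])
    expect_equal(cc$area, sort(areas, decreasing = TRUE))
    # bbox of the largest component against the oracle labeling
    bigIdx <- which(lab == which.max(areas))
    rows <- range(((bigIdx - 1L) %% 24L) + 1L)
    cols <- range(((bigIdx - 1L) %/% 24L) + 1L)
    expect_equal(c(cc$rowMin[1], cc$rowMax[1], cc$colMin[1], cc$colMax[1]),
                 c(rows[1] - 1L, rows[2], cols[1] - 1L, cols[2]))
  }
})

test_that("hand bounding box applies the maximum-area rule with margin", {
  comps <- data.frame(label = 1:3, area = c(900L, 50L, 50L),
                      rowMin = c(10L, 0L, 60L), rowMax = c(50L, 5L, 70L),
                      colMin = c(20L, 90L, 0L), colMax = c(60L, 99L, 8L),
                      touchesBorder = FALSE)
  # margin 0: identity on the top component
  bb0 <- handBBox(comps, c(100L, 100L), margin = 0)
  expect_equal(c(bb0@rowMin, bb0@rowMax, bb0@colMin, bb0@colMax),
               c(10L, 50L, 20L, 60L))
  # margin 2% on a 100x100 frame expands by 2 px per side
  bb2 <- handBBox(comps, c(100L, 100L), margin = 0.02)
  expect_equal(c(bb2@rowMin, bb2@rowMax, bb2@colMin, bb2@colMax),
               c(8L, 52L, 18L, 62L))
  # containment of the selected component
  expect_true(bb2@rowMin <= comps$rowMin[1] && bb2@rowMax >= comps$rowMax[1])
  expect_error(handBBox(comps[0, ], c(100L, 100L)), "no hand found")
})

test_that("crop is exact and round-trips", {
  img <- matrix(seq_len(30) / 30, 5, 6)
  expect_identical(cropImage(img, BoundingBox(0, 5, 0, 6)), img)
  expect_equal(cropImage(img, BoundingBox(2, 3, 4, 5)),
               img[3, 5, drop = FALSE])
  bb <- BoundingBox(1, 4, 2, 5)
  sub <- cropImage(img, bb)
  back <- img
  back[2:4, 3:5] <- sub
  expect_identical(back, img)
  expect_error(cropImage(img, BoundingBox(0, 6, 0, 6)), "outside")
})

test_that("histogram equalization applies the CDF mapping", {
  # two-level image: 25% at level 10, 75% at level 200 (N = 400)
  img <- matrix(200 / 255, 20, 20)
  img[1:5, ] <- 10 / 255
  eq <- equalizeHist(img)
  # cdf(10) = 100 = cdfmin -> 0; cdf(200) = 400 -> round(255*300/300) = 255
  expect_setequal(unique(as.vector(eq)), c(0, 255))
  expect_true(all(eq[1:5, ] == 0))
  # an image with a perfectly uniform histogram maps to itself
  ramp <- matrix(0:255 / 255, 16, 16)
  expect_equal(equalizeHist(ramp), matrix(0:255, 16, 16))
  # range and shape contract
  r <- equalizeHist(matrix(runif(35), 5, 7))
  expect_equal(dim(r), c(5L, 7L))
  expect_true(min(r) >= 0 && max(r) <= 255)
  # constant image passes through the identity map
  expect_equal(unique(as.vector(equalizeHist(matrix(0.5, 4, 4)))), 128)
})

test_that("pipeline output is square, sized, and shape-idempotent", {
  img <- matrix(runif(60 * 80, 0, 0.3), 60, 80)
  res <- preprocessPipeline(img, size = 64L, enabled = FALSE)
  expect_equal(dim(res$image), c(64L, 64L))
  res2 <- preprocessPipeline(res$image, size = 64L, enabled = FALSE)
  expect_equal(dim(res2$image), c(64L, 64L))
  expect_true(all(res$image >= 0 & res$image <= 1))
})

test_that("pipeline localizes a noise-free synthetic hand", {
  spec <- SceneSpec(imageHeight = 64L, imageWidth = 64L, handScale = 0.5,
                    noiseSd = 0, nDistractors = 1L, seed = 21L)
  sc <- renderScene(spec)
  cfg <- clusterNetConfig(p = 8L, q = 8L, nIterations = 30L)
  res <- preprocessPipeline(sc$image, cfg, size = 64L, seed = 4L)
  expect_equal(dim(res$image), c(64L, 64L))
  # the final crop contains the entire ground-truth hand box
  expect_lte(res$bbox@rowMin, sc$bbox@rowMin)
  expect_gte(res$bbox@rowMax, sc$bbox@rowMax)
  expect_lte(res$bbox@colMin, sc$bbox@colMin)
  expect_gte(res$bbox@colMax, sc$bbox@colMax)
  # mask covers most of the ground-truth hand
  expect_gte(sum(res$mask & sc$mask) / sum(sc$mask), 0.8)
})

test_that("pipeline errors are tagged with the failing stage", {
  flat <- matrix(0.5, 40, 40) # constant image: nothing separable
  err <- tryCatch(
    preprocessPipeline(flat, clusterNetConfig(p = 4L, q = 4L, nIterations = 2L),
                       size = 32L, seed = 1L),
    error = conditionMessage)
  expect_match(err, "preprocess stage '(foreground|segment)'")
})

test_that("intermediate artifacts are written on request", {
  spec <- SceneSpec(imageHeight = 48L, imageWidth = 48L, noiseSd = 0,
                    nDistractors = 0L, seed = 2L)
  sc <- renderScene(spec)
  dir <- withr::local_tempdir()
  preprocessPipeline(sc$image, clusterNetConfig(p = 6L, q = 6L, nIterations = 10L),
                     size = 48L, seed = 2L, saveDir = dir, id = "t1")
  expect_true(all(file.exists(file.path(
    dir, c("t1.seg.png", "t1.mask.png", "t1.bbox.json", "t1.final.png")))))
  bb <- jsonlite::fromJSON(file.path(dir, "t1.bbox.json"))
  expect_true(bb$rowMax > bb$rowMin)
})
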