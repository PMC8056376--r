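# Unsupervised localization: response maps, argmax labels, the similarity /
# continuity losses against literal oracles, and per-image optimization.

test_that("forward responses have the contracted shape and finiteness", {
  cfg <- clusterNetConfig(p = 8L, q = 8L)
  net <- buildClusterNet(cfg, seed = 1L)
  img <- matrix(runif(16 * 16), 16, 16)
  resp <- forwardResponses(img, net)
  expect_equal(dim(resp), c(16L, 16L, 8L))
  expect_true(all(is.finite(resp)))
  expect_error(forwardResponses(matrix(c(0, Inf), 1, 2), net), "finite")
})

test_that("a constant image yields identical response vectors at every pixel", {
  cfg <- clusterNetConfig(p = 6L, q = 4L)
  net <- buildClusterNet(cfg, seed = 2L)
  resp <- forwardResponses(matrix(0, 12, 12), net)
  for (i in seq_len(4))
    expect_lt(diff(range(resp[, , i])), 1e-9)
})

test_that("argmax labeling matches exhaustive search and breaks ties low", {
  expect_equal(assignLabels(array(c(0.1, 0.9, 0.3), c(1, 1, 3)))@labels[1, 1], 1L)
  expect_equal(assignLabels(array(c(0.5, 0.5), c(1, 1, 2)))@labels[1, 1], 0L)
  set.seed(11)
  resp <- randomResponses(6, 6, 5)
  lm <- assignLabels(resp)
  for (r in 1:6) for (c in 1:6) {
    v <- resp[r, c, ]
    expect_identical(lm@labels[r, c], which(v == max(v))[1] - 1L)
  }
  expect_true(nLabels(lm) >= 1 && nLabels(lm) <= 5)
})

test_that("similarity loss matches its closed forms and the literal oracle", {
  # one-hot probabilities at the assigned label -> loss 0
  onehot <- array(0, c(3, 3, 4))
  lab <- matrix(c(0:3, 0:3, 0L), 3, 3)
  for (r in 1:3) for (c in 1:3) onehot[r, c, lab[r, c] + 1] <- 1
  lm <- LabelMap(lab, 4L)
  expect_equal(similarityLoss(onehot, lm, probabilities = TRUE), 0, tolerance = 1e-9)
  # uniform probabilities -> N * ln(q)
  unif <- array(1 / 4, c(5, 7, 4))
  lmu <- assignLabels(unif)
  expect_equal(similarityLoss(unif, lmu, probabilities = TRUE),
               35 * log(4), tolerance = 1e-9)
  # random map via softmax matches the double-loop oracle
  set.seed(21)
  resp <- randomResponses(5, 5, 4)
  lmr <- assignLabels(resp)
  expect_equal(similarityLoss(resp, lmr),
               oracleSimilarity(oracleSoftmax(resp), lmr@labels),
               tolerance = 1e-9)
})

test_that("continuity loss follows the printed index ranges", {
  expect_equal(continuityLoss(array(3.7, c(4, 5, 2))), 0)
  # hand-enumerated 2x2 example: only (xi=1, eta=1) enters the double sum
  resp <- array(0, c(2, 2, 1))
  resp[1, 1, 1] <- 0; resp[1, 2, 1] <- 1 # right neighbor
  resp[2, 1, 1] <- 3; resp[2, 2, 1] <- 7 # down neighbor
  expect_equal(continuityLoss(resp), 4)
  set.seed(31)
  r2 <- randomResponses(6, 6, 3)
  expect_equal(continuityLoss(r2), oracleContinuity(r2), tolerance = 1e-6)
  expect_error(continuityLoss(array(1, c(1, 5, 2))), "H >= 2")
})

test_that("losses match literal oracles on many random maps and stay non-negative", {
  set.seed(77)
  for (i in 1:25) {
    H <- sample(3:7, 1); W <- sample(3:7, 1); q <- sample(2:5, 1)
    resp <- randomResponses(H, W, q)
    lm <- assignLabels(resp)
    sim <- similarityLoss(resp, lm)
    con <- continuityLoss(resp)
    expect_equal(sim, oracleSimilarity(oracleSoftmax(resp), lm@labels),
                 tolerance = 1e-6 * max(1, sim))
    expect_equal(con, oracleContinuity(resp), tolerance = 1e-6 * max(1, con))
    expect_gte(sim, 0)
    expect_gte(con, 0)
    lam <- runif(1, 0, 5); mu <- runif(1, 0, 5)
    expect_equal(totalLoss(resp, lm, lam, mu), lam * sim + mu * con,
                 tolerance = 1e-9)
    expect_gte(totalLoss(resp, lm, lam, mu), 0)
  }
})

test_that("total loss degenerates correctly at zero weights", {
  set.seed(5)
  resp <- randomResponses(4, 4, 3)
  lm <- assignLabels(resp)
  expect_equal(totalLoss(resp, lm, lambda = 0, mu = 2),
               2 * continuityLoss(resp))
  onehot <- array(0, c(2, 2, 3)); onehot[, , 2] <- 1
  lmo <- assignLabels(onehot)
  expect_equal(totalLoss(onehot, lmo, lambda = 4, mu = 0, probabilities = TRUE),
               0, tolerance = 1e-9)
  expect_error(totalLoss(resp, lm, lambda = -1), "non-negative")
})

test_that("segmentImage separates a two-region image and is reproducible", {
  img <- twoRegionImage(32L)
  cfg <- clusterNetConfig(p = 8L, q = 8L, nIterations = 50L)
  lm <- segmentImage(img, cfg, seed = 9L)
  expect_s4_class(lm, "LabelMap")
  expect_equal(dim(lm@labels), c(32L, 32L))
  k <- nLabels(lm)
  expect_true(k >= 2 && k <= 8)
  modal <- function(x) as.integer(names(sort(table(x), decreasing = TRUE))[1])
  inside <- lm@labels[img > 0.5]
  outside <- lm@labels[img <= 0.5]
  expect_false(modal(inside) == modal(outside))
  # seeded determinism
  expect_identical(lm@labels, segmentImage(img, cfg, seed = 9L)@labels)
  # a single iteration returns the argmax of the once-updated network
  lm1 <- segmentImage(img, clusterNetConfig(p = 8L, q = 8L, nIterations = 1L),
                      seed = 9L)
  expect_true(nLabels(lm1) >= 1 && nLabels(lm1) <= 8)
})

test_that("stronger continuity pressure does not fragment the label map", {
  img <- twoRegionImage(32L)
  counts <- vapply(c(0.2, 1, 5), function(mu) {
    lm <- segmentImage(img, clusterNetConfig(p = 8L, q = 8L, muCon = mu),
                       seed = 13L)
    countLabelComponents(lm, 4L)
  }, 1L)
  # monotone non-increasing trend, tolerating one violation
  expect_lte(sum(diff(counts) > 0), 1)
})

test_that("large images are clustered at the working size and upscaled back", {
  img <- twoRegionImage(96L)
  cfg <- clusterNetConfig(p = 6L, q = 6L, nIterations = 5L, workingSize = 48L)
  lm <- segmentImage(img, cfg, seed = 3L)
  expect_equal(dim(lm@labels), c(96L, 96L))
})
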