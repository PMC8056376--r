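# Training protocol: standardization, MSE, splits, learning-rate schedule,
# augmentation, ablation contracts, and a micro training run.

test_that("age standardization is exact and invertible", {
  s <- AgeStandardizer(120, 40)
  expect_equal(standardizeAge(120, s), 0)
  expect_equal(standardizeAge(160, s), 1)
  set.seed(61)
  y <- runif(1000, 0, 240)
  expect_equal(destandardizeAge(standardizeAge(y, s), s), y, tolerance = 1e-12)
  expect_error(AgeStandardizer(120, 0), "sigma")
  fit <- fitAgeStandardizer(c(100, 120, 140))
  expect_equal(fit@mu, 120)
  expect_equal(fit@sigma, 20)
})

test_that("mse matches its closed forms and a summation oracle", {
  expect_equal(mseLoss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mseLoss(c(1, 3), c(0, 0)), 5)
  set.seed(62)
  p <- rnorm(100); t <- rnorm(100)
  acc <- 0
  for (i in 1:100) acc <- acc + (p[i] - t[i])^2
  expect_equal(mseLoss(p, t), acc / 100, tolerance = 1e-10)
  expect_error(mseLoss(1:3, 1:2), "equal length")
})

test_that("the 7:2:1 split partitions records", {
  sp <- splitDataset(100, splitSpec(seed = 5L))
  expect_equal(lengths(sp), c(train = 70L, val = 20L, test = 10L))
  expect_identical(sp, splitDataset(100, splitSpec(seed = 5L)))
  all_idx <- sort(c(sp$train, sp$val, sp$test))
  expect_identical(all_idx, 1:100)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_error(splitDataset(9), "at least 10")
})

test_that("the learning rate decays tenfold every 30 epochs", {
  expect_equal(lrSchedule(29, 0.01), 0.01)
  expect_equal(lrSchedule(30, 0.01), 0.001)
  expect_equal(lrSchedule(60, 0.01), 0.0001)
  epochs <- 0:159
  expect_equal(lrSchedule(epochs, 0.01), 0.01 * 10^(-(epochs %/% 30)))
})

test_that("augmentation is identity when disabled and bounded when enabled", {
  img <- matrix(runif(48 * 48), 48, 48)
  expect_identical(augmentImage(img, augmentConfig(enabled = FALSE)), img)
  set.seed(63)
  out <- augmentImage(img, augmentConfig())
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("gender ablation controls sensitivity to the gender flag", {
  img <- matrix(runif(32 * 32), 32, 32)
  withG <- buildBoneAgeModel(inputSize = 32L, useGender = TRUE, seed = 3L)
  withG@standardizer <- AgeStandardizer(120, 30)
  p0 <- predictAge(withG, img, male = 0)
  p1 <- predictAge(withG, img, male = 1)
  expect_false(isTRUE(all.equal(p0, p1)))
  noG <- buildBoneAgeModel(inputSize = 32L, useGender = FALSE, seed = 3L)
  noG@standardizer <- AgeStandardizer(120, 30)
  expect_identical(predictAge(noG, img, male = 0), predictAge(noG, img, male = 1))
})

test_that("a micro training run keeps its books in order", {
  set <- generateDataset(6, seed = 8L, imageSize = 48L, nDistractors = 0L)
  cfg <- trainConfig(batchSize = 3L, epochs = 3L, baseLr = 0.005,
                     inputSize = 48L, usePreprocess = FALSE, seed = 4L,
                     augment = augmentConfig(enabled = FALSE))
  fit <- trainModel(set, cfg, split = list(train = 1:4, val = 5:6))
  h <- fit$history
  expect_equal(nrow(h), 3L)
  expect_equal(h$lr, lrSchedule(0:2, 0.005))
  expect_true(all(is.finite(h$trainMSE)))
  expect_true(all(is.finite(h$valMAE)))
  # standardizer fitted on the training split only
  expect_equal(fit$model@standardizer@mu, mean(boneAge(set)[1:4]))
  expect_equal(fit$model@standardizer@sigma, sd(boneAge(set)[1:4]))
  # the retained checkpoint reproduces the best validation MAE
  expect_equal(evaluateMAE(fit$model, set, 5:6), min(h$valMAE),
               tolerance = 1e-8)
  # training is reproducible under the same seed
  fit2 <- trainModel(set, cfg, split = list(train = 1:4, val = 5:6))
  expect_equal(fit$history$trainMSE, fit2$history$trainMSE, tolerance = 1e-12)
})

test_that("evaluateMAE averages month-scale errors and ignores record order", {
  set <- generateDataset(5, seed = 9L, imageSize = 32L, nDistractors = 0L)
  model <- buildBoneAgeModel(inputSize = 32L, seed = 5L)
  model@standardizer <- AgeStandardizer(mean(boneAge(set)), sd(boneAge(set)))
  mae <- evaluateMAE(model, set)
  preds <- predictAge(model, images(set), male = isMale(set))
  expect_equal(mae, mean(abs(preds - boneAge(set))), tolerance = 1e-10)
  expect_equal(mae, mean(vapply(sample(5), function(i)
    abs(predictAge(model, images(set)[[i]], male = isMale(set)[i]) -
        boneAge(set)[i]), 1)), tolerance = 1e-8)
  expect_error(evaluateMAE(model, set, integer(0)), "empty")
})
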