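# BoneAgeNet

Computer-aided **bone age assessment** from pediatric hand-wrist
radiographs, for image-analysis researchers and engineers who need a fully
testable, annotation-free pipeline: bone age (in months) is a standard
measure of skeletal maturity, and reading it from radiographs by hand is
slow and subjective. `BoneAgeNet` implements the three stages of an
automated reading as a single R package:

1. **Unsupervised hand localization.** A small CNN is optimized *on each
   target image individually*: per-pixel responses
   $y_n \in \mathbb{R}^q$ are clustered by their argmax
   $c_n = \arg\max_i y_{n,i}$ while minimizing
   $L = \lambda L_{\mathrm{sim}} + \mu L_{\mathrm{con}}$ with
   $L_{\mathrm{sim}} = \sum_n -\log\,\mathrm{softmax}(y_n)_{c_n}$
   (feature similarity) and
   $L_{\mathrm{con}} = \sum_{\xi=1}^{W-1}\sum_{\eta=1}^{H-1}
   \lVert y_{\xi+1,\eta}-y_{\xi,\eta}\rVert_1 +
   \lVert y_{\xi,\eta+1}-y_{\xi,\eta}\rVert_1$ (spatial continuity),
   defaults $\lambda = 4$, $\mu = 1$, 50 SGD iterations (momentum 0.9,
   lr 0.1), $p = q = 90$ channels. No labels of any kind are used.
2. **Pre-processing.** Background removal from the label map (border-based),
   8-connected component analysis, maximum-area crop with a 2% margin,
   global histogram equalization, pad-to-square and resize.
3. **Gender-embedded regression.** A MobileNetV3-style backbone maps the
   image to a 1280-dim feature; the binary gender flag passes through a
   rectified 24-dim embedding; the concatenated 1304-dim vector feeds a
   one-hidden-layer MLP (1304 neurons, ReLU) that predicts standardized
   bone age $Y' = (Y - \mu)/\sigma$, trained with SGD + momentum on mean
   squared error (batch 10, lr /10 every 30 epochs) and evaluated as MAE in
   months.

Clinical archives are private, so the package ships a seeded
synthetic-radiograph generator (bright connected hand-shaped blob,
distractors, noise, gender-dependent bone-age labels, RSNA-style
`id,boneage,male` metadata) that gives every stage ground truth to test
against. The whole neural-network engine (convolutions via compiled
im2col + BLAS kernels, batch norm, squeeze-and-excitation,
backpropagation, SGD) is implemented in the package; no deep-learning
framework is required.

## Worked example

```r
library(BoneAgeNet)

radiographs <- generateDataset(20, seed = 7L, imageSize = 128L)
radiographs
#> RadiographSet with 20 record(s)
#>   sizes: 128x128
#>   bone age: 75-213 months; male: 14/20
#>   ground truth: masks + boxes

# localize the hand on the first image and compare with ground truth
cfg <- clusterNetConfig(p = 32L, q = 32L)
res <- preprocessPipeline(images(radiographs)[[1]], cfg, size = 224L, seed = 8L)
res$bbox
#> BoundingBox rows [17,96) x cols [37,92)  (79 x 55 px)
bboxIoU(res$bbox, handBoxes(radiographs)[[1]])
#> [1] 0.805
```

The localizer found the hand with a box overlapping the ground-truth box at
IoU 0.81 — entirely without annotations. A short desk-scale training run
(14 training images, 30 epochs at 64 px, no augmentation) then looks like:

```r
tc <- trainConfig(batchSize = 10L, epochs = 30L, inputSize = 64L,
                  usePreprocess = FALSE, seed = 1L,
                  augment = augmentConfig(enabled = FALSE))
split <- splitDataset(length(radiographs), splitSpec(seed = 1L))
fit <- trainModel(radiographs, tc, split = split)
tail(fit$history, 3)
#>    epoch   lr  trainMSE   valMSE    valMAE
#> 28    28 0.01 0.3126407 21.82154 117.62291
#> 29    29 0.01 0.1937252 16.28436  84.61601
#> 30    30 0.01 0.3689925 13.99902  76.79392
evaluateMAE(fit$model, radiographs, split$test)
#> [1] 26.7
predictAge(fit$model, images(radiographs)[[3]], male = isMale(radiographs)[3])
#> [1] 156.4
```

Training MSE (standardized units) collapses while the 4-record validation
split stays noisy — exactly what overfitting 14 synthetic images must look
like; the retained best-validation checkpoint gives a 26.7-month test MAE
and a month-scale prediction for a single image. These numbers demonstrate
pipeline mechanics, not clinical accuracy: month-scale clinical MAE requires
the real 12,611-image archive and GPU-scale training, which is out of scope
here.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/scripts/boneage generate --out runs/demo --seed 1
Rscript inst/scripts/boneage all --config run.yaml
Rscript inst/scripts/boneage predict --image hand.png --male --out runs/demo
```

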