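# Run configuration and the umbrella pipeline driver behind the command
# line interface (inst/scripts/boneage).

#' Default run configuration
#'
#' Nested configuration for all stages; serialize with
#' \code{\link{writeRunConfig}} / \code{\link{loadRunConfig}} (YAML).
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    paths = list(dataDir = "data", csv = "metadata.csv", outDir = "out"),
    generate = list(n = 20L, genderRatio = 0.5, imageSize = c(112L, 160L),
                    noiseSd = 0.05, nDistractors = 2L,
                    meanMale = 132, meanFemale = 120, sdAge = 30),
    cluster = list(p = 90L, q = 90L, nIterations = 50L, lr = 0.1,
                   momentum = 0.9, lambda = 4, mu = 1, workingSize = 256L),
    preprocess = list(size = 224L, margin = 0.02, saveIntermediates = FALSE),
    train = list(batchSize = 10L, epochs = 160L, baseLr = 0.01,
                 lrDecayFactor = 10, lrDecayEvery = 30L, momentum = 0.9,
                 inputSize = 224L, useGender = TRUE, usePreprocess = TRUE,
                 usePretrained = FALSE, augment = TRUE,
                 pretrainedWeights = NULL),
    predict = list(image = NULL, male = NULL, checkpoint = "model.rds"))
}

checkKeys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      checkKeys(as.list(cfg[[nm]]), ref[[nm]], paste0(path, nm, "$"))
}

#' Load / write a run configuration (YAML)
#'
#' Unknown keys are rejected; missing keys fall back to
#' \code{\link{defaultRunConfig}} values.
#'
#' @param path YAML file path.
#' @return \code{loadRunConfig}: the merged, validated config list.
#' @export
loadRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- defaultRunConfig()
  checkKeys(cfg, ref)
  merge <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge(ref, cfg)
}

#' @rdname loadRunConfig
#' @param config a configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

cfgClusterConfig <- function(cfg) {
  cl <- cfg$cluster
  clusterNetConfig(p = cl$p, q = cl$q, nIterations = cl$nIterations,
                   lr = cl$lr, momentum = cl$momentum, lambdaSim = cl$lambda,
                   muCon = cl$mu, workingSize = cl$workingSize)
}

cfgTrainConfig <- function(cfg) {
  tr <- cfg$train
  trainConfig(batchSize = tr$batchSize, epochs = tr$epochs, baseLr = tr$baseLr,
              lrDecayFactor = tr$lrDecayFactor, lrDecayEvery = tr$lrDecayEvery,
              momentum = tr$momentum, inputSize = tr$inputSize,
              useGender = tr$useGender, usePreprocess = tr$usePreprocess,
              usePretrained = tr$usePretrained, seed = cfg$seed,
              augment = augmentConfig(enabled = isTRUE(tr$augment)))
}

writeProvenance <- function(cfg, outDir, stage) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(stage = stage, seed = cfg$seed,
         package = "BoneAgeNet",
         version = as.character(utils::packageVersion("BoneAgeNet")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = cfg),
    file.path(outDir, paste0("provenance-", stage, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run one pipeline stage (or a chain)
#'
#' Stages: \code{generate} (synthetic dataset to disk), \code{segment}
#' (label maps for every image), \code{preprocess} (cropped equalized
#' images), \code{train}, \code{predict} (one image), \code{evaluate}
#' (MAE in months on the test split), or \code{all}
#' (generate-train-evaluate). Every run writes a provenance record (config
#' snapshot + seed + package version) into the output directory.
#'
#' @param cfg configuration list (see \code{\link{defaultRunConfig}}).
#' @param stage stage name.
#' @return stage-dependent artifact list, invisibly where the side effect is
#'   the point.
#' @export
runPipeline <- function(cfg, stage) {
  stages <- c("generate", "segment", "preprocess", "train", "predict",
              "evaluate", "all")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(stages, collapse = ", "))
  outDir <- cfg$paths$outDir
  writeProvenance(cfg, outDir, stage)

  if (stage == "generate") {
    g <- cfg$generate
    set <- generateDataset(g$n, g$genderRatio,
                           ageModel(g$meanMale, g$meanFemale, g$sdAge),
                           seed = cfg$seed, imageSize = unlist(g$imageSize),
                           nDistractors = g$nDistractors, noiseSd = g$noiseSd)
    writeRadiographSet(set, cfg$paths$dataDir, cfg$paths$csv)
    return(invisible(set))
  }

  manifest <- readManifest(file.path(cfg$paths$dataDir, cfg$paths$csv),
                           cfg$paths$dataDir)
  set <- loadRadiographSet(manifest)
  clc <- cfgClusterConfig(cfg)

  if (stage == "segment") {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(length(set))) {
      lm <- segmentImage(set@images[[i]], clc, seed = cfg$seed + i)
      EBImage::writeImage(EBImage::Image(t(lm@labels) / max(1L, lm@q - 1L)),
                          file.path(outDir, paste0(manifest$id[i], ".seg.png")),
                          type = "png")
      jsonlite::write_json(
        list(id = manifest$id[i], q = lm@q,
             labelsPresent = sort(unique(as.vector(lm@labels)))),
        file.path(outDir, paste0(manifest$id[i], ".labels.json")),
        auto_unbox = TRUE)
    }
    return(invisible(NULL))
  }

  if (stage == "preprocess") {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    pp <- cfg$preprocess
    for (i in seq_len(length(set))) {
      res <- preprocessPipeline(set@images[[i]], clc, size = pp$size,
                                margin = pp$margin, seed = cfg$seed + i,
                                saveDir = if (isTRUE(pp$saveIntermediates)) outDir,
                                id = manifest$id[i])
      EBImage::writeImage(EBImage::Image(t(res$image)),
                          file.path(outDir, paste0(manifest$id[i], ".final.png")),
                          type = "png")
    }
    return(invisible(NULL))
  }

  tc <- cfgTrainConfig(cfg)
  split <- if (length(set) >= 10) splitDataset(length(set), splitSpec(seed = cfg$seed))

  if (stage %in% c("train", "all")) {
    model <- NULL
    if (isTRUE(cfg$train$usePretrained)) {
      if (is.null(cfg$train$pretrainedWeights))
        stop("usePretrained requires train$pretrainedWeights (converted checkpoint path)")
      model <- buildBoneAgeModel(tc@inputSize, tc@useGender, seed = cfg$seed)
      model <- loadBackboneWeights(model, cfg$train$pretrainedWeights)
    }
    fit <- trainModel(set, tc, split = split, clusterConfig = clc, model = model)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    saveModel(fit$model, file.path(outDir, cfg$predict$checkpoint))
    utils::write.csv(fit$history, file.path(outDir, "history.csv"),
                     row.names = FALSE)
    if (stage == "train") return(invisible(fit))
    model <- fit$model
  } else {
    model <- readModel(file.path(outDir, cfg$predict$checkpoint))
  }

  if (stage == "predict") {
    if (is.null(cfg$predict$image)) stop("predict stage needs predict$image")
    img <- asGrayMatrix(EBImage::readImage(cfg$predict$image))
    months <- predictAge(model, img, male = as.numeric(isTRUE(cfg$predict$male)))
    cat(sprintf("predicted bone age: %.1f months\n", months))
    return(invisible(months))
  }

  idx <- if (!is.null(split)) split$test else seq_len(length(set))
  mae <- evaluateMAE(model, set, idx)
  cat(sprintf("test MAE: %.1f months (n = %d)\n", mae, length(idx)))
  invisible(list(mae = mae, n = length(idx)))
}
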