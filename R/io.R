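# Dataset readers/writers and model (de)serialization.

#' Read and validate an RSNA-style dataset manifest
#'
#' The CSV must provide id, bone age (months) and gender columns (default
#' names \code{id,boneage,male}; a column mapping handles variants). Gender
#' parses \code{True}/\code{False} case-insensitively. Every id must resolve
#' to exactly one image file (\code{<id>.png}/\code{.jpg}/\code{.jpeg}) in
#' \code{imageDir}; duplicate ids, unparsable or negative ages and missing
#' images are rejected with per-row messages.
#'
#' @param csvPath path to the metadata CSV.
#' @param imageDir directory holding the images.
#' @param idCol,ageCol,maleCol column-name mapping.
#' @return data.frame with columns \code{id}, \code{boneage} (numeric),
#'   \code{male} (logical) and \code{path}.
#' @export
readManifest <- function(csvPath, imageDir, idCol = "id", ageCol = "boneage",
                         maleCol = "male") {
  if (!file.exists(csvPath)) stop("metadata file not found: ", csvPath)
  if (!dir.exists(imageDir)) stop("image directory not found: ", imageDir)
  raw <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  for (col in c(idCol, ageCol, maleCol))
    if (!col %in% names(raw)) stop("metadata is missing column '", col, "'")

  id <- as.character(raw[[idCol]])
  problems <- character(0)
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    problems <- c(problems, paste0("duplicate id(s): ", paste(dup, collapse = ", ")))

  age <- suppressWarnings(as.numeric(raw[[ageCol]]))
  bad <- which(!is.finite(age) | age < 0)
  if (length(bad))
    problems <- c(problems, sprintf("row %d (id %s): bone age '%s' is not a non-negative number",
                                    bad, id[bad], raw[[ageCol]][bad]))

  maleRaw <- tolower(trimws(as.character(raw[[maleCol]])))
  male <- ifelse(maleRaw %in% c("true", "t", "1"), TRUE,
                 ifelse(maleRaw %in% c("false", "f", "0"), FALSE, NA))
  bad <- which(is.na(male))
  if (length(bad))
    problems <- c(problems, sprintf("row %d (id %s): gender '%s' is not True/False",
                                    bad, id[bad], raw[[maleCol]][bad]))

  path <- vapply(id, function(i) {
    for (ext in c(".png", ".jpg", ".jpeg")) {
      p <- file.path(imageDir, paste0(i, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }, "", USE.NAMES = FALSE)
  bad <- which(is.na(path))
  if (length(bad))
    problems <- c(problems, sprintf("row %d: no image file for id %s", bad, id[bad]))

  if (length(problems))
    stop("invalid manifest:\n  ", paste(problems, collapse = "\n  "))
  data.frame(id = id, boneage = age, male = as.logical(male), path = path,
             stringsAsFactors = FALSE)
}

#' Load a radiograph set from a manifest
#'
#' @param manifest data.frame from \code{\link{readManifest}}.
#' @return a \code{\link{RadiographSet}} (no ground-truth masks).
#' @export
loadRadiographSet <- function(manifest) {
  imgs <- lapply(manifest$path, function(p) asGrayMatrix(EBImage::readImage(p)))
  new("RadiographSet", images = imgs,
      meta = manifest[, c("id", "boneage", "male")],
      masks = list(), bboxes = list())
}

#' Save / load a bone-age model checkpoint
#'
#' Single-file checkpoint with an embedded JSON header recording the
#' backbone block table, input size, gender-embedding width and the age
#' standardizer, alongside the parameter arrays.
#'
#' @param model a \code{\link{BoneAgeModel}}.
#' @param path checkpoint file path.
#' @return \code{saveModel}: invisibly, \code{path}. \code{readModel}: the
#'   restored model.
#' @export
saveModel <- function(model, path) {
  std <- model@standardizer
  header <- jsonlite::toJSON(list(
    package = "BoneAgeNet",
    version = as.character(utils::packageVersion("BoneAgeNet")),
    inputSize = model@inputSize,
    genderEmbeddingWidth = if (model@useGender) 24L else 0L,
    standardizer = if (!is.null(std)) list(mu = std@mu, sigma = std@sigma),
    blockTable = model@arch), auto_unbox = TRUE, digits = NA)
  saveRDS(list(header = header, netParams = model@net$params,
               netState = model@net$state, head = model@head), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
readModel <- function(path) {
  obj <- readRDS(path)
  h <- jsonlite::fromJSON(obj$header)
  model <- buildBoneAgeModel(inputSize = h$inputSize,
                             useGender = h$genderEmbeddingWidth > 0,
                             table = as.data.frame(h$blockTable))
  model@net$params <- obj$netParams
  model@net$state <- obj$netState
  model@head <- obj$head
  if (!is.null(h$standardizer))
    model@standardizer <- AgeStandardizer(h$standardizer$mu, h$standardizer$sigma)
  model
}

#' Load backbone weights from a converted checkpoint
#'
#' Replaces backbone parameters by name from an RDS file holding a named
#' list of arrays (e.g. weights converted from a published ImageNet
#' checkpoint). Shapes must match; unknown names error.
#'
#' @param model a \code{\link{BoneAgeModel}}.
#' @param path RDS file with a named list of parameter arrays.
#' @return the model with replaced weights.
#' @export
loadBackboneWeights <- function(model, path) {
  w <- readRDS(path)
  for (nm in names(w)) {
    if (is.null(model@net$params[[nm]]))
      stop("unknown backbone parameter: ", nm)
    if (!identical(dim(model@net$params[[nm]]), dim(w[[nm]])) &&
        length(model@net$params[[nm]]) != length(w[[nm]]))
      stop("shape mismatch for backbone parameter: ", nm)
    model@net$params[[nm]] <- w[[nm]]
  }
  model
}
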