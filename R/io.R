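#' Read and write single-channel fluorescence TIFFs
#'
#' `readFluorImage()` accepts 8- or 16-bit grayscale TIFF and returns a
#' [FluorImage-class] with native integer intensities. Multi-channel
#' (e.g. RGB) files are rejected unless a `channel` index selects one
#' plane. `writeFluorImage()` writes the image back at its bit depth;
#' the pair round-trips bit-exactly.
#'
#' @param path TIFF file path.
#' @param channel Optional channel index for multi-channel files.
#' @return A [FluorImage-class].
#' @export
readFluorImage <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e) stop("cannot read TIFF '", path, "': ",
                                           conditionMessage(e)))
  if (length(dim(arr)) == 3L) {
    if (is.null(channel)) {
      stop("multi-channel TIFF '", path, "' (", dim(arr)[3],
           " channels): supply a channel index")
    }
    stopifnot(channel >= 1, channel <= dim(arr)[3])
    arr <- arr[, , channel]
  }
  if (length(dim(arr)) != 2L) stop("unsupported TIFF layout in '", path, "'")
  # readTIFF(as.is) returns integers at the file's bit depth
  depth <- as.integer(attr(arr, "bits.per.sample") %||% 16L)
  if (!depth %in% c(8L, 16L)) stop("unsupported bit depth: ", depth)
  FluorImage(matrix(as.numeric(arr), nrow(arr), ncol(arr)),
             bitDepth = depth, source = path)
}

#' @rdname readFluorImage
#' @param image A [FluorImage-class] to write.
#' @export
writeFluorImage <- function(image, path) {
  stopifnot(is(image, "FluorImage"))
  maxv <- 2^bitDepth(image) - 1
  tiff::writeTIFF(pixels(image) / maxv, path,
                  bits.per.sample = bitDepth(image))
  invisible(path)
}

#' Read and validate a run manifest
#'
#' A manifest CSV pairs test and control images per condition, one image
#' per row: columns `condition`, `role` ("test" or "control"),
#' `replicate` (integer index) and `path`. Every condition must have at
#' least one test image; a condition without control rows is processed
#' raw-only with a warning at run time. Paths are resolved relative to the
#' manifest's directory.
#'
#' @param path Manifest CSV path.
#' @param checkPaths Verify that all image files exist (default TRUE).
#' @return A validated data.frame.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "role", "replicate", "path")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty manifest")
  if (!all(df$role %in% c("test", "control"))) {
    stop("manifest role must be 'test' or 'control'")
  }
  noTest <- setdiff(unique(df$condition), df$condition[df$role == "test"])
  if (length(noTest)) {
    stop("condition(s) without a test image: ", paste(noTest, collapse = ", "))
  }
  rel <- !file.exists(df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  if (checkPaths && !all(file.exists(df$path))) {
    stop("missing image file(s): ",
         paste(df$path[!file.exists(df$path)], collapse = ", "))
  }
  df
}

#' Pipeline configuration
#'
#' Bundles the segmentation and rim parameters, the replicate/control
#' ordering, screening thresholds and the seed. `readConfig()` loads the
#' same structure from JSON, rejecting unknown keys so that a typo never
#' silently falls back to a default.
#'
#' @param seg From [segParams()].
#' @param rim From [rimParams()].
#' @param mergeOrder "merge_then_subtract" (default: replicates of test and
#'   control are merged first, then the merged control is subtracted) or
#'   "subtract_then_merge" (pairwise subtraction per replicate, then
#'   merge) - used when replicate controls exist pairwise.
#' @param minBeads,maxClumpFraction QC thresholds (see
#'   [checkBeadDistribution()]).
#' @param highTier,lowTier Screening tier thresholds (see
#'   [classifyScreen()]).
#' @param seed Integer seed recorded for provenance.
#' @param logLevel "info" or "quiet".
#' @return A named list.
#' @export
flipConfig <- function(seg = segParams(), rim = rimParams(),
                       mergeOrder = c("merge_then_subtract",
                                      "subtract_then_merge"),
                       minBeads = 3, maxClumpFraction = 0.5,
                       highTier = 1.0, lowTier = 0.6, seed = 1L,
                       logLevel = c("info", "quiet")) {
  list(seg = seg, rim = rim, mergeOrder = match.arg(mergeOrder),
       minBeads = minBeads, maxClumpFraction = maxClumpFraction,
       highTier = highTier, lowTier = lowTier, seed = as.integer(seed),
       logLevel = match.arg(logLevel))
}

#' @rdname flipConfig
#' @param path JSON config path.
#' @export
readConfig <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(flipConfig))
  unknown <- setdiff(names(js), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys are: ", paste(known, collapse = ", "))
  }
  if (!is.null(js$seg)) js$seg <- do.call(segParams, js$seg)
  if (!is.null(js$rim)) js$rim <- do.call(rimParams, js$rim)
  do.call(flipConfig, js)
}
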