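#' @include AllGenerics.R
NULL

# Central S4 containers. All pixel coordinates in the package are 1-based
# (row, col) matrix indices; distances are Euclidean between pixel centres.

#' Single-channel fluorescence micrograph
#'
#' A rectangular grid of non-negative fluorescence intensities in native
#' camera units, together with its bit depth. Intensities are stored
#' unnormalised (0 .. 2^bitDepth - 1); all region statistics in the package
#' are computed on these raw values.
#'
#' @slot pixels Numeric matrix of intensities (rows x cols).
#' @slot bitDepth Integer, 8 or 16.
#' @slot source Character provenance string (file path or simulator tag);
#'   may be empty.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param bitDepth Integer bit depth, 8 or 16 (default 16).
#' @param source Optional provenance string.
#' @return A `FluorImage` object.
#' @examples
#' img <- FluorImage(matrix(0:3, 2, 2), bitDepth = 8L)
#' dim(pixels(img))
#' @export
setClass("FluorImage",
  representation(pixels = "matrix", bitDepth = "integer", source = "character"),
  prototype(bitDepth = 16L, source = character(0))
)

setValidity("FluorImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (length(dim(p)) != 2L || any(dim(p) < 1L)) {
    return("pixels must be a non-empty 2-D matrix")
  }
  if (!(object@bitDepth %in% c(8L, 16L))) return("bitDepth must be 8 or 16")
  if (anyNA(p)) return("pixels must not contain NA")
  if (min(p) < 0) return("pixel intensities must be non-negative")
  if (max(p) > 2^object@bitDepth - 1) {
    return(sprintf("pixel intensities exceed the %d-bit range", object@bitDepth))
  }
  TRUE
})

#' @rdname FluorImage-class
#' @export
FluorImage <- function(pixels, bitDepth = 16L, source = character(0)) {
  new("FluorImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      source = as.character(source))
}

#' Synthetic scene specification
#'
#' Full description of a synthetic bead micrograph: frame size, background
#' level, a bead table, optional non-spherical contaminants, the noise model
#' and the seed. The seed fully determines the rendered image.
#'
#' Beads are ideal filled discs; a bead with `rimThickness > 0` carries an
#' annulus of uniform `rimIntensity` over the outer `rimThickness` pixels of
#' its radius, the remainder being `bodyIntensity`. Overlapping objects are
#' combined with per-pixel maximum intensity.
#'
#' @slot imageShape Integer length-2, (rows, cols).
#' @slot backgroundIntensity Numeric background level (>= 0).
#' @slot beads data.frame built by [beadSpec()].
#' @slot contaminants List of descriptors from [ellipseContaminant()] /
#'   [polygonContaminant()].
#' @slot gaussianSigma Numeric sd of additive Gaussian read noise (0 = none).
#' @slot shotNoise Logical; add signal-dependent noise with variance equal
#'   to the noiseless intensity.
#' @slot seed Integer RNG seed.
#' @slot bitDepth Integer, 8 or 16.
#' @slot allowClip Logical; permit beads extending beyond the frame.
#' @export
setClass("SceneSpec",
  representation(imageShape = "integer", backgroundIntensity = "numeric",
                 beads = "data.frame", contaminants = "list",
                 gaussianSigma = "numeric", shotNoise = "logical",
                 seed = "integer", bitDepth = "integer", allowClip = "logical")
)

setValidity("SceneSpec", function(object) {
  sh <- object@imageShape
  if (length(sh) != 2L || any(sh < 1L)) return("imageShape must be two positive integers")
  if (object@backgroundIntensity < 0) return("backgroundIntensity must be >= 0")
  if (object@gaussianSigma < 0) return("gaussianSigma must be >= 0")
  if (!(object@bitDepth %in% c(8L, 16L))) return("bitDepth must be 8 or 16")
  b <- object@beads
  need <- c("row", "col", "radius", "bodyIntensity", "rimIntensity", "rimThickness")
  if (nrow(b) > 0) {
    if (!all(need %in% names(b))) return("beads must come from beadSpec()")
    if (any(b$radius < 3)) return("bead radius must be >= 3 px")
    if (any(b$rimThickness < 0) || any(b$rimThickness >= b$radius)) {
      return("rimThickness must satisfy 0 <= rimThickness < radius")
    }
    if (any(b$bodyIntensity < 0) || any(b$rimIntensity < 0)) {
      return("bead intensities must be >= 0")
    }
    maxv <- 2^object@bitDepth - 1
    if (any(pmax(b$bodyIntensity, b$rimIntensity) > maxv)) {
      return("bead intensities exceed the bit-depth range")
    }
    if (!object@allowClip) {
      inside <- b$row - b$radius >= 1 & b$row + b$radius <= sh[1] &
                b$col - b$radius >= 1 & b$col + b$radius <= sh[2]
      if (!all(inside)) {
        return("bead extends outside the frame (set allowClip = TRUE to permit)")
      }
    }
  }
  TRUE
})

#' Exact ground truth for a synthetic scene
#'
#' Label image (0 = background, k = object k) plus per-object truth: type,
#' geometry, and for beads the true ring mean, body mean and their
#' difference (`rimIntensity - bodyIntensity` for noiseless scenes).
#'
#' @slot labels Integer label matrix, same shape as the rendered image.
#' @slot objects data.frame with one row per object (beads first, then
#'   contaminants): label, type, row, col, radius, rimThickness,
#'   bodyIntensity, rimIntensity, trueRingMean, trueBodyMean,
#'   trueDifference.
#' @export
setClass("GroundTruth",
  representation(labels = "matrix", objects = "data.frame")
)

#' Rendered synthetic scene
#'
#' Pairs the rendered [FluorImage] with its [GroundTruth] and the
#' originating [SceneSpec].
#'
#' @slot image A [FluorImage].
#' @slot truth A [GroundTruth].
#' @slot spec The [SceneSpec] that produced the scene.
#' @export
setClass("SimulatedScene",
  representation(image = "FluorImage", truth = "GroundTruth", spec = "SceneSpec")
)

#' Detected bead regions
#'
#' Output of [detectBeads()]: a label matrix over the image and a per-region
#' table of centroids, sizes, shape scores and the retained/rejected status
#' with its reason (`none`, `too_small`, `too_large`, `non_spherical`,
#' `clump`, `border`).
#'
#' @slot labels Integer label matrix (0 = background); labels are ordered by
#'   centroid row, then column.
#' @slot regions data.frame: label, centroidRow, centroidCol, area,
#'   equivalentRadius, circularity, solidity, retained, reason.
#' @slot params List of segmentation parameters in effect (see [segParams()]).
#' @slot saturated Logical; TRUE when the input image was fully saturated.
#' @export
setClass("BeadRegions",
  representation(labels = "matrix", regions = "data.frame", params = "list",
                 saturated = "logical"),
  prototype(saturated = FALSE)
)

setValidity("BeadRegions", function(object) {
  r <- object@regions
  need <- c("label", "centroidRow", "centroidCol", "area", "equivalentRadius",
            "circularity", "solidity", "retained", "reason")
  if (!all(need %in% names(r))) return("regions table is missing columns")
  if (nrow(r) > 0) {
    if (any(r$circularity > 1.05, na.rm = TRUE)) {
      return("circularity exceeds the discretisation tolerance of 1.05")
    }
    if (any(r$retained & r$reason != "none")) {
      return("retained regions must have reason 'none'")
    }
  }
  TRUE
})

#' FLIP signal for one image or condition
#'
#' The per-image FLIP signal is the unweighted mean over retained beads of
#' each bead's (ring mean - body mean). `controlSignal`/`correctedSignal`
#' are populated by [controlSubtract()]; `replicateValues`/`variability`
#' (the max - min range of duplicate measurements, the assay's "var.") by
#' [replicateMerge()]. Signals may be negative: IgG-control beads typically
#' have rims darker than their bodies.
#'
#' @slot rawSignal Numeric, mean per-bead rim-minus-body difference.
#' @slot controlSignal Numeric or NA when no control has been applied.
#' @slot correctedSignal Numeric or NA; exactly rawSignal - controlSignal.
#' @slot nBeads Integer number of beads contributing.
#' @slot replicateValues Numeric vector of per-replicate raw signals.
#' @slot variability Numeric max - min of replicateValues (0 for a single
#'   measurement, NA when replicates were never merged).
#' @export
setClass("FlipResult",
  representation(rawSignal = "numeric", controlSignal = "numeric",
                 correctedSignal = "numeric", nBeads = "integer",
                 replicateValues = "numeric", variability = "numeric"),
  prototype(controlSignal = NA_real_, correctedSignal = NA_real_,
            replicateValues = numeric(0), variability = NA_real_)
)

setValidity("FlipResult", function(object) {
  if (length(object@rawSignal) != 1L) return("rawSignal must be length 1")
  if (is.na(object@controlSignal) != is.na(object@correctedSignal)) {
    return("correctedSignal must be present exactly when controlSignal is")
  }
  if (!is.na(object@correctedSignal)) {
    if (object@correctedSignal != object@rawSignal - object@controlSignal) {
      return("correctedSignal must equal rawSignal - controlSignal exactly")
    }
  }
  TRUE
})

#' Recombinant-YFP standard curve
#'
#' Ordinary least-squares line `fluorescence = slope * mass + intercept`
#' fitted to known recombinant-YFP masses (a typical curve spans 0-500 ng).
#' Samples read with a different plate/gain context must not be quantified
#' against it, so the plate identifier is carried along.
#'
#' @slot points data.frame (massNg, fluorescence) used for the fit.
#' @slot slope Fluorescence units per ng.
#' @slot intercept Fluorescence units.
#' @slot rSquared Coefficient of determination of the fit.
#' @slot massRange Numeric length-2, ng range spanned by the fitted points.
#' @slot plateId Character plate/gain context ("" when not supplied).
#' @export
setClass("StandardCurve",
  representation(points = "data.frame", slope = "numeric",
                 intercept = "numeric", rSquared = "numeric",
                 massRange = "numeric", plateId = "character")
)

setValidity("StandardCurve", function(object) {
  if (nrow(object@points) < 2L) return("a standard curve needs >= 2 points")
  if (length(unique(object@points$massNg)) < 2L) {
    return("a standard curve needs >= 2 distinct masses")
  }
  if (length(object@massRange) != 2L) return("massRange must be length 2")
  TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "FluorImage", function(object) {
  cat(sprintf("FluorImage: %d x %d px, %d-bit, intensity range [%g, %g]\n",
              nrow(object@pixels), ncol(object@pixels), object@bitDepth,
              min(object@pixels), max(object@pixels)))
  if (length(object@source)) cat("  source:", object@source, "\n")
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d px (%d-bit), background %g, %d bead(s), %d contaminant(s)\n",
              object@imageShape[1], object@imageShape[2], object@bitDepth,
              object@backgroundIntensity, nrow(object@beads),
              length(object@contaminants)))
  cat(sprintf("  noise: gaussian sigma %g%s; seed %d\n", object@gaussianSigma,
              if (object@shotNoise) " + shot noise" else "", object@seed))
})

setMethod("show", "SimulatedScene", function(object) {
  cat("SimulatedScene\n")
  show(object@image)
  cat(sprintf("  ground truth: %d object(s)\n", nrow(object@truth@objects)))
})

setMethod("show", "BeadRegions", function(object) {
  r <- object@regions
  cat(sprintf("BeadRegions: %d object(s), %d retained\n",
              nrow(r), sum(r$retained)))
  if (nrow(r) > 0 && any(!r$retained)) {
    tab <- table(r$reason[!r$retained])
    cat("  rejected:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (isTRUE(object@saturated)) cat("  WARNING: saturated input image\n")
})

setMethod("show", "FlipResult", function(object) {
  cat(sprintf("FlipResult: raw %.4g (n beads = %d)\n",
              object@rawSignal, object@nBeads))
  if (!is.na(object@correctedSignal)) {
    cat(sprintf("  control %.4g -> corrected %.4g\n",
                object@controlSignal, object@correctedSignal))
  }
  if (length(object@replicateValues) > 1L) {
    cat(sprintf("  replicates: %s (var. = %.4g)\n",
                paste(signif(object@replicateValues, 5), collapse = ", "),
                object@variability))
  }
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: fluorescence = %.6g * ng + %.6g (R^2 = %.4f)\n",
              object@slope, object@intercept, object@rSquared))
  cat(sprintf("  %d points, %g-%g ng%s\n", nrow(object@points),
              object@massRange[1], object@massRange[2],
              if (nzchar(object@plateId)) paste0(", plate ", object@plateId) else ""))
})

## ---- accessors --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("pixels", "FluorImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("bitDepth", "FluorImage", function(object) object@bitDepth)

#' @rdname accessors
#' @export
setMethod("labelMatrix", "BeadRegions", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("labelMatrix", "GroundTruth", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("regionTable", "BeadRegions", function(object) object@regions)

#' @rdname accessors
#' @export
setMethod("sceneImage", "SimulatedScene", function(object) object@image)

#' @rdname accessors
#' @export
setMethod("sceneTruth", "SimulatedScene", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("truthTable", "GroundTruth", function(object) object@objects)

#' @rdname accessors
#' @export
setMethod("rawSignal", "FlipResult", function(object) object@rawSignal)

#' @rdname accessors
#' @export
setMethod("controlSignal", "FlipResult", function(object) object@controlSignal)

#' @rdname accessors
#' @export
setMethod("correctedSignal", "FlipResult", function(object) object@correctedSignal)

#' @rdname accessors
#' @export
setMethod("nBeads", "FlipResult", function(object) object@nBeads)

#' @rdname accessors
#' @export
setMethod("replicateValues", "FlipResult", function(object) object@replicateValues)

#' @rdname accessors
#' @export
setMethod("variability", "FlipResult", function(object) object@variability)

#' @rdname accessors
#' @export
setMethod("curveSlope", "StandardCurve", function(object) object@slope)

#' @rdname accessors
#' @export
setMethod("curveIntercept", "StandardCurve", function(object) object@intercept)

#' @rdname accessors
#' @export
setMethod("curveRSquared", "StandardCurve", function(object) object@rSquared)

#' @rdname accessors
#' @export
setMethod("massRange", "StandardCurve", function(object) object@massRange)
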