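#' Ring-band parameters
#'
#' Geometry of the two measured regions of a bead. The ring is the band of
#' depth `d = max(minRimPx, rimFraction * equivalentRadius)` inside the
#' bead's outer radius; the body is the bead eroded by `d + guardPx`, the
#' guard band keeping the two regions from touching. `edgeMarginPx` is a
#' sub-pixel margin applied at both edges of the ring band so that
#' single-lattice-pixel boundary error (rasterisation, segmentation wobble)
#' cannot mix body or background pixels into the ring; it does not change
#' noiseless results on ideal beads.
#'
#' Defaults keep the body non-empty for beads of radius >= 5 px.
#'
#' @param rimFraction Ring depth as a fraction of the equivalent radius,
#'   in (0, 0.5].
#' @param minRimPx Floor on the ring depth in pixels (>= 1).
#' @param guardPx Guard band between ring and body in pixels (>= 0).
#' @param edgeMarginPx Sub-pixel margin at the ring-band edges (>= 0).
#' @return A named list of validated parameters.
#' @export
rimParams <- function(rimFraction = 0.15, minRimPx = 2, guardPx = 1,
                      edgeMarginPx = 0.5) {
  stopifnot(rimFraction > 0, rimFraction <= 0.5, minRimPx >= 1,
            guardPx >= 0, edgeMarginPx >= 0)
  list(rimFraction = rimFraction, minRimPx = minRimPx, guardPx = guardPx,
       edgeMarginPx = edgeMarginPx)
}

#' Per-bead ring and body statistics
#'
#' For every retained bead, measures the mean raw fluorescence of the
#' perimeter ring and of the bead body, and their signed difference - the
#' per-bead FLIP contribution. A bright ring over a dimmer body (positive
#' difference) is the signature of a successful IP; IgG-control beads give
#' differences near zero (uniform glow) or negative (edges darker than the
#' body).
#'
#' For a bead with outer radius `R` (the largest centroid distance in its
#' mask) and ring depth `d`, ring pixels satisfy `R - d + m < dist <= R - m`
#' and body pixels `dist <= R - d - guard`, with `m` the sub-pixel edge
#' margin; all intensities are read from the raw image.
#'
#' @param image A [FluorImage-class].
#' @param regions A [BeadRegions-class] (from [detectBeads()] or
#'   [beadRegionsFromTruth()]).
#' @param params From [rimParams()].
#' @return data.frame with one row per retained bead: `beadLabel`,
#'   `ringMean`, `bodyMean`, `difference` (= ringMean - bodyMean),
#'   `ringPixelCount`, `bodyPixelCount`.
#' @examples
#' sc <- renderScene(sceneSpec(imageShape = c(96, 96), backgroundIntensity = 10,
#'                             beads = beadSpec(48, 48, 20, 200, 1000, 3)))
#' rg <- beadRegionsFromTruth(sceneTruth(sc))
#' ringBodyStats(sceneImage(sc), rg, rimParams(minRimPx = 3))
#' @export
ringBodyStats <- function(image, regions, params = rimParams()) {
  stopifnot(is(image, "FluorImage"), is(regions, "BeadRegions"))
  raw <- pixels(image)
  labels <- labelMatrix(regions)
  stopifnot(identical(dim(raw), dim(labels)))
  reg <- regionTable(regions)
  keep <- reg[reg$retained, , drop = FALSE]
  rows <- row(labels); cols <- col(labels)
  out <- lapply(seq_len(nrow(keep)), function(i) {
    lab <- keep$label[i]
    idx <- which(labels == lab)
    pr <- rows[idx]; pc <- cols[idx]
    cr <- mean(pr); cc <- mean(pc)
    dc <- sqrt((pr - cr)^2 + (pc - cc)^2)
    rOut <- max(dc)
    rEq <- sqrt(length(idx) / pi)
    d <- max(params$minRimPx, params$rimFraction * rEq)
    m <- params$edgeMarginPx
    ring <- dc > rOut - d + m & dc <= rOut - m
    body <- dc <= rOut - d - params$guardPx
    if (!any(ring) || !any(body)) {
      stop(sprintf(paste0("degenerate bead %d: radius %.1f px leaves no ",
                          "%s pixels for ring depth %.2f + guard %g"),
                   lab, rOut, if (!any(ring)) "ring" else "body",
                   d, params$guardPx))
    }
    ringMean <- mean(raw[idx[ring]])
    bodyMean <- mean(raw[idx[body]])
    data.frame(beadLabel = lab, ringMean = ringMean, bodyMean = bodyMean,
               difference = ringMean - bodyMean,
               ringPixelCount = sum(ring), bodyPixelCount = sum(body))
  })
  if (length(out) == 0) {
    return(data.frame(beadLabel = integer(0), ringMean = numeric(0),
                      bodyMean = numeric(0), difference = numeric(0),
                      ringPixelCount = integer(0), bodyPixelCount = integer(0)))
  }
  do.call(rbind, out)
}

#' Image-level FLIP signal
#'
#' The FLIP signal of one image: the unweighted mean over retained beads of
#' each bead's ring-minus-body difference. Treating every bead as a single
#' entity makes the value independent of how many beads happen to lie in
#' the frame - the decisive advantage over the legacy whole-image mean
#' (see [globalMeanFlip()]).
#'
#' @inheritParams ringBodyStats
#' @return A [FlipResult-class] carrying the raw signal only.
#' @seealso [controlSubtract()], [replicateMerge()]
#' @export
imageFlipSignal <- function(image, regions, params = rimParams()) {
  st <- ringBodyStats(image, regions, params)
  if (nrow(st) == 0) {
    stop("no usable beads in image: cannot compute a FLIP signal ",
         "(this is distinct from a zero signal)")
  }
  raw <- mean(st$difference)
  new("FlipResult", rawSignal = raw, nBeads = nrow(st),
      replicateValues = raw, variability = NA_real_)
}

#' Subtract the IgG-control signal
#'
#' The true FLIP signal of a test image is its raw signal minus the signal
#' of the matched IgG-control IP. Control signals are typically negative
#' (control bead edges are darker than their bodies), so subtraction can
#' raise the corrected value. Negative corrected signals are preserved
#' here; clipping to zero is purely a reporting convention (see
#' [classifyScreen()]).
#'
#' @param test,control [FlipResult-class] objects for the test-antibody and
#'   IgG-control images. A missing control is an error, never a silent
#'   zero.
#' @return A [FlipResult-class] with `controlSignal` and `correctedSignal`
#'   populated.
#' @export
controlSubtract <- function(test, control) {
  if (missing(control) || is.null(control)) {
    stop("absent control: an IgG-control FlipResult is required ",
         "(a missing control is never treated as zero)")
  }
  stopifnot(is(test, "FlipResult"), is(control, "FlipResult"))
  new("FlipResult", rawSignal = test@rawSignal,
      controlSignal = control@rawSignal,
      correctedSignal = test@rawSignal - control@rawSignal,
      nBeads = test@nBeads, replicateValues = test@replicateValues,
      variability = test@variability)
}

#' Merge replicate FLIP measurements
#'
#' Combines duplicate measurements of the same condition (e.g. two
#' pictures from two aliquots of the same beads): the merged signal is the
#' mean of the replicate signals and the reported variability ("var.") is
#' their range, max - min. With a single replicate the variability is 0.
#'
#' @param results List of [FlipResult-class] objects from the same
#'   condition (>= 1).
#' @return A merged [FlipResult-class]. When every input already carries a
#'   control, the merged control is the mean of the replicate controls and
#'   the corrected signal is recomputed; `replicateValues` then holds the
#'   per-replicate corrected signals.
#' @export
replicateMerge <- function(results) {
  if (length(results) == 0) stop("replicateMerge needs at least one result")
  stopifnot(all(vapply(results, is, logical(1), "FlipResult")))
  raws <- vapply(results, function(r) r@rawSignal, numeric(1))
  ctls <- vapply(results, function(r) r@controlSignal, numeric(1))
  nb <- sum(vapply(results, function(r) r@nBeads, integer(1)))
  if (all(!is.na(ctls))) {
    vals <- raws - ctls
    raw <- mean(raws); ctl <- mean(ctls)
    new("FlipResult", rawSignal = raw, controlSignal = ctl,
        correctedSignal = raw - ctl, nBeads = nb, replicateValues = vals,
        variability = max(vals) - min(vals))
  } else {
    new("FlipResult", rawSignal = mean(raws), nBeads = nb,
        replicateValues = raws, variability = max(raws) - min(raws))
  }
}

#' Legacy whole-image FLIP quantification
#'
#' The original readout: mean fluorescence of all pixels in the test image
#' minus the mean of all pixels in the matched IgG-control image. Kept for
#' comparison; unlike [imageFlipSignal()], this value scales with the
#' number of beads in the frame and is inflated by fluorescent
#' contaminants, which is what motivated the per-bead ring/body method.
#'
#' @param testImage,controlImage [FluorImage-class] objects acquired with
#'   identical microscope settings.
#' @return Signed intensity difference (numeric scalar).
#' @export
globalMeanFlip <- function(testImage, controlImage) {
  stopifnot(is(testImage, "FluorImage"), is(controlImage, "FluorImage"))
  mean(pixels(testImage)) - mean(pixels(controlImage))
}
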