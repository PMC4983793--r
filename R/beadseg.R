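#' Segmentation parameters
#'
#' Controls for [detectBeads()]. The pipeline is: Gaussian smoothing ->
#' threshold (Otsu by default) -> hole filling -> connected components ->
#' shape and size filtering -> radial mask refinement of retained beads.
#' The threshold is found on the smoothed image but all statistics are
#' measured on the raw image, so the rim is never blurred into the numbers.
#'
#' @param smoothingSigma Gaussian smoothing sd in pixels (0 disables).
#' @param thresholdMethod "otsu" (automatic, histogram-based) or "fixed".
#' @param thresholdValue Fixed threshold on the normalised \[0, 1\] intensity
#'   scale; required when `thresholdMethod = "fixed"`.
#' @param minRadius,maxRadius Equivalent-radius bounds in pixels for a
#'   retained bead.
#' @param minCircularity Minimum `4*pi*area/perimeter^2` (perimeter from the
#'   traced boundary chain). Elongated contaminants and touching-bead clumps
#'   fall well below the default.
#' @param minSolidity Minimum area / convex-hull-area; deeply concave
#'   objects (merged beads) fail here and are rejected as clumps rather
#'   than split, since an overlapping bead has no complete rim to measure.
#' @param excludeBorder Reject beads touching the image border (their rim is
#'   incomplete).
#' @param refineRadius Snap each retained bead's mask to the disc of the
#'   largest integer shell whose mean raw intensity stays above background;
#'   this undoes the ~0.5 px mask dilation that smoothing plus thresholding
#'   produces and recovers dark rims that fall below the global threshold
#'   (IgG-control beads). See the package vignette.
#' @return A named list of validated parameters.
#' @export
segParams <- function(smoothingSigma = 2, thresholdMethod = c("otsu", "fixed"),
                      thresholdValue = NULL, minRadius = 5, maxRadius = 100,
                      minCircularity = 0.80, minSolidity = 0.90,
                      excludeBorder = TRUE, refineRadius = TRUE) {
  thresholdMethod <- match.arg(thresholdMethod)
  stopifnot(smoothingSigma >= 0, minRadius > 0, minRadius < maxRadius,
            minCircularity >= 0, minCircularity <= 1,
            minSolidity >= 0, minSolidity <= 1)
  if (thresholdMethod == "fixed") {
    stopifnot(is.numeric(thresholdValue), thresholdValue > 0, thresholdValue < 1)
  }
  list(smoothingSigma = smoothingSigma, thresholdMethod = thresholdMethod,
       thresholdValue = thresholdValue, minRadius = minRadius,
       maxRadius = maxRadius, minCircularity = minCircularity,
       minSolidity = minSolidity, excludeBorder = excludeBorder,
       refineRadius = refineRadius)
}

# Perimeter of one labelled object from its ordered boundary chain.
chainPerimeter <- function(contour) {
  seg <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE]) - contour
  sum(sqrt(rowSums(seg^2)))
}

# area / rasterised convex-hull area, capped at 1.
hullSolidity <- function(contour, area) {
  if (nrow(unique(contour)) < 3L) return(1)
  h <- grDevices::chull(contour)
  poly <- contour[h, , drop = FALSE]
  rng <- apply(contour, 2, range)
  g <- expand.grid(x = rng[1, 1]:rng[2, 1], y = rng[1, 2]:rng[2, 2])
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                         as.matrix(g))
  min(1, area / max(area, sum(inside)))
}

emptyRegionTable <- function() {
  data.frame(label = integer(0), centroidRow = numeric(0),
             centroidCol = numeric(0), area = integer(0),
             equivalentRadius = numeric(0), circularity = numeric(0),
             solidity = numeric(0), retained = logical(0),
             reason = character(0), radiusRefined = logical(0))
}

# Radially refine one bead: largest contiguous run of integer shells
# (from the component centroid) whose mean raw intensity stays above
# background + 0.25 * (threshold - background).
refineBeadMask <- function(raw, labels, lab, centroid, rComp, level, maxR) {
  nr <- nrow(raw); nc <- ncol(raw)
  ext <- min(maxR + 1, rComp + max(5, ceiling(0.25 * rComp)))
  r0 <- max(1L, floor(centroid[1] - ext)); r1 <- min(nr, ceiling(centroid[1] + ext))
  c0 <- max(1L, floor(centroid[2] - ext)); c1 <- min(nc, ceiling(centroid[2] + ext))
  rows <- r0:r1; cols <- c0:c1
  d <- sqrt(outer((rows - centroid[1])^2, (cols - centroid[2])^2, "+"))
  sub <- raw[rows, cols, drop = FALSE]
  lsub <- labels[rows, cols, drop = FALSE]
  usable <- lsub == 0L | lsub == lab         # never claim another object
  shell <- ceiling(d)
  rMeas <- 0L
  for (k in seq_len(floor(ext))) {
    px <- shell == k & usable
    if (!any(px)) break
    if (mean(sub[px]) < level) break
    rMeas <- k
  }
  if (rMeas < 1L) return(NULL)
  keep <- d <= rMeas & usable
  list(rows = rows, cols = cols, keep = keep, radius = rMeas)
}

#' Detect beads in a fluorescence micrograph
#'
#' Segments bright objects on a dark background and scores every connected
#' component, marking each as retained or rejected with a reason: `border`
#' (touches the frame edge), `too_small` / `too_large` (equivalent radius
#' outside bounds), `non_spherical` (circularity below threshold: elongated
#' contaminants, and most merged bead pairs), or `clump` (solidity below
#' threshold: concave merged objects). The per-bead treatment excludes
#' rather than splits overlaps, so no watershed is attempted: a merged
#' bead has no complete rim to measure.
#'
#' A constant (blank) image yields an empty region set; a fully saturated
#' image raises a warning and sets the `saturated` flag with nothing
#' retained. Output is deterministic and labels are ordered by centroid row,
#' then column.
#'
#' @param image A [FluorImage-class].
#' @param params From [segParams()].
#' @return A [BeadRegions-class]; see [regionTable()] and [labelMatrix()].
#' @examples
#' sc <- renderScene(sceneSpec(imageShape = c(128, 128), backgroundIntensity = 20,
#'                             beads = beadSpec(64, 64, 18, 300, 1200, 3)))
#' rg <- detectBeads(sceneImage(sc))
#' regionTable(rg)
#' @export
detectBeads <- function(image, params = segParams()) {
  stopifnot(is(image, "FluorImage"))
  validObject(image)
  raw <- pixels(image)
  maxv <- 2^bitDepth(image) - 1
  empty <- new("BeadRegions", labels = matrix(0L, nrow(raw), ncol(raw)),
               regions = emptyRegionTable(), params = params)

  if (diff(range(raw)) == 0) {
    if (min(raw) >= maxv) {
      warning("saturated image: all pixels at the bit-depth maximum")
      empty@saturated <- TRUE
    }
    return(empty)
  }

  norm <- raw / maxv
  sm <- if (params$smoothingSigma > 0) {
    as.matrix(EBImage::gblur(EBImage::as.Image(norm),
                             sigma = params$smoothingSigma))
  } else norm
  # Otsu over the occupied intensity range: low-intensity micrographs use
  # a sliver of the bit-depth range and would otherwise fall into one bin
  thr <- if (params$thresholdMethod == "otsu") {
    EBImage::otsu(EBImage::as.Image(sm), range = range(sm), levels = 1024L)
  } else params$thresholdValue
  mask <- sm > thr
  if (!any(mask)) return(empty)
  mask <- EBImage::fillHull(mask)
  labels <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(raw), ncol(raw))
  nObj <- max(labels)
  contours <- EBImage::ocontour(labels)

  rows <- row(labels); cols <- col(labels)
  bgLevel <- stats::median(raw[labels == 0L])
  refineLevel <- bgLevel + 0.25 * (thr * maxv - bgLevel)

  reg <- vector("list", nObj)
  for (lab in seq_len(nObj)) {
    idx <- labels == lab
    area <- sum(idx)
    cr <- mean(rows[idx]); cc <- mean(cols[idx])
    rEq <- sqrt(area / pi)
    onBorder <- any(rows[idx] == 1L | rows[idx] == nrow(raw) |
                    cols[idx] == 1L | cols[idx] == ncol(raw))
    circ <- NA_real_; sol <- NA_real_
    reason <- "none"
    if (params$excludeBorder && onBorder) {
      reason <- "border"
    } else if (rEq < params$minRadius) {
      reason <- "too_small"
    } else {
      ct <- contours[[lab]]
      per <- chainPerimeter(ct)
      circ <- min(4 * pi * area / per^2, 1.05)
      sol <- hullSolidity(ct, area)
      if (rEq > params$maxRadius) reason <- "too_large"
      else if (circ < params$minCircularity) reason <- "non_spherical"
      else if (sol < params$minSolidity) reason <- "clump"
    }
    reg[[lab]] <- data.frame(label = lab, centroidRow = cr, centroidCol = cc,
                             area = area, equivalentRadius = rEq,
                             circularity = circ, solidity = sol,
                             retained = reason == "none", reason = reason,
                             radiusRefined = FALSE)
  }
  regions <- do.call(rbind, reg)

  # radial refinement of retained beads (raw-intensity shells)
  if (params$refineRadius) {
    for (i in which(regions$retained)) {
      lab <- regions$label[i]
      rf <- refineBeadMask(raw, labels, lab,
                           c(regions$centroidRow[i], regions$centroidCol[i]),
                           regions$equivalentRadius[i], refineLevel,
                           params$maxRadius)
      if (is.null(rf)) next
      labels[labels == lab] <- 0L
      block <- labels[rf$rows, rf$cols, drop = FALSE]
      block[rf$keep] <- lab
      labels[rf$rows, rf$cols] <- block
      area <- sum(rf$keep)
      regions$area[i] <- area
      regions$equivalentRadius[i] <- sqrt(area / pi)
      regions$radiusRefined[i] <- TRUE
      if (params$excludeBorder &&
          (regions$centroidRow[i] - rf$radius < 1 ||
           regions$centroidRow[i] + rf$radius > nrow(raw) ||
           regions$centroidCol[i] - rf$radius < 1 ||
           regions$centroidCol[i] + rf$radius > ncol(raw))) {
        regions$retained[i] <- FALSE
        regions$reason[i] <- "border"
      }
    }
    # size filter on the refined radius
    for (i in which(regions$retained)) {
      if (regions$equivalentRadius[i] < params$minRadius) {
        regions$retained[i] <- FALSE; regions$reason[i] <- "too_small"
      } else if (regions$equivalentRadius[i] > params$maxRadius) {
        regions$retained[i] <- FALSE; regions$reason[i] <- "too_large"
      }
    }
  }

  # stable ordering: centroid row, then column
  ord <- order(regions$centroidRow, regions$centroidCol)
  regions <- regions[ord, , drop = FALSE]
  remap <- integer(nObj)
  remap[regions$label] <- seq_len(nrow(regions))
  regions$label <- seq_len(nrow(regions))
  rownames(regions) <- NULL
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]

  new("BeadRegions", labels = labels, regions = regions, params = params)
}

#' Bead-distribution quality control
#'
#' Summarises a detection the way an operator would eyeball the well before
#' trusting the numbers: how many beads were retained, how much of the
#' frame they cover, what was rejected and why. The monolayer flag is
#' raised when fewer than `minBeads` beads survive ("too-few-beads") or
#' when clump-like rejections (`clump` plus `non_spherical`) exceed
#' `maxClumpFraction` of all objects ("clump-dominated"), signalling beads
#' stacked in layers or a contaminated well.
#'
#' @param regions A [BeadRegions-class].
#' @param minBeads Minimum retained beads before flagging (default 3).
#' @param maxClumpFraction Maximum tolerated clump-like fraction (default 0.5).
#' @return A list: `nRetained`, `nObjects`, `coverage` (fraction of frame
#'   area under retained beads), `rejectionCounts` (named), `clumpFraction`,
#'   `monolayerFlag`, `flagReasons`.
#' @export
checkBeadDistribution <- function(regions, minBeads = 3,
                                  maxClumpFraction = 0.5) {
  stopifnot(is(regions, "BeadRegions"))
  r <- regionTable(regions)
  nObj <- nrow(r)
  nRet <- sum(r$retained)
  rej <- r$reason[!r$retained]
  counts <- table(factor(rej, levels = c("border", "too_small", "too_large",
                                         "non_spherical", "clump")))
  clumpFrac <- if (nObj > 0) {
    sum(rej %in% c("clump", "non_spherical")) / nObj
  } else 0
  coverage <- sum(r$area[r$retained]) / length(labelMatrix(regions))
  reasons <- character(0)
  if (nRet < minBeads) reasons <- c(reasons, "too-few-beads")
  if (clumpFrac > maxClumpFraction) reasons <- c(reasons, "clump-dominated")
  list(nRetained = nRet, nObjects = nObj, coverage = coverage,
       rejectionCounts = as.list(counts), clumpFraction = clumpFrac,
       monolayerFlag = length(reasons) > 0, flagReasons = reasons)
}

#' Bead regions from synthetic ground truth
#'
#' Builds a [BeadRegions-class] directly from a scene's [GroundTruth-class]
#' label image, bypassing segmentation. Beads are retained (shape scores
#' are not recomputed); contaminants carry `reason = "non_spherical"`. Used
#' to test the quantification stage in isolation against exact masks.
#'
#' @param truth A [GroundTruth-class].
#' @return A [BeadRegions-class].
#' @export
beadRegionsFromTruth <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  labels <- labelMatrix(truth)
  objects <- truthTable(truth)
  rows <- row(labels); cols <- col(labels)
  reg <- lapply(seq_len(nrow(objects)), function(i) {
    lab <- objects$label[i]
    idx <- labels == lab
    area <- sum(idx)
    isBead <- objects$type[i] == "bead"
    data.frame(label = lab,
               centroidRow = mean(rows[idx]), centroidCol = mean(cols[idx]),
               area = area, equivalentRadius = sqrt(area / pi),
               circularity = NA_real_, solidity = NA_real_,
               retained = isBead,
               reason = if (isBead) "none" else "non_spherical",
               radiusRefined = FALSE)
  })
  regions <- if (length(reg)) do.call(rbind, reg) else emptyRegionTable()
  new("BeadRegions", labels = labels, regions = regions,
      params = list(source = "ground-truth"))
}

#' Write detected regions to disk
#'
#' Writes the per-region table as CSV and, optionally, the label matrix as
#' a 16-bit TIFF mask.
#'
#' @param regions A [BeadRegions-class].
#' @param csvPath Output CSV path.
#' @param maskPath Optional output TIFF path for the label image.
#' @return Invisibly, the paths written.
#' @export
writeRegions <- function(regions, csvPath, maskPath = NULL) {
  utils::write.csv(regionTable(regions), csvPath, row.names = FALSE)
  out <- csvPath
  if (!is.null(maskPath)) {
    tiff::writeTIFF(labelMatrix(regions) / 65535, maskPath,
                    bits.per.sample = 16L)
    out <- c(out, maskPath)
  }
  invisible(out)
}
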