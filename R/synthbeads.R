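#' Describe one synthetic bead
#'
#' Beads are ideal filled discs of `radius` pixels centred at (`row`,
#' `col`). When `rimThickness > 0` the outer annulus of that thickness
#' carries `rimIntensity` (the captured-fluorophore ring of a positive IP);
#' the interior carries `bodyIntensity`. `rimThickness = 0` gives a uniform
#' bead, the appearance of nonspecific background binding; `rimIntensity <
#' bodyIntensity` gives the dark-edged beads typical of IgG controls.
#'
#' @param row,col Bead centre in pixel coordinates (1-based, row-major).
#' @param radius Bead radius in pixels (>= 3).
#' @param bodyIntensity Interior intensity, arbitrary fluorescence units >= 0.
#' @param rimIntensity Annulus intensity (default equal to the body).
#' @param rimThickness Annulus thickness in pixels, `0 <= t < radius`.
#' @return A one-row data.frame; rbind several to build a scene bead table.
#' @seealso [sceneSpec()], [renderScene()]
#' @examples
#' beads <- rbind(
#'   beadSpec(60, 60, 20, bodyIntensity = 200, rimIntensity = 1000, rimThickness = 3),
#'   beadSpec(60, 120, 20, bodyIntensity = 500)  # uniform bead
#' )
#' @export
beadSpec <- function(row, col, radius, bodyIntensity, rimIntensity = bodyIntensity,
                     rimThickness = 0) {
  if (length(row) == 0) {
    return(data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
                      bodyIntensity = numeric(0), rimIntensity = numeric(0),
                      rimThickness = numeric(0)))
  }
  data.frame(row = row, col = col, radius = radius,
             bodyIntensity = bodyIntensity, rimIntensity = rimIntensity,
             rimThickness = rimThickness)
}

#' Non-spherical contaminant descriptors
#'
#' Contaminants exercise the segmentation stage's shape filter: lint fibres
#' and debris are emulated as elongated ellipses (aspect ratio >= 2 is
#' typical), irregular precipitates as free-form polygons. Both are filled
#' with a uniform intensity.
#'
#' @param row,col Centre of the ellipse (pixel coordinates).
#' @param semiMajor,semiMinor Ellipse semi-axes in pixels.
#' @param angle Rotation of the major axis, radians counter-clockwise from
#'   the column axis.
#' @param intensity Fill intensity, arbitrary units >= 0.
#' @return A contaminant descriptor (list) for [sceneSpec()].
#' @examples
#' ell <- ellipseContaminant(100, 80, semiMajor = 30, semiMinor = 10, intensity = 800)
#' tri <- polygonContaminant(rows = c(20, 40, 40), cols = c(30, 20, 40), intensity = 600)
#' @export
ellipseContaminant <- function(row, col, semiMajor, semiMinor, angle = 0,
                               intensity) {
  stopifnot(semiMajor > 0, semiMinor > 0, intensity >= 0)
  list(type = "ellipse", row = row, col = col, semiMajor = semiMajor,
       semiMinor = semiMinor, angle = angle, intensity = intensity)
}

#' @rdname ellipseContaminant
#' @param rows,cols Polygon vertex coordinates (>= 3 vertices).
#' @export
polygonContaminant <- function(rows, cols, intensity) {
  stopifnot(length(rows) == length(cols), length(rows) >= 3, intensity >= 0)
  list(type = "polygon", rows = as.numeric(rows), cols = as.numeric(cols),
       intensity = intensity)
}

#' Specify a synthetic bead scene
#'
#' Collects everything that determines a rendered micrograph. The default
#' frame is 512 x 512 at 16-bit depth; intensities are arbitrary units
#' (only relative intensities matter for FLIP). The seed fully determines
#' the noise realisation, so identical specs render bit-identical images.
#'
#' @param imageShape Integer (rows, cols) of the frame.
#' @param backgroundIntensity Background level in intensity units.
#' @param beads data.frame from [beadSpec()] rows (may be empty).
#' @param contaminants List of [ellipseContaminant()] / [polygonContaminant()]
#'   descriptors.
#' @param gaussianSigma Standard deviation of additive zero-mean Gaussian
#'   read noise (0 disables).
#' @param shotNoise Logical; add signal-dependent noise with variance equal
#'   to the noiseless pixel value (Poisson-like shot noise).
#' @param seed Integer seed for the noise generator.
#' @param bitDepth 8 or 16; noisy renders are clipped and rounded to this range.
#' @param allowClip Permit beads that extend beyond the frame (default an
#'   error, since a clipped bead has no complete rim).
#' @return A [SceneSpec-class] object.
#' @examples
#' sp <- sceneSpec(imageShape = c(128, 128), backgroundIntensity = 10,
#'                 beads = beadSpec(64, 64, 20, 200, 1000, 3))
#' sc <- renderScene(sp)
#' truthTable(sceneTruth(sc))
#' @export
sceneSpec <- function(imageShape = c(512L, 512L), backgroundIntensity = 20,
                      beads = beadSpec(numeric(0), numeric(0), numeric(0),
                                       numeric(0)),
                      contaminants = list(), gaussianSigma = 0,
                      shotNoise = FALSE, seed = 1L, bitDepth = 16L,
                      allowClip = FALSE) {
  new("SceneSpec", imageShape = as.integer(imageShape),
      backgroundIntensity = backgroundIntensity, beads = beads,
      contaminants = contaminants, gaussianSigma = gaussianSigma,
      shotNoise = shotNoise, seed = as.integer(seed),
      bitDepth = as.integer(bitDepth), allowClip = allowClip)
}

# Fill one object onto the accumulators. Overlaps take the pixelwise
# maximum intensity; the label goes to the brighter object (first wins ties).
paintObject <- function(objVal, labels, field, rows, cols, k) {
  idx <- cbind(rows, cols)
  cur <- objVal[idx]
  win <- is.na(cur) | field > cur
  if (any(win)) {
    objVal[idx[win, , drop = FALSE]] <- field[win]
    labels[idx[win, , drop = FALSE]] <- k
  }
  list(objVal = objVal, labels = labels)
}

# Pixel support of a bead/contaminant, restricted to the frame.
objectSupport <- function(obj, nr, nc) {
  if (!is.null(obj[["radius"]])) {                 # bead
    rr <- max(1L, floor(obj$row - obj$radius)):min(nr, ceiling(obj$row + obj$radius))
    cc <- max(1L, floor(obj$col - obj$radius)):min(nc, ceiling(obj$col + obj$radius))
    g <- expand.grid(row = rr, col = cc)
    d <- sqrt((g$row - obj$row)^2 + (g$col - obj$col)^2)
    keep <- d <= obj$radius
    v <- ifelse(d[keep] > obj$radius - obj$rimThickness & obj$rimThickness > 0,
                obj$rimIntensity, obj$bodyIntensity)
    list(rows = g$row[keep], cols = g$col[keep], values = v)
  } else if (obj$type == "ellipse") {
    ext <- max(obj$semiMajor, obj$semiMinor)
    rr <- max(1L, floor(obj$row - ext)):min(nr, ceiling(obj$row + ext))
    cc <- max(1L, floor(obj$col - ext)):min(nc, ceiling(obj$col + ext))
    g <- expand.grid(row = rr, col = cc)
    dr <- g$row - obj$row; dc <- g$col - obj$col
    # rotate into the ellipse frame (angle from the column axis)
    u <- dc * cos(obj$angle) + dr * sin(obj$angle)
    v <- -dc * sin(obj$angle) + dr * cos(obj$angle)
    keep <- (u / obj$semiMajor)^2 + (v / obj$semiMinor)^2 <= 1
    list(rows = g$row[keep], cols = g$col[keep],
         values = rep(obj$intensity, sum(keep)))
  } else {                                         # polygon
    rr <- max(1L, floor(min(obj$rows))):min(nr, ceiling(max(obj$rows)))
    cc <- max(1L, floor(min(obj$cols))):min(nc, ceiling(max(obj$cols)))
    g <- expand.grid(row = rr, col = cc)
    bnd <- cbind(c(obj$rows, obj$rows[1]), c(obj$cols, obj$cols[1]))
    keep <- mgcv::in.out(bnd, cbind(g$row, g$col))
    list(rows = g$row[keep], cols = g$col[keep],
         values = rep(obj$intensity, sum(keep)))
  }
}

#' Render a synthetic bead micrograph with exact ground truth
#'
#' Deterministically renders the scene described by a [SceneSpec-class]. A
#' noiseless render contains exactly the background, body and rim values by
#' region; with noise enabled, zero-mean Gaussian read noise and optional
#' shot noise are added, then values are clipped to the bit-depth range and
#' rounded to integers. The accompanying [GroundTruth-class] carries the
#' label image (0 = background; objects numbered beads first, then
#' contaminants) and each bead's true ring mean, body mean and difference.
#'
#' @param spec A [SceneSpec-class] from [sceneSpec()].
#' @return A [SimulatedScene-class]; use [sceneImage()] and [sceneTruth()].
#' @details `renderControlScene()` renders IgG-control scenes - uniform or
#'   dark-edged beads representing background binding - and refuses beads
#'   whose rim is brighter than their body, the signature of a real IP.
#' @examples
#' sp <- sceneSpec(imageShape = c(96, 96), backgroundIntensity = 10,
#'                 beads = beadSpec(48, 48, 15, 300, 100, 3), seed = 7L)
#' ctl <- renderControlScene(sp)
#' truthTable(sceneTruth(ctl))$trueDifference   # -200: darker edge
#' @export
renderScene <- function(spec) {
  validObject(spec)
  nr <- spec@imageShape[1]; nc <- spec@imageShape[2]
  objVal <- matrix(NA_real_, nr, nc)
  labels <- matrix(0L, nr, nc)
  beads <- spec@beads
  objs <- c(
    lapply(seq_len(nrow(beads)), function(i) as.list(beads[i, ])),
    spec@contaminants
  )
  for (k in seq_along(objs)) {
    s <- objectSupport(objs[[k]], nr, nc)
    if (length(s$rows)) {
      p <- paintObject(objVal, labels, s$values, s$rows, s$cols, k)
      objVal <- p$objVal; labels <- p$labels
    }
  }
  img <- matrix(spec@backgroundIntensity, nr, nc)
  img[labels > 0] <- objVal[labels > 0]

  maxv <- 2^spec@bitDepth - 1
  if (spec@gaussianSigma > 0 || spec@shotNoise) {
    img <- withSeed(spec@seed, {
      noisy <- img + rnorm(length(img), 0, spec@gaussianSigma)
      if (spec@shotNoise) noisy <- noisy + rnorm(length(img), 0, sqrt(img))
      noisy
    })
    img <- matrix(round(pmin(pmax(img, 0), maxv)), nr, nc)
  }

  nb <- nrow(beads)
  nObj <- length(objs)
  objects <- data.frame(
    label = seq_len(nObj),
    type = c(rep("bead", nb), rep("contaminant", nObj - nb)),
    row = rep(NA_real_, nObj), col = rep(NA_real_, nObj),
    radius = rep(NA_real_, nObj), rimThickness = rep(NA_real_, nObj),
    bodyIntensity = rep(NA_real_, nObj), rimIntensity = rep(NA_real_, nObj),
    trueRingMean = rep(NA_real_, nObj), trueBodyMean = rep(NA_real_, nObj),
    trueDifference = rep(NA_real_, nObj)
  )
  if (nb > 0) {
    objects$row[1:nb] <- beads$row
    objects$col[1:nb] <- beads$col
    objects$radius[1:nb] <- beads$radius
    objects$rimThickness[1:nb] <- beads$rimThickness
    objects$bodyIntensity[1:nb] <- beads$bodyIntensity
    objects$rimIntensity[1:nb] <- beads$rimIntensity
    hasRim <- beads$rimThickness > 0
    objects$trueRingMean[1:nb] <- ifelse(hasRim, beads$rimIntensity,
                                         beads$bodyIntensity)
    objects$trueBodyMean[1:nb] <- beads$bodyIntensity
    objects$trueDifference[1:nb] <- objects$trueRingMean[1:nb] -
      objects$trueBodyMean[1:nb]
  }
  if (length(objs) > nb) {
    for (k in (nb + 1):length(objs)) {
      o <- objs[[k]]
      objects$row[k] <- if (!is.null(o[["row"]])) o[["row"]] else mean(o$rows)
      objects$col[k] <- if (!is.null(o[["col"]])) o[["col"]] else mean(o$cols)
    }
  }
  new("SimulatedScene",
      image = FluorImage(img, bitDepth = spec@bitDepth,
                         source = sprintf("synthetic(seed=%d)", spec@seed)),
      truth = new("GroundTruth", labels = labels, objects = objects),
      spec = spec)
}

#' @rdname renderScene
#' @export
renderControlScene <- function(spec) {
  b <- spec@beads
  if (nrow(b) > 0 && any(b$rimThickness > 0 & b$rimIntensity > b$bodyIntensity)) {
    stop("control scenes must not contain beads with a bright rim; ",
         "use uniform or dark-edged beads")
  }
  renderScene(spec)
}

#' Write a rendered scene to disk
#'
#' Writes the rendered image as a single-channel 8- or 16-bit TIFF, the
#' ground-truth label image as a 16-bit TIFF sidecar, and the per-object
#' truth table as JSON.
#'
#' @param scene A [SimulatedScene-class].
#' @param dir Output directory (created if missing).
#' @param basename File stem; files are `<stem>.tif`, `<stem>_labels.tif`,
#'   `<stem>_truth.json`.
#' @return Invisibly, the three paths written.
#' @export
writeScene <- function(scene, dir, basename = "scene") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  imgPath <- file.path(dir, paste0(basename, ".tif"))
  labPath <- file.path(dir, paste0(basename, "_labels.tif"))
  jsonPath <- file.path(dir, paste0(basename, "_truth.json"))
  writeFluorImage(scene@image, imgPath)
  tiff::writeTIFF(labelMatrix(scene@truth) / 65535, labPath,
                  bits.per.sample = 16L)
  jsonlite::write_json(truthTable(scene@truth), jsonPath, digits = NA,
                       na = "null")
  invisible(c(image = imgPath, labels = labPath, truth = jsonPath))
}
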