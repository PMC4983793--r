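# Independent brute-force oracles and shared fixture builders. The oracles
# deliberately use naive per-pixel loops so they share no code path with the
# package implementation.

# Ring/body means for one labelled bead by looping over every frame pixel:
# centroid and outer radius from the mask, then the documented band
# definition (ring: R - d + m < dist <= R - m; body: dist <= R - d - guard).
oracleRingBody <- function(img, labels, lab, rimFraction = 0.15,
                           minRimPx = 2, guardPx = 1, edgeMarginPx = 0.5) {
  px <- pixels(img)
  rs <- c(); cs <- c()
  for (r in seq_len(nrow(px))) for (c in seq_len(ncol(px))) {
    if (labels[r, c] == lab) { rs <- c(rs, r); cs <- c(cs, c) }
  }
  cr <- sum(rs) / length(rs); cc <- sum(cs) / length(cs)
  dc <- sqrt((rs - cr)^2 + (cs - cc)^2)
  rOut <- max(dc)
  d <- max(minRimPx, rimFraction * sqrt(length(rs) / pi))
  ringVals <- c(); bodyVals <- c()
  for (i in seq_along(rs)) {
    if (dc[i] > rOut - d + edgeMarginPx && dc[i] <= rOut - edgeMarginPx) {
      ringVals <- c(ringVals, px[rs[i], cs[i]])
    }
    if (dc[i] <= rOut - d - guardPx) {
      bodyVals <- c(bodyVals, px[rs[i], cs[i]])
    }
  }
  list(ringMean = mean(ringVals), bodyMean = mean(bodyVals),
       difference = mean(ringVals) - mean(bodyVals),
       nRing = length(ringVals), nBody = length(bodyVals))
}

# Jaccard overlap of one detected label against one ground-truth label.
maskJaccard <- function(detLabels, detLab, truthLabels, truthLab) {
  a <- detLabels == detLab
  b <- truthLabels == truthLab
  sum(a & b) / sum(a | b)
}

# Standard positive-IP scene: three well-separated rimmed beads.
positiveScene <- function(seed = 1L, rim = 1000, body = 300, bg = 20,
                          sigma = 0, shot = FALSE, radius = 18,
                          thickness = 3) {
  sceneSpec(imageShape = c(160L, 160L), backgroundIntensity = bg,
            beads = rbind(
              beadSpec(50, 50, radius, body, rim, thickness),
              beadSpec(50, 115, radius, body, rim, thickness),
              beadSpec(115, 80, radius, body, rim, thickness)),
            gaussianSigma = sigma, shotNoise = shot, seed = seed)
}

# Matched IgG-control scene: same geometry, dark-edged beads.
controlScene <- function(seed = 1L, rim = 240, body = 300, ...) {
  positiveScene(seed = seed, rim = rim, body = body, ...)
}
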