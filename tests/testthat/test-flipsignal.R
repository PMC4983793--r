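test_that("ring/body statistics equal the brute-force oracle exactly", {
  sp <- sceneSpec(imageShape = c(200, 200), backgroundIntensity = 10,
                  beads = rbind(
                    beadSpec(50, 50, 20, 200, 1000, 3),   # positive bead
                    beadSpec(60, 140, 18, 500),           # uniform bead
                    beadSpec(145, 95, 20, 300, 100, 3)))  # dark-edged control
  sc <- renderScene(sp)
  rg <- beadRegionsFromTruth(sceneTruth(sc))
  st <- ringBodyStats(sceneImage(sc), rg, rimParams(minRimPx = 3))
  for (i in 1:3) {
    o <- oracleRingBody(sceneImage(sc), labelMatrix(sceneTruth(sc)), i,
                        minRimPx = 3)
    expect_identical(st$ringMean[i], o$ringMean)
    expect_identical(st$bodyMean[i], o$bodyMean)
    expect_identical(st$difference[i], o$difference)
    expect_identical(st$ringPixelCount[i], o$nRing)
    expect_identical(st$bodyPixelCount[i], o$nBody)
  }
  # the noiseless values are the construction values themselves
  expect_identical(st$ringMean[1], 1000)
  expect_identical(st$bodyMean[1], 200)
  expect_identical(st$difference[1], 800)
  expect_identical(st$difference[2], 0)     # uniform bead
  expect_identical(st$difference[3], -200)  # dark edge: negative signal
  # ring and body are disjoint and both non-empty
  expect_true(all(st$ringPixelCount >= 1 & st$bodyPixelCount >= 1))
  expect_true(all(st$ringPixelCount + st$bodyPixelCount <=
                  regionTable(rg)$area[1:3]))
})

test_that("a uniform bead gives zero difference for any valid rim geometry", {
  sc <- renderScene(sceneSpec(imageShape = c(96, 96), backgroundIntensity = 10,
                              beads = beadSpec(48, 48, 18, 650)))
  rg <- beadRegionsFromTruth(sceneTruth(sc))
  for (p in list(rimParams(), rimParams(0.3, 4, 0, 0), rimParams(0.1, 1, 2))) {
    expect_identical(ringBodyStats(sceneImage(sc), rg, p)$difference, 0)
  }
})

test_that("degenerate beads raise an error naming the label", {
  sc <- renderScene(sceneSpec(imageShape = c(64, 64), backgroundIntensity = 10,
                              beads = beadSpec(32, 32, 4, 500)))
  rg <- beadRegionsFromTruth(sceneTruth(sc))
  expect_error(ringBodyStats(sceneImage(sc), rg,
                             rimParams(rimFraction = 0.5, minRimPx = 3,
                                       guardPx = 3)),
               "degenerate bead 1")
})

test_that("image signal averages per-bead differences and needs beads", {
  # one positive (diff 800) and one uniform (diff 0) bead -> mean 400
  sp <- sceneSpec(imageShape = c(160, 160), backgroundIntensity = 10,
                  beads = rbind(beadSpec(50, 50, 20, 200, 1000, 3),
                                beadSpec(110, 110, 20, 500)))
  sc <- renderScene(sp)
  res <- imageFlipSignal(sceneImage(sc), beadRegionsFromTruth(sceneTruth(sc)),
                         rimParams(minRimPx = 3))
  expect_identical(rawSignal(res), 400)
  expect_identical(nBeads(res), 2L)
  blank <- renderScene(sceneSpec(imageShape = c(64, 64),
                                 backgroundIntensity = 10))
  expect_error(imageFlipSignal(sceneImage(blank),
                               beadRegionsFromTruth(sceneTruth(blank))),
               "no usable beads")
})

test_that("the per-bead signal is invariant to bead count, the legacy mean is not", {
  mk <- function(n) {
    centres <- expand.grid(row = c(40, 100, 160), col = c(40, 100, 160))[1:n, ]
    sceneSpec(imageShape = c(200, 200), backgroundIntensity = 10,
              beads = beadSpec(centres$row, centres$col, 18,
                               rep(300, n), rep(1000, n), rep(3, n)))
  }
  sc2 <- renderScene(mk(2)); sc8 <- renderScene(mk(8))
  sig <- function(sc) rawSignal(imageFlipSignal(
    sceneImage(sc), detectBeads(sceneImage(sc))))
  expect_lt(abs(sig(sc2) - sig(sc8)), 1e-9)
  # the legacy whole-image mean scales with bead count
  blankImg <- sceneImage(renderScene(sceneSpec(imageShape = c(200, 200),
                                               backgroundIntensity = 10)))
  legacy2 <- globalMeanFlip(sceneImage(sc2), blankImg)
  legacy8 <- globalMeanFlip(sceneImage(sc8), blankImg)
  expect_gt(legacy8, legacy2 * 2)
})

test_that("control subtraction is exact signed arithmetic", {
  fr <- function(x) new("FlipResult", rawSignal = x, nBeads = 3L)
  expect_identical(correctedSignal(controlSubtract(fr(800), fr(-50))), 850)
  expect_identical(correctedSignal(controlSubtract(fr(42), fr(42))), 0)
  expect_identical(correctedSignal(controlSubtract(fr(0.3), fr(0.5))), -0.2)
  expect_error(controlSubtract(fr(1), NULL), "absent control")
  expect_error(controlSubtract(fr(1)), "absent control")
})

test_that("replicate merge takes the mean and reports the range as var.", {
  fr <- function(x) new("FlipResult", rawSignal = x, nBeads = 2L)
  m <- replicateMerge(list(fr(790), fr(810)))
  expect_identical(rawSignal(m), 800)
  expect_identical(variability(m), 20)
  expect_identical(replicateValues(m), c(790, 810))
  one <- replicateMerge(list(fr(800)))
  expect_identical(rawSignal(one), 800)
  expect_identical(variability(one), 0)
  expect_error(replicateMerge(list()), "at least one")
  # corrected replicates merge on the corrected scale
  cr <- function(x, c) controlSubtract(fr(x), fr(c))
  mc <- replicateMerge(list(cr(800, -50), cr(820, -40)))
  expect_identical(correctedSignal(mc), 855)
  expect_identical(variability(mc), 10)
})

test_that("merged noisy replicates land within 2% of the noiseless truth", {
  reps <- lapply(1:2, function(s) {
    sc <- renderScene(positiveScene(seed = s, sigma = 50, shot = TRUE))
    imageFlipSignal(sceneImage(sc), detectBeads(sceneImage(sc)))
  })
  merged <- replicateMerge(reps)
  expect_lt(abs(rawSignal(merged) - 700) / 700, 0.02)
  expect_gte(variability(merged), 0)
})

test_that("the legacy whole-image difference matches direct pixel means", {
  t1 <- FluorImage(matrix(60, 20, 20)); c1 <- FluorImage(matrix(10, 20, 20))
  expect_identical(globalMeanFlip(t1, c1), 50)
  half <- matrix(0, 20, 20); half[, 1:10] <- 100
  expect_identical(globalMeanFlip(FluorImage(half),
                                  FluorImage(matrix(0, 20, 20))), 50)
})

test_that("the raw signal increases strictly with rim intensity", {
  sig <- vapply(c(400, 600, 800, 1000), function(rim) {
    sc <- renderScene(positiveScene(rim = rim))
    rawSignal(imageFlipSignal(sceneImage(sc), detectBeads(sceneImage(sc))))
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("noiseless dilution series is linear in the rim intensity", {
  rims <- seq(400, 1200, by = 200)
  sig <- vapply(rims, function(rim) {
    sc <- renderScene(positiveScene(rim = rim))
    rawSignal(imageFlipSignal(sceneImage(sc), detectBeads(sceneImage(sc))))
  }, numeric(1))
  expect_gte(cor(sig, rims)^2, 0.95)
})
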