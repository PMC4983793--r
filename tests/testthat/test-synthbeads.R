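test_that("background-only scene renders a constant image with empty labels", {
  sc <- renderScene(sceneSpec(imageShape = c(40, 60), backgroundIntensity = 10))
  expect_true(all(pixels(sceneImage(sc)) == 10))
  expect_identical(dim(pixels(sceneImage(sc))), c(40L, 60L))
  expect_true(all(labelMatrix(sceneTruth(sc)) == 0L))
  expect_identical(nrow(truthTable(sceneTruth(sc))), 0L)
})

test_that("noiseless bead pixels match a per-pixel distance oracle", {
  sc <- renderScene(sceneSpec(imageShape = c(96, 96), backgroundIntensity = 10,
                              beads = beadSpec(48, 48, 20, 200, 1000, 3)))
  px <- pixels(sceneImage(sc))
  lab <- labelMatrix(sceneTruth(sc))
  for (r in seq_len(96)) for (c in seq_len(96)) {
    d <- sqrt((r - 48)^2 + (c - 48)^2)
    expected <- if (d > 20) 10 else if (d > 17) 1000 else 200
    expect_identical(px[r, c], expected)
    expect_identical(lab[r, c], if (d <= 20) 1L else 0L)
  }
  # ground-truth consistency: region means recomputed from the label image
  tt <- truthTable(sceneTruth(sc))
  expect_identical(tt$trueRingMean, 1000)
  expect_identical(tt$trueBodyMean, 200)
  expect_identical(tt$trueDifference, 800)
})

test_that("seed fully determines a noisy render", {
  sp <- function(seed) sceneSpec(imageShape = c(64, 64), backgroundIntensity = 50,
                                 beads = beadSpec(32, 32, 15, 400, 900, 3),
                                 gaussianSigma = 5, seed = seed)
  a <- renderScene(sp(7L)); b <- renderScene(sp(7L)); c <- renderScene(sp(8L))
  expect_identical(pixels(sceneImage(a)), pixels(sceneImage(b)))
  expect_false(identical(pixels(sceneImage(a)), pixels(sceneImage(c))))
  # noisy values are rounded integers within the bit-depth range
  expect_true(all(pixels(sceneImage(a)) == round(pixels(sceneImage(a)))))
  expect_gte(min(pixels(sceneImage(a))), 0)
})

test_that("control scenes carry dark-edged or uniform beads, never bright rims", {
  dark <- renderControlScene(sceneSpec(imageShape = c(80, 80),
    backgroundIntensity = 10, beads = beadSpec(40, 40, 15, 300, 100, 3)))
  expect_identical(truthTable(sceneTruth(dark))$trueDifference, -200)
  unif <- renderControlScene(sceneSpec(imageShape = c(80, 80),
    backgroundIntensity = 10, beads = beadSpec(40, 40, 15, 500)))
  expect_identical(truthTable(sceneTruth(unif))$trueDifference, 0)
  expect_error(renderControlScene(sceneSpec(imageShape = c(80, 80),
    backgroundIntensity = 10, beads = beadSpec(40, 40, 15, 200, 900, 3))),
    "bright rim")
})

test_that("invalid scene specifications are refused", {
  expect_error(renderScene(sceneSpec(imageShape = c(50, 50),
    beads = beadSpec(45, 45, 10, 100))), "outside the frame")
  # same bead allowed with the explicit clip flag
  expect_s4_class(renderScene(sceneSpec(imageShape = c(50, 50),
    beads = beadSpec(45, 45, 10, 100), allowClip = TRUE)), "SimulatedScene")
  expect_error(sceneSpec(imageShape = c(0, 50)), "positive")
  expect_error(renderScene(sceneSpec(beads = beadSpec(50, 50, 2, 100))),
               "radius")
  expect_error(renderScene(sceneSpec(beads = beadSpec(50, 50, 10, 100, 200, 10))),
               "rimThickness")
  expect_error(renderScene(sceneSpec(beads = beadSpec(50, 50, 10, 1e6))),
               "bit-depth")
})

test_that("noisy renders clip to the bit-depth range", {
  sp <- sceneSpec(imageShape = c(64, 64), backgroundIntensity = 5,
                  beads = beadSpec(32, 32, 15, 65000, 65530, 3),
                  gaussianSigma = 300, seed = 2L)
  px <- pixels(sceneImage(renderScene(sp)))
  expect_gte(min(px), 0)
  expect_lte(max(px), 65535)
  px8 <- pixels(sceneImage(renderScene(sceneSpec(imageShape = c(64, 64),
    backgroundIntensity = 5, beads = beadSpec(32, 32, 15, 200, 250, 3),
    gaussianSigma = 30, seed = 2L, bitDepth = 8L))))
  expect_lte(max(px8), 255)
})

test_that("zero-mean noise leaves region means unbiased", {
  # uniform control beads, Gaussian sigma 10: mean measured difference over
  # 20 seeded scenes stays within 3 units of 0
  diffs <- vapply(1:20, function(s) {
    sc <- renderControlScene(sceneSpec(imageShape = c(96, 96),
      backgroundIntensity = 10, beads = beadSpec(48, 48, 18, 500),
      gaussianSigma = 10, seed = s))
    st <- ringBodyStats(sceneImage(sc), beadRegionsFromTruth(sceneTruth(sc)))
    st$difference
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3)

  # ring mean of a rimmed bead converges to its noiseless value (3 SE)
  rings <- vapply(1:50, function(s) {
    sc <- renderScene(positiveScene(seed = s, sigma = 20,
                                    radius = 20, thickness = 4))
    st <- ringBodyStats(sceneImage(sc), beadRegionsFromTruth(sceneTruth(sc)))
    mean(st$ringMean)
  }, numeric(1))
  se <- sd(rings) / sqrt(length(rings))
  expect_lt(abs(mean(rings) - 1000), 3 * se)
})

test_that("overlapping beads render as a max-intensity union with one label each", {
  sp <- sceneSpec(imageShape = c(96, 128), backgroundIntensity = 10,
                  beads = rbind(beadSpec(48, 50, 15, 200, 800, 3),
                                beadSpec(48, 70, 15, 400, 600, 3)),
                  allowClip = TRUE)
  sc <- renderScene(sp)
  px <- pixels(sceneImage(sc)); lab <- labelMatrix(sceneTruth(sc))
  # a pixel in the overlap body region takes the max of the two body values
  expect_identical(px[48, 60], 400)
  expect_true(all(sort(unique(as.vector(lab))) == c(0L, 1L, 2L)))
})

test_that("a written scene round-trips through the TIFF reader bit-exactly", {
  dir <- withr::local_tempdir()
  sc <- renderScene(sceneSpec(imageShape = c(64, 64), backgroundIntensity = 30,
                              beads = beadSpec(32, 32, 14, 250, 900, 3),
                              gaussianSigma = 8, seed = 11L))
  paths <- writeScene(sc, dir, "fix")
  expect_true(all(file.exists(paths)))
  back <- readFluorImage(paths["image"])
  expect_identical(pixels(back), pixels(sceneImage(sc)))
  expect_identical(bitDepth(back), 16L)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$trueDifference, 650)
})
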