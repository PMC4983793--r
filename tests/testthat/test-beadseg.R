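test_that("blank and saturated images yield no regions", {
  blank <- FluorImage(matrix(500, 64, 64))
  expect_identical(nrow(regionTable(detectBeads(blank))), 0L)
  sat <- FluorImage(matrix(65535, 32, 32))
  expect_warning(rg <- detectBeads(sat), "saturated")
  expect_identical(nrow(regionTable(rg)), 0L)
  expect_true(rg@saturated)
})

test_that("noiseless beads are recovered with sub-pixel centroids and radii", {
  sp <- sceneSpec(imageShape = c(192, 192), backgroundIntensity = 20,
                  beads = rbind(beadSpec(50, 50, 15, 300, 1000, 3),
                                beadSpec(60, 130, 20, 300, 1000, 3),
                                beadSpec(140, 90, 25, 300, 1000, 4)))
  sc <- renderScene(sp)
  rg <- detectBeads(sceneImage(sc))
  r <- regionTable(rg)
  expect_identical(nrow(r), 3L)
  expect_true(all(r$retained))
  truth <- truthTable(sceneTruth(sc))
  # labels ordered by centroid row then column -> same order as the spec rows
  expect_true(all(abs(r$centroidRow - truth$row) <= 1))
  expect_true(all(abs(r$centroidCol - truth$col) <= 1))
  expect_true(all(abs(r$equivalentRadius - truth$radius) <= 1))
  for (i in 1:3) {
    expect_gte(maskJaccard(labelMatrix(rg), r$label[i],
                           labelMatrix(sceneTruth(sc)), truth$label[i]), 0.95)
  }
})

test_that("elongated contaminants are rejected as non-spherical", {
  a <- 30; b <- 10  # aspect ratio 3
  sp <- sceneSpec(imageShape = c(160, 160), backgroundIntensity = 20,
                  beads = beadSpec(50, 50, 18, 300, 1000, 3),
                  contaminants = list(
                    ellipseContaminant(110, 90, a, b, 0.4, 1000)))
  rg <- detectBeads(sceneImage(renderScene(sp)))
  r <- regionTable(rg)
  expect_identical(nrow(r), 2L)
  expect_identical(sum(r$retained), 1L)
  bad <- r[!r$retained, ]
  expect_identical(bad$reason, "non_spherical")
  # analytic oracle: circularity of the ideal ellipse is already below the
  # threshold (Ramanujan perimeter approximation)
  h <- ((a - b) / (a + b))^2
  perim <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_lt(4 * pi * (pi * a * b) / perim^2, 0.80)
  expect_lt(bad$circularity, 0.80)
})

test_that("overlapping bead pairs are rejected, isolated beads retained", {
  sp <- sceneSpec(imageShape = c(192, 192), backgroundIntensity = 20,
                  beads = rbind(beadSpec(50, 50, 18, 300, 1000, 3),
                                beadSpec(140, 40, 18, 300, 1000, 3),
                                beadSpec(140, 140, 18, 300, 1000, 3),
                                beadSpec(60, 130, 18, 300, 1000, 3),
                                beadSpec(60, 157, 18, 300, 1000, 3)),
                  allowClip = TRUE, seed = 5L)
  sc <- renderScene(sp)
  rg <- detectBeads(sceneImage(sc))
  r <- regionTable(rg)
  expect_identical(nrow(r), 4L)  # the pair merges into one component
  expect_identical(sum(r$retained), 3L)
  expect_true(r$reason[!r$retained] %in% c("non_spherical", "clump"))
  qc <- checkBeadDistribution(rg)
  expect_identical(qc$nRetained, 3L)
  expect_false(qc$monolayerFlag)
})

test_that("bead count is exact across seeded noisy scenes", {
  counts <- vapply(1:20, function(s) {
    sc <- renderScene(positiveScene(seed = s, sigma = 50, shot = TRUE))
    sum(regionTable(detectBeads(sceneImage(sc)))$retained)
  }, numeric(1))
  expect_true(all(counts == 3))
})

test_that("detection is deterministic", {
  sc <- renderScene(positiveScene(seed = 3L, sigma = 40, shot = TRUE))
  a <- detectBeads(sceneImage(sc))
  b <- detectBeads(sceneImage(sc))
  expect_identical(regionTable(a), regionTable(b))
  expect_identical(labelMatrix(a), labelMatrix(b))
})

test_that("border beads are rejected by default but configurable", {
  sp <- sceneSpec(imageShape = c(120, 120), backgroundIntensity = 20,
                  beads = rbind(beadSpec(60, 60, 15, 300, 1000, 3),
                                beadSpec(8, 60, 15, 300, 1000, 3)),
                  allowClip = TRUE)
  img <- sceneImage(renderScene(sp))
  r <- regionTable(detectBeads(img))
  expect_identical(r$reason[r$centroidRow < 20], "border")
  expect_identical(sum(r$retained), 1L)
  rAll <- regionTable(detectBeads(img, segParams(excludeBorder = FALSE)))
  expect_identical(sum(rAll$retained), 2L)
})

test_that("size filters reject beads outside the radius bounds", {
  sp <- sceneSpec(imageShape = c(140, 140), backgroundIntensity = 20,
                  beads = rbind(beadSpec(30, 30, 3.5, 1000),
                                beadSpec(80, 80, 20, 300, 1000, 3)))
  r <- regionTable(detectBeads(sceneImage(renderScene(sp))))
  expect_identical(r$reason[r$equivalentRadius < 5], "too_small")
  r2 <- regionTable(detectBeads(sceneImage(renderScene(sp)),
                                segParams(minRadius = 5, maxRadius = 15)))
  expect_identical(r2$reason[r2$equivalentRadius > 15], "too_large")
  expect_identical(sum(r2$retained), 0L)
})

test_that("the monolayer QC flag follows the retained-count and clump rules", {
  mkRegions <- function(nRetained, nClump) {
    n <- nRetained + nClump
    new("BeadRegions", labels = matrix(0L, 10, 10),
        regions = data.frame(
          label = seq_len(n), centroidRow = seq_len(n), centroidCol = 1,
          area = 10L, equivalentRadius = 5, circularity = 0.9, solidity = 1,
          retained = rep(c(TRUE, FALSE), c(nRetained, nClump)),
          reason = rep(c("none", "clump"), c(nRetained, nClump)),
          radiusRefined = FALSE),
        params = list())
  }
  ok <- checkBeadDistribution(mkRegions(10, 0))
  expect_false(ok$monolayerFlag)
  bad <- checkBeadDistribution(mkRegions(1, 9))
  expect_true(bad$monolayerFlag)
  expect_true("clump-dominated" %in% bad$flagReasons)
  expect_true("too-few-beads" %in% bad$flagReasons)
  expect_identical(bad$rejectionCounts$clump, 9L)
})

test_that("ground-truth regions mirror the scene and retain only beads", {
  sp <- sceneSpec(imageShape = c(160, 160), backgroundIntensity = 20,
                  beads = beadSpec(50, 50, 18, 300, 1000, 3),
                  contaminants = list(polygonContaminant(
                    c(100, 130, 130, 100), c(100, 95, 130, 125), 700)))
  sc <- renderScene(sp)
  rg <- beadRegionsFromTruth(sceneTruth(sc))
  r <- regionTable(rg)
  expect_identical(r$retained, c(TRUE, FALSE))
  expect_identical(r$reason[2], "non_spherical")
  expect_identical(labelMatrix(rg), labelMatrix(sceneTruth(sc)))
})
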