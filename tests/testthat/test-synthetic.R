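test_that("fbmSurface is deterministic, bounded and validates arguments", {
  s1 <- fbmSurface(64, 0.5, seed = 1)
  s2 <- fbmSurface(64, 0.5, seed = 1)
  expect_identical(surfaceGrid(s1), surfaceGrid(s2))
  expect_true(all(surfaceGrid(s1) >= 0 & surfaceGrid(s1) <= 255))
  expect_true(all(is.finite(surfaceGrid(s1))))
  expect_equal(theoreticalFD(s1), 2.5)
  expect_false(identical(surfaceGrid(s1), surfaceGrid(fbmSurface(64, 0.5, 2))))

  expect_error(fbmSurface(8, 0.5, 1), "at least 16")
  expect_error(fbmSurface(64, 0, 1), "strictly in")
  expect_error(fbmSurface(64, 1.2, 1), "strictly in")
})

test_that("larger Hurst gives smoother grids (lag-1 variation ordering)", {
  lag1 <- function(g) mean(abs(diff(g)))
  m01 <- mean(sapply(1:10, function(s) lag1(surfaceGrid(fbmSurface(64, 0.1, s)))))
  m05 <- mean(sapply(1:10, function(s) lag1(surfaceGrid(fbmSurface(64, 0.5, s)))))
  m09 <- mean(sapply(1:10, function(s) lag1(surfaceGrid(fbmSurface(64, 0.9, s)))))
  expect_gt(m01, m05)
  expect_gt(m05, m09)
})

test_that("fbmImage stacks three independent channels deterministically", {
  img <- fbmImage(32, 0.4, seed = 3)
  expect_identical(dim(img), c(32L, 32L, 3L))
  expect_identical(img, fbmImage(32, 0.4, seed = 3))
  expect_false(identical(img[, , 1], img[, , 2]))
})

test_that("syntheticLesion realizes compositions to within one pixel", {
  cs <- testClusters()
  les <- syntheticLesion(128, cs, c(cl1 = 0.4, cl2 = 0.3, cl5 = 0.3),
                         seed = 4, maskArea = 10000)
  expect_equal(sum(lesionMask(les)), 10000)
  expect_true(all(abs(les@counts - c(4000, 3000, 3000)) <= 1))

  # every in-mask pixel lies inside exactly one generating box
  img <- lesionImage(les)
  msk <- lesionMask(les)
  b <- clusterBoxes(cs)[clusterBoxes(cs)$id %in% c("cl1", "cl2", "cl5"), ]
  r <- img[, , 1][msk]; g <- img[, , 2][msk]; bl <- img[, , 3][msk]
  nHits <- Reduce(`+`, lapply(seq_len(nrow(b)), function(i)
    (r >= b$rmin[i] & r <= b$rmax[i] & g >= b$gmin[i] & g <= b$gmax[i] &
     bl >= b$bmin[i] & bl <= b$bmax[i]) * 1L))
  expect_true(all(nHits == 1L))

  # degenerate one-cluster mixture
  les1 <- syntheticLesion(64, cs, c(cl1 = 1.0), seed = 5)
  pct <- clusterPercentages(lesionImage(les1), lesionMask(les1), cs)
  expect_equal(unname(pct["cl1"]), 100)

  expect_identical(lesionImage(syntheticLesion(64, cs, c(cl1 = 1), seed = 9)),
                   lesionImage(syntheticLesion(64, cs, c(cl1 = 1), seed = 9)))
})

test_that("syntheticLesion rejects bad compositions, overlap and skin clash", {
  cs <- testClusters()
  expect_error(syntheticLesion(64, cs, c(cl1 = 0.5, cl2 = 0.4), seed = 1),
               "sum to 1")
  expect_error(syntheticLesion(64, cs, c(nope = 1), seed = 1),
               "cluster ids")
  over <- ColorClusterSet(data.frame(
    id = c("a", "b"), rmin = c(0, 20), rmax = c(40, 60),
    gmin = c(0, 20), gmax = c(40, 60), bmin = c(0, 20), bmax = c(40, 60)))
  expect_error(syntheticLesion(64, over, c(a = 0.5, b = 0.5), seed = 1),
               "overlap")
  expect_error(syntheticLesion(64, cs, c(cl1 = 1), seed = 1,
                               skinColor = c(20, 20, 20)),
               "inside cluster box")
})

test_that("twoClassTable controls effects and is reproducible", {
  t1 <- twoClassTable(100, nInformative = 3, nNoise = 5, effect = 0, seed = 1)
  expect_identical(featureMatrix(t1),
                   featureMatrix(twoClassTable(100, 3, 5, 0, seed = 1)))
  expect_identical(levels(sampleLabels(t1)), c("nevus", "melanoma"))
  # null case: no column separates the classes strongly
  tt <- apply(featureMatrix(t1), 2, function(v)
    abs(stats::t.test(v ~ sampleLabels(t1))$statistic))
  expect_true(all(tt < 4))

  t2 <- twoClassTable(50, nInformative = 4, nNoise = 0, effect = 3, seed = 2)
  p <- apply(featureMatrix(t2), 2, function(v)
    stats::t.test(v ~ sampleLabels(t2))$p.value)
  expect_true(all(p < 0.05))
  expect_equal(t2@effectSizes, rep(3, 4))

  expect_error(twoClassTable(1, 1, 1, 1, 1), "at least 2")
})

test_that("lesion and surface writers produce readable files with sidecars", {
  tmp <- withr::local_tempdir()
  cs <- testClusters()
  les <- syntheticLesion(32, cs, c(cl1 = 0.5, cl2 = 0.5), seed = 1)
  paths <- writeLesion(les, file.path(tmp, "les.png"))
  img <- readRGBImage(paths["image"])
  expect_identical(img, lesionImage(les))
  expect_identical(readMask(paths["mask"]), lesionMask(les))
  side <- jsonlite::fromJSON(paths["json"])
  expect_equal(side$composition$cl1, 0.5)
  expect_equal(side$maskArea, sum(lesionMask(les)))

  s <- fbmSurface(32, 0.3, 1)
  sp <- writeSurface(s, file.path(tmp, "surf.png"))
  expect_equal(readRGBImage(sp["image"])[, , 1], surfaceGrid(s))
  expect_equal(jsonlite::fromJSON(sp["json"])$hurst, 0.3)
})
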