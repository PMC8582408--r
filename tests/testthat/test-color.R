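test_that("the packaged default set has 23 valid, pairwise disjoint boxes", {
  cs <- defaultClusterSet()
  expect_equal(nClusters(cs), 23)
  expect_identical(clusterIds(cs), paste0("cl", 1:23))
  b <- clusterBoxes(cs)
  expect_true(all(b$rmin <= b$rmax & b$gmin <= b$gmax & b$bmin <= b$bmax))
  expect_equal(nrow(fractalDerm:::overlappingBoxes(b)), 0)
})

test_that("loadClusterSet validates files and names offenders", {
  tmp <- withr::local_tempdir()
  bad <- file.path(tmp, "bad.csv")
  write.csv(data.frame(id = "clX", rmin = 200, rmax = 100, gmin = 0,
                       gmax = 10, bmin = 0, bmax = 10), bad,
            row.names = FALSE)
  expect_error(loadClusterSet(bad), "clX")

  dup <- file.path(tmp, "dup.csv")
  write.csv(data.frame(id = c("a", "a"), rmin = 0, rmax = 1, gmin = 0,
                       gmax = 1, bmin = 0, bmax = 1), dup, row.names = FALSE)
  expect_error(loadClusterSet(dup), "duplicate")

  three <- file.path(tmp, "three.csv")
  write.csv(clusterBoxes(defaultClusterSet())[1:3, ], three,
            row.names = FALSE)
  expect_equal(nClusters(loadClusterSet(three)), 3)

  js <- file.path(tmp, "set.json")
  jsonlite::write_json(clusterBoxes(defaultClusterSet())[1:2, ], js)
  expect_equal(nClusters(loadClusterSet(js)), 2)

  expect_error(loadClusterSet(file.path(tmp, "missing.csv")), "not found")
})

test_that("assignPixel uses inclusive bounds and the first-match rule", {
  cs <- testClusters()
  b <- clusterBoxes(cs)
  corner <- c(b$rmin[3], b$gmin[3], b$bmin[3])
  expect_identical(assignPixel(corner, cs), "cl3")
  expect_identical(assignPixel(c(b$rmax[1], b$gmax[1], b$bmax[1]), cs), "cl1")
  expect_true(is.na(assignPixel(c(255, 0, 255), cs)))

  over <- ColorClusterSet(data.frame(
    id = c("first", "second"), rmin = c(0, 0), rmax = c(50, 50),
    gmin = c(0, 0), gmax = c(50, 50), bmin = c(0, 0), bmax = c(50, 50)))
  expect_identical(assignPixel(c(25, 25, 25), over), "first")
})

test_that("clusterPercentages recovers generated compositions exactly", {
  cs <- testClusters()
  comp <- c(cl1 = 0.4, cl2 = 0.3, cl5 = 0.3)
  les <- syntheticLesion(128, cs, comp, seed = 8, maskArea = 10000)
  pct <- clusterPercentages(lesionImage(les), lesionMask(les), cs)
  expect_true(all(abs(pct[names(comp)] - 100 * comp) <= 0.01))
  expect_equal(unname(pct["cl3"]), 0)
  expect_equal(unname(pct["unassigned"]), 0)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
})

test_that("percentages are conserved and invariant to transposition", {
  cs <- testClusters()
  les <- syntheticLesion(64, cs, c(cl2 = 0.7, cl3 = 0.3), seed = 9)
  img <- lesionImage(les)
  msk <- lesionMask(les)
  pct <- clusterPercentages(img, msk, cs)
  tImg <- aperm(img, c(2, 1, 3))
  expect_identical(pct, clusterPercentages(tImg, t(msk), cs))

  # with disjoint boxes the list order is irrelevant
  rev <- ColorClusterSet(clusterBoxes(cs)[4:1, ])
  pr <- clusterPercentages(img, msk, rev)
  expect_equal(pr[names(pct)[1:4]], pct[1:4])
})

test_that("clusterPercentages validates masks", {
  cs <- testClusters()
  les <- syntheticLesion(32, cs, c(cl1 = 1), seed = 1)
  empty <- matrix(FALSE, 32, 32)
  expect_error(clusterPercentages(lesionImage(les), empty, cs),
               "at least 1 pixel")
  expect_error(clusterPercentages(lesionImage(les), matrix(TRUE, 16, 16), cs),
               "shape")
})

test_that("subsetClusters keeps requested boxes in order", {
  cs <- defaultClusterSet()
  sub <- subsetClusters(cs, c("cl5", "cl1"))
  expect_identical(clusterIds(sub), c("cl5", "cl1"))
  expect_error(subsetClusters(cs, "nope"), "unknown cluster id")
})
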