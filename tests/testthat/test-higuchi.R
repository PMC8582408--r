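test_that("subsampleMatrix follows the k-step, offset-m index arithmetic", {
  g <- outer(1:5, 1:5, function(i, j) 10 * i + j)

  expect_identical(subsampleMatrix(g, k = 1, m = 1), g)

  x <- subsampleMatrix(g, k = 2, m = 1)
  expect_equal(x, matrix(c(11, 13, 15, 31, 33, 35, 51, 53, 55), 3,
                         byrow = TRUE))

  x <- subsampleMatrix(g, k = 3, m = 2)
  expect_equal(x, g[c(2, 5), c(2, 5)])

  expect_error(subsampleMatrix(g, k = 2, m = 3), "1 <= m <= k")
  expect_error(subsampleMatrix(g, k = 5, m = 1), "at most")
})

test_that("areaEstimate matches a hand-computed single-cell sum", {
  g <- matrix(c(0, 1, 0,
                1, 2, 1,
                0, 1, 0), 3, byrow = TRUE)
  # all four cells contribute 1*1*1*1; xi = 1/2 * (2/2) * (2/2)
  expect_equal(areaEstimate(g, k = 1, m = 1), 0.5 * 4)
  expect_equal(areaEstimate(matrix(7, 10, 10), k = 2, m = 1), 0)
  expect_error(areaEstimate(matrix(1:4, 2), k = 1, m = 1), NA)
})

test_that("corrected and as_printed modes are distinct and non-negative", {
  set.seed(42)
  g <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
  a1 <- areaEstimate(g, k = 3, m = 2, mode = "corrected")
  a2 <- areaEstimate(g, k = 3, m = 2, mode = "as_printed")
  expect_gte(a1, 0)
  expect_gte(a2, 0)
  expect_false(isTRUE(all.equal(a1, a2)))
})

test_that("averageArea is the mean of the per-offset estimates", {
  set.seed(7)
  g <- matrix(runif(20 * 20, 0, 255), 20, 20)
  expect_equal(averageArea(g, 1), areaEstimate(g, 1, 1))
  expect_equal(averageArea(g, 2),
               mean(c(areaEstimate(g, 2, 1), areaEstimate(g, 2, 2))))
  expect_equal(averageArea(matrix(3, 20, 20), 4), 0)
})

test_that("channelHFD errors on degenerate (flat) surfaces naming the scale", {
  expect_error(channelHFD(matrix(5, 32, 32)), "degenerate.*k = 1")
  img <- fbmImage(32, 0.5, 1)
  img[, , 2] <- 100
  expect_error(imageHFD(img), "channel G")
})

test_that("white noise estimates near 3 and a smooth ramp near 1", {
  set.seed(1)
  wn <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  expect_gt(channelHFD(wn)$hfd, 2.8)
  ramp <- outer(1:64, 1:64, function(i, j) (i + j) * 2 - 3)
  expect_lt(channelHFD(ramp)$hfd, 1.2)
})

test_that("vertical intensity scaling multiplies areas by c^4, slope fixed", {
  set.seed(11)
  g <- matrix(runif(32 * 32, 0, 255), 32, 32)
  base <- channelHFD(g)
  for (cc in c(0.5, 3)) {
    sc <- channelHFD(cc * g)
    expect_equal(sc$areas, cc^4 * base$areas, tolerance = 1e-12)
    expect_equal(sc$slope, base$slope, tolerance = 1e-9)
    expect_equal(sc$hfd, base$hfd, tolerance = 1e-9)
  }
})

test_that("HFD is invariant to transposition of a square channel", {
  set.seed(3)
  g <- matrix(runif(24 * 24, 0, 255), 24, 24)
  expect_equal(channelHFD(g)$hfd, channelHFD(t(g))$hfd, tolerance = 1e-12)
})

test_that("identical channels give identical per-channel and mean HFD", {
  g <- surfaceGrid(fbmSurface(32, 0.5, 9))
  img <- array(rep(g, 3), c(32, 32, 3))
  res <- imageHFD(img)
  h <- vapply(hfdChannels(res), `[[`, numeric(1), "hfd")
  expect_equal(unname(h), rep(meanHFD(res), 3))
})

test_that("rougher fBm surfaces (small Hurst) yield larger channel HFD", {
  h02 <- mean(sapply(1:10, function(s)
    channelHFD(surfaceGrid(fbmSurface(64, 0.2, s)))$hfd))
  h08 <- mean(sapply(1:10, function(s)
    channelHFD(surfaceGrid(fbmSurface(64, 0.8, s)))$hfd))
  expect_gt(h02, h08)
  expect_gt(h02, 1)
  expect_lt(h02, 3)
})

test_that("mean HFD is reported raw with a clamped copy alongside", {
  img <- fbmImage(48, 0.9, 2)   # smooth: raw estimate falls below 2
  res <- imageHFD(img)
  expect_lt(meanHFD(res), res@meanHFDClamped + 1e-12)
  expect_gte(res@meanHFDClamped, 2)
  expect_lte(res@meanHFDClamped, 3)
})

test_that("offsets that leave no complete grid cell are rejected", {
  g <- matrix(runif(100, 0, 255), 10, 10)
  expect_error(areaEstimate(g, k = 8, m = 8), "smaller than 2x2")
})
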