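test_that("knnPredict matches a brute-force neighbor oracle", {
  set.seed(1)
  train <- matrix(rnorm(40), 20, 2)
  y <- factor(rep(c("nevus", "melanoma"), 10), levels = c("nevus", "melanoma"))
  query <- matrix(rnorm(14), 7, 2)
  for (k in c(1, 3, 5)) {
    got <- knnPredict(train, y, query, k = k)
    ref <- refKnn(train, y, query, k = k)
    expect_equal(got$scores, ref$scores)
    expect_equal(as.character(got$labels), ref$labels)
  }

  # five hand-placed points, k = 3: the neighbor set is unambiguous
  tr <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5, 6, 5), 5, 2, byrow = TRUE)
  yy <- factor(c("a", "a", "b", "b", "b"))
  got <- knnPredict(tr, yy, matrix(c(0.2, 0.2), 1), k = 3)
  expect_equal(got$scores, 1 / 3)
  expect_identical(as.character(got$labels), "a")
})

test_that("knnPredict handles degenerate and invalid configurations", {
  tr <- matrix(c(0, 0), 1, 2)
  y <- factor("melanoma", levels = c("nevus", "melanoma"))
  got <- knnPredict(tr, y, matrix(c(9, 9), 1), k = 1)
  expect_identical(as.character(got$labels), "melanoma")

  tr2 <- matrix(rnorm(20), 10, 2)
  y2 <- factor(rep(c("nevus", "melanoma"), 5))
  expect_identical(as.character(knnPredict(tr2, y2, tr2[3, ], k = 1)$labels),
                   as.character(y2[3]))
  expect_error(knnPredict(tr2, y2, tr2[1, ], k = 11), "exceed")
  expect_error(knnPredict(tr2, y2, tr2[1, ], k = 4), "odd")
  expect_error(knnPredict(tr2, y2, c(1, 2, 3), k = 1), "dimensions")
})

test_that("distance ties at the neighborhood boundary prefer lower indices", {
  # four equidistant training points around the origin, different labels
  tr <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1), 4, 2, byrow = TRUE)
  y <- factor(c("melanoma", "nevus", "nevus", "nevus"),
              levels = c("nevus", "melanoma"))
  got <- knnPredict(tr, y, matrix(c(0, 0), 1), k = 1)
  expect_identical(as.character(got$labels), "melanoma")  # index 1 wins
})

test_that("makeFolds is stratified, balanced and deterministic", {
  y <- factor(rep(c("nevus", "melanoma"), c(50, 53)))
  f1 <- makeFolds(y, 5, seed = 1)
  expect_identical(f1, makeFolds(y, 5, seed = 1))
  expect_identical(sort(as.integer(table(f1)), decreasing = TRUE),
                   c(21L, 21L, 21L, 20L, 20L))
  perClass <- table(y, f1)
  expect_true(all(abs(perClass - rowMeans(perClass)) <= 1))
  expect_error(makeFolds(factor(rep(c("a", "b"), c(3, 60))), 5),
               "at least as many samples")
})

test_that("runCV pools every sample exactly once and is seed-stable", {
  tab <- twoClassTable(30, 2, 2, effect = 2, seed = 1)
  cv <- runCV(tab, model = "knn", seed = 7)
  expect_equal(sort(unlist(lapply(cv@perFold, `[[`, "test"))), 1:60)
  m <- pooledMetrics(cv)
  expect_equal(m@tp + m@fp + m@fn + m@tn, 60L)
  cv2 <- runCV(tab, model = "knn", seed = 7)
  expect_identical(foldAssignments(cv), foldAssignments(cv2))
  expect_identical(pooledPredictions(cv), pooledPredictions(cv2))
})

test_that("pooled CV metrics are invariant to sample order for fixed folds", {
  tab <- twoClassTable(25, 2, 3, effect = 1.5, seed = 2)
  x <- featureMatrix(tab)
  y <- sampleLabels(tab)
  base <- runCV(x, y, model = "knn", seed = 3)
  perm <- sample(nrow(x))
  permuted <- runCV(x[perm, ], y[perm], model = "knn", seed = 3,
                    foldAssign = foldAssignments(base)[perm])
  expect_equal(pooledMetrics(base)@accuracy, pooledMetrics(permuted)@accuracy)
  expect_equal(pooledScores(base)[perm], pooledScores(permuted))
})

test_that("RBFNN training interpolates small exact problems", {
  xor <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- factor(c("a", "b", "b", "a"))
  m <- trainRBFNN(xor, y, maxNeurons = 4, spread = 0.5, standardize = FALSE,
                  mseGoal = 1e-12)
  pr <- predictRBFNN(m, xor)
  expect_identical(as.character(pr$labels), as.character(y))

  set.seed(4)
  x <- matrix(rnorm(16), 8, 2)
  y8 <- factor(rep(c("a", "b"), 4))
  m8 <- trainRBFNN(x, y8, maxNeurons = 8, spread = 0.3, standardize = FALSE,
                   mseGoal = 1e-10)
  expect_lt(tail(mseTrajectory(m8), 1), 1e-6)
})

test_that("RBFNN trajectory is non-increasing and respects halting rules", {
  tab <- twoClassTable(40, 2, 3, effect = 1, seed = 5)
  m <- trainRBFNN(tab, maxNeurons = 20, mseGoal = 0.01)
  tr <- mseTrajectory(m)
  expect_true(all(diff(tr) <= 1e-10))
  expect_true(tail(tr, 1) <= 0.01 || nrow(rbfCenters(m)) == 20)
  expect_equal(length(tr), nrow(rbfCenters(m)) + 1)  # includes 0-neuron MSE
})

test_that("a 0-neuron RBFNN is the bias-only majority solution", {
  x <- matrix(rnorm(60), 30, 2)
  y <- factor(rep(c("nevus", "melanoma"), c(20, 10)),
              levels = c("nevus", "melanoma"))
  m <- trainRBFNN(x, y, maxNeurons = 0)
  expect_equal(nrow(rbfCenters(m)), 0)
  pr <- predictRBFNN(m, matrix(rnorm(10), 5, 2))
  expect_true(all(pr$labels == "nevus"))   # majority class everywhere
  expect_equal(unname(m@weights[1, ]), c(2 / 3, 1 / 3), tolerance = 1e-9)
})

test_that("RBFNN round-trips through JSON serialization", {
  tab <- twoClassTable(20, 2, 1, effect = 2, seed = 6)
  m <- trainRBFNN(tab, maxNeurons = 10)
  tmp <- withr::local_tempfile(fileext = ".json")
  writeRBFNN(m, tmp)
  m2 <- readRBFNN(tmp)
  q <- featureMatrix(tab)[1:5, ]
  expect_equal(predictRBFNN(m, q)$outputs, predictRBFNN(m2, q)$outputs,
               tolerance = 1e-12)
})

test_that("kNN cross-validation is uninformative at zero effect", {
  accs <- sapply(1:5, function(s) {
    tab <- twoClassTable(50, 0, 5, effect = 0, seed = 100 + s)
    pooledMetrics(runCV(tab, model = "knn", seed = s))@accuracy
  })
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})
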