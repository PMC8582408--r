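makeConfusion <- function(tp, fn, fp, tn) {
  labels <- rep(c("melanoma", "nevus"), c(tp + fn, fp + tn))
  preds <- c(rep(c("melanoma", "nevus"), c(tp, fn)),
             rep(c("melanoma", "nevus"), c(fp, tn)))
  list(labels = factor(labels, levels = c("nevus", "melanoma")),
       preds = factor(preds, levels = c("nevus", "melanoma")))
}

test_that("the worked confusion example evaluates exactly", {
  cf <- makeConfusion(tp = 8, fn = 2, fp = 3, tn = 7)
  m <- computeMetrics(cf$labels, cf$preds)
  expect_equal(m@sensitivity, 0.800)
  expect_equal(m@precision, 8 / 11)
  expect_equal(m@accuracy, 0.750)
  expect_equal(m@dice, 16 / 21)
  expect_identical(c(m@tp, m@fp, m@fn, m@tn), c(8L, 3L, 2L, 7L))
})

test_that("AUC is the Mann-Whitney rank statistic", {
  labels <- factor(rep(c("nevus", "melanoma"), each = 10),
                   levels = c("nevus", "melanoma"))
  perfect <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  m <- computeMetrics(labels, labels, scores = perfect)
  expect_equal(m@auc, 1.0)

  set.seed(1)
  sc <- rnorm(20)
  m2 <- computeMetrics(labels, labels, scores = sc)
  ref <- pROC::auc(pROC::roc(labels, sc, levels = c("nevus", "melanoma"),
                             direction = "<", quiet = TRUE))
  expect_equal(m2@auc, as.numeric(ref))
})

test_that("swapping the positive class maps AUC to 1 - AUC", {
  set.seed(2)
  labels <- factor(sample(rep(c("nevus", "melanoma"), 15)),
                   levels = c("nevus", "melanoma"))
  sc <- rnorm(30)
  a <- computeMetrics(labels, labels, scores = sc)@auc
  flipped <- factor(as.character(labels), levels = c("melanoma", "nevus"))
  b <- computeMetrics(flipped, flipped, scores = -sc)@auc   # same ordering
  expect_equal(a, b)
  bSwap <- computeMetrics(flipped, flipped, scores = sc)@auc
  expect_equal(bSwap, 1 - a)
})

test_that("Dice equals the precision/sensitivity harmonic mean", {
  set.seed(3)
  for (i in 1:20) {
    counts <- sample(0:30, 4, replace = TRUE)
    if (counts[1] == 0) counts[1] <- 1   # keep tp > 0 so both are defined
    cf <- makeConfusion(counts[1], counts[2], counts[3], counts[4])
    m <- suppressWarnings(computeMetrics(cf$labels, cf$preds))
    if (!is.na(m@precision) && !is.na(m@sensitivity)) {
      expect_equal(m@dice, 2 * m@precision * m@sensitivity /
                             (m@precision + m@sensitivity))
    }
  }
})

test_that("zero denominators give NA with a warning, not 0", {
  labels <- factor(rep("nevus", 5), levels = c("nevus", "melanoma"))
  w <- capture_warnings(m <- computeMetrics(labels, labels))
  expect_true(any(grepl("sensitivity undefined", w)))
  expect_true(is.na(m@sensitivity))
  expect_true(is.na(m@precision))
  expect_equal(m@accuracy, 1)
})

test_that("MSE follows the one-hot output convention and flags surrogates", {
  labels <- factor(c("nevus", "melanoma"), levels = c("nevus", "melanoma"))
  outputs <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  m <- computeMetrics(labels, labels, scores = c(0.1, 0.8),
                      outputs = outputs)
  expect_equal(m@mse, mean(c(0.1, 0.1, 0.2, 0.2)^2))
  expect_true(m@mseComparable)

  m2 <- computeMetrics(labels, labels, scores = c(0.1, 0.8))
  expect_equal(m2@mse, mean(c(0.1, 0.2)^2))
  expect_false(m2@mseComparable)
})

test_that("length mismatches are rejected", {
  labels <- factor(c("nevus", "melanoma"))
  expect_error(computeMetrics(labels, labels[1]), "length")
  expect_error(computeMetrics(labels, labels, scores = 1), "length")
})

test_that("renderReport emits per-fold and pooled rows that reconcile", {
  tab <- twoClassTable(50, 3, 2, effect = 2, seed = 4)
  cv <- runCV(tab, model = "rbfnn", seed = 1)
  rep <- renderReport(cv, "synthetic")
  expect_equal(nrow(rep), 6)
  expect_identical(rep$fold, c(as.character(1:5), "pooled"))

  pooled <- rep[rep$fold == "pooled", ]
  m <- pooledMetrics(cv)
  expect_equal(pooled$accuracy_pct, round(100 * m@accuracy, 2))
  expect_equal(pooled$n, 100)
  expect_false(is.na(pooled$n_hidden))

  # balanced folds: fold accuracies average to the pooled accuracy (within 1%)
  foldAcc <- rep$accuracy_pct[rep$fold != "pooled"]
  expect_lt(abs(mean(foldAcc) - pooled$accuracy_pct), 1)

  tmp <- withr::local_tempfile(fileext = ".csv")
  renderReport(cv, "synthetic", path = tmp)
  expect_identical(read.csv(tmp)$fold, c(as.character(1:5), "pooled"))
})

test_that("renderReport can reproduce a published-style report row", {
  # pooled counts tp=25, fn=5, fp=15, tn=52 (n=97) with binary scores
  cf <- makeConfusion(25, 5, 15, 52)
  m <- computeMetrics(cf$labels, cf$preds,
                      scores = as.numeric(cf$preds == "melanoma"))
  expect_equal(round(100 * m@sensitivity, 2), 83.33)
  expect_equal(round(100 * m@accuracy, 2), 79.38)
  expect_equal(round(100 * m@precision, 2), 62.50)
  expect_equal(round(m@auc, 4), 0.8047)
  expect_equal(round(m@dice, 4), 0.7143)
})
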