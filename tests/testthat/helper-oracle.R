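# Loop-literal reference implementation of the 2D Higuchi surface-area
# estimator, written directly from the index arithmetic with explicit loops.
# It is deliberately independent of the vectorized production code and serves
# as its oracle.

refAreaEstimate <- function(g, k, m, mode = "corrected") {
  storage.mode(g) <- "double"   # 8-bit difference products overflow ints
  M <- nrow(g)
  N <- ncol(g)
  P <- floor((M - m) / k)
  S <- floor((N - m) / k)
  total <- 0
  for (i in seq_len(P)) {
    for (j in seq_len(S)) {
      f1 <- abs(g[m + (i - 1) * k, m + j * k] -
                g[m + (i - 1) * k, m + (j - 1) * k])
      f2 <- if (mode == "corrected") {
        abs(g[m + i * k, m + j * k] - g[m + (i - 1) * k, m + j * k])
      } else {
        abs(g[m + i * k, m + j * k] - g[m + (i - 1) * k, m + k])
      }
      f3 <- abs(g[m + i * k, m + j * k] - g[m + i * k, m + (j - 1) * k])
      f4 <- abs(g[m + i * k, m + (j - 1) * k] -
                g[m + (i - 1) * k, m + (j - 1) * k])
      total <- total + f1 * f2 * f3 * f4
    }
  }
  xi <- 1 / (2 * k^4) * (N - 1) / S * (M - 1) / P
  xi * total
}

refAverageArea <- function(g, k, mode = "corrected") {
  vals <- numeric(k)
  for (m in seq_len(k)) vals[m] <- refAreaEstimate(g, k, m, mode)
  mean(vals)
}

refChannelHFD <- function(g, kMax = 8, mode = "corrected",
                          fitScale = "inverse_k_squared") {
  areas <- numeric(kMax)
  for (k in seq_len(kMax)) areas[k] <- refAverageArea(g, k, mode)
  x <- if (fitScale == "inverse_k_squared") log(1 / (1:kMax)^2)
       else log((1:kMax)^2)
  fit <- stats::lm(log(areas) ~ x)
  slope <- unname(stats::coef(fit)[2])
  list(areas = areas, slope = slope, hfd = slope + 1,
       rSquared = summary(fit)$r.squared)
}

# Brute-force kNN oracle: full distance sort with index tie-break.
refKnn <- function(train, labels, query, k) {
  pos <- levels(labels)[nlevels(labels)]
  scores <- apply(query, 1, function(q) {
    d <- sqrt(colSums((t(train) - q)^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    mean(labels[nb] == pos)
  })
  list(scores = as.numeric(scores),
       labels = ifelse(scores > 0.5, pos, levels(labels)[1]))
}
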