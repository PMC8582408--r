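# Shared fixtures built in code.

# Small disjoint cluster set with dark lesion colors on a light background;
# narrow boxes keep within-lesion texture mild for the hair-removal tests.
testClusters <- function() {
  ColorClusterSet(data.frame(
    id = c("cl1", "cl2", "cl3", "cl5"),
    rmin = c(10, 60, 110, 160), rmax = c(40, 90, 140, 190),
    gmin = c(10, 40, 70, 100), gmax = c(40, 70, 100, 130),
    bmin = c(10, 30, 50, 70), bmax = c(40, 60, 80, 100)))
}

tightClusters <- function() {
  ColorClusterSet(data.frame(
    id = c("dk", "md"),
    rmin = c(30, 80), rmax = c(36, 86),
    gmin = c(20, 60), gmax = c(26, 66),
    bmin = c(20, 50), bmax = c(26, 56)))
}

# Deterministic Hurst sweep used by the HFD band and monotonicity checks
# (9 Hurst values x 20 seeds, 128x128 RGB, kMax = 8). Computed once per
# session and cached.
acceptanceSweep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      hs <- seq(0.1, 0.9, by = 0.1)
      cfg <- hfdConfig(kMax = 8)
      vals <- sapply(hs, function(h) {
        sapply(1:20, function(s) {
          meanHFD(imageHFD(fbmImage(128, h, seed = round(1000 * h) + s), cfg))
        })
      })
      colnames(vals) <- paste0("H", hs)
      cache <<- vals
    }
    cache
  }
})
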