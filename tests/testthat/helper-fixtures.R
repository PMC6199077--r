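# Shared fixtures, built once per test run and cached. Problem sizes are
# scaled to keep the suite fast: the detector is trained for 200 epochs on
# the 1008-patch augmented set (the classic recipe runs 2000; the loss is
# flat long before 200 on well-separated synthetic patches).

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- build()
  .fixtureCache[[key]]
}

# Full detector chain on a surface at 11 tips/um^2 (5 x 5 um, 10 nm/px).
trainedChain <- function() {
  .cached("chain", function() {
    truth <- generatePattern(11, 5000, 5000, exclusionRadius = 150,
                             seed = 401)
    img <- renderMicrograph(truth, pixelSize = 10, tipWidth = 110,
                            peakIntensity = 180, backgroundLevel = 40,
                            noiseSd = 8, seed = 402)
    base <- samplePatches(img, truth, nPerClass = 7, seed = 403)
    aug <- augmentPatches(base)
    net <- trainNetwork(initNetwork(seed = 404), aug, epochs = 200,
                        learningRate = 0.1, seed = 405)
    list(truth = truth, img = img, base = base, aug = aug, net = net)
  })
}

# Short-range-ordered pattern with characteristic spacing 306 nm at
# 10 tips/um^2 on a 10 x 10 um field (the printed study conditions).
orderedPattern306 <- function() {
  .cached("ordered306", function()
    generatePattern(10, 10000, 10000, exclusionRadius = 150, spacing = 306,
                    seed = 1))
}

# Rendered micrograph of that pattern at 10 nm/px.
orderedRender306 <- function() {
  .cached("render306", function()
    renderMicrograph(orderedPattern306(), pixelSize = 10, tipWidth = 110,
                     peakIntensity = 180, backgroundLevel = 40, noiseSd = 8,
                     seed = 2))
}

# Brute-force pair-count oracle: explicit double loop over all unordered
# pairs, independent of the estimator's vectorized path.
bruteForcePairCounts <- function(xy, breaks) {
  counts <- numeric(length(breaks) - 1)
  n <- nrow(xy)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    for (b in seq_len(length(breaks) - 1)) {
      if (d > breaks[b] && d <= breaks[b + 1]) counts[b] <- counts[b] + 1
    }
  }
  counts
}
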