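test_that("forward pass has logistic behaviour", {
  zero <- new("NetworkWeights", W1 = matrix(0, 432, 24), b1 = rep(0, 24),
              W2 = matrix(0, 24, 2), b2 = rep(0, 2), metadata = list())
  out <- nnForward(zero, matrix(0.3, 12, 12))
  expect_equal(unname(out), c(0.5, 0.5))        # sigma(0) = 0.5

  net <- initNetwork(seed = 8)
  for (k in 1:5) {
    out <- nnForward(net, matrix(runif(144), 12, 12))
    expect_true(all(out > 0 & out < 1))
  }
  expect_error(nnForward(net, matrix(c(NA, runif(143)), 12, 12)),
               "non-finite")
})

test_that("a reduced 2-2-2 network matches hand-computed arithmetic", {
  # x = (1, 0.5); frozen values computed independently from
  # sigma(W x + b) with sigma the logistic function
  fw <- nanopillar:::.mlpForward(
    c(1, 0.5),
    W1 = matrix(c(0.1, 0.3, -0.2, 0.4), 2, 2), b1 = c(0.05, -0.05),
    W2 = matrix(c(0.2, -0.1, 0.3, 0.25), 2, 2), b2 = c(0.1, -0.2))
  expect_equal(fw$h, c(0.574442516811659, 0.4875026035157896),
               tolerance = 1e-12)
  expect_equal(fw$o, c(0.5414392875955243, 0.5235346977457905),
               tolerance = 1e-12)
})

test_that("back-propagation gradients match central finite differences", {
  set.seed(77)
  for (case in 1:3) {
    nin <- sample(2:5, 1); nh <- sample(2:4, 1); nout <- 2
    W1 <- matrix(rnorm(nin * nh, sd = 0.5), nin, nh); b1 <- rnorm(nh, sd = 0.3)
    W2 <- matrix(rnorm(nh * nout, sd = 0.5), nh, nout); b2 <- rnorm(nout, sd = 0.3)
    x <- runif(nin); target <- c(0, 1)
    g <- nanopillar:::.mlpGradients(x, target, W1, b1, W2, b2)
    loss <- function(W1, b1, W2, b2)
      0.5 * sum((nanopillar:::.mlpForward(x, W1, b1, W2, b2)$o - target)^2)
    eps <- 1e-6
    checkGrad <- function(analytic, bump) {
      num <- analytic
      for (i in seq_along(analytic)) {
        up <- bump(i, eps); dn <- bump(i, -eps)
        num[i] <- (do.call(loss, up) - do.call(loss, dn)) / (2 * eps)
      }
      expect_lt(max(abs(num - analytic)) / max(abs(analytic), 1e-8), 1e-5)
    }
    checkGrad(g$W1, function(i, e) {
      W <- W1; W[i] <- W[i] + e; list(W, b1, W2, b2) })
    checkGrad(g$b1, function(i, e) {
      b <- b1; b[i] <- b[i] + e; list(W1, b, W2, b2) })
    checkGrad(g$W2, function(i, e) {
      W <- W2; W[i] <- W[i] + e; list(W1, b1, W, b2) })
    checkGrad(g$b2, function(i, e) {
      b <- b2; b[i] <- b[i] + e; list(W1, b1, W2, b) })
  }
})

test_that("augmentation produces 72 variants per base patch", {
  set.seed(5)
  base <- new("PatchSet", patches = matrix(runif(14 * 144), 14),
              labels = factor(rep(c("E", "P"), each = 7),
                              levels = c("E", "P")),
              metadata = list())
  aug <- augmentPatches(base)
  expect_equal(nrow(aug@patches), 1008)
  expect_equal(sum(aug@labels == "E"), 504)     # 7 x 24 x 3 per class
  expect_equal(sum(aug@labels == "P"), 504)
})

test_that("rotation by 0 degrees at scale 1 is the identity", {
  p <- matrix(runif(144), 12, 12)
  expect_equal(resamplePatch(p, 0, 1), p)
})

test_that("a rotationally symmetric patch is invariant under all 24 angles", {
  ctr <- (12 + 1) / 2
  r2 <- outer((1:12 - ctr)^2, (1:12 - ctr)^2, "+")
  p <- exp(-r2 / 18)                            # radial Gaussian blob
  base <- resamplePatch(p, 0, 1)
  disc <- r2 <= 25          # inscribed disc: untouched by border padding
  for (a in seq(0, 345, by = 15)) {
    expect_lt(max(abs((resamplePatch(p, a, 1) - base)[disc])), 0.03)
  }
})

test_that("training separates a linearly separable toy set", {
  set.seed(9)
  bright <- matrix(runif(10 * 144, 0.7, 1.0), 10)
  dark <- matrix(runif(10 * 144, 0.0, 0.3), 10)
  toy <- new("PatchSet", patches = rbind(dark, bright),
             labels = factor(rep(c("E", "P"), each = 10),
                             levels = c("E", "P")),
             metadata = list())
  net <- trainNetwork(initNetwork(seed = 1), toy, epochs = 40,
                      learningRate = 0.1, seed = 2)
  expect_equal(mean(classifyPatches(net, toy) == toy@labels), 1)
  # squared-error loss decreases from its initial value and is monotone
  lc <- net@metadata$lossCurve
  expect_lt(tail(lc, 1), lc[1])
  expect_true(all(diff(lc) <= 1e-6))
})

test_that("zero training passes leave the weights unchanged", {
  toy <- new("PatchSet", patches = matrix(runif(4 * 144), 4),
             labels = factor(c("E", "P", "E", "P"), levels = c("E", "P")),
             metadata = list())
  net0 <- initNetwork(seed = 3)
  net <- trainNetwork(net0, toy, epochs = 0, seed = 4)
  expect_identical(net@W1, net0@W1)
  expect_identical(net@b2, net0@b2)
})

test_that("training is reproducible and diverges loudly at huge rates", {
  set.seed(12)
  toy <- new("PatchSet", patches = matrix(runif(8 * 144), 8),
             labels = factor(rep(c("E", "P"), 4), levels = c("E", "P")),
             metadata = list())
  a <- trainNetwork(initNetwork(seed = 5), toy, epochs = 5, seed = 6)
  b <- trainNetwork(initNetwork(seed = 5), toy, epochs = 5, seed = 6)
  expect_identical(a@W1, b@W1)
})

test_that("held-out synthetic patches are classified above 95% accuracy", {
  ch <- trainedChain()
  held <- samplePatches(ch$img, ch$truth, nPerClass = 30, seed = 911)
  acc <- mean(classifyPatches(ch$net, held) == held@labels)
  expect_gte(acc, 0.95)
})

test_that("scanning has the documented windowing semantics", {
  ch <- trainedChain()
  # constant image: constant response map
  flat <- new("Micrograph", intensity = matrix(7, 40, 40), pixelSize = 10)
  r <- values2d(scanMicrograph(ch$net, flat, stride = 2))
  expect_lt(diff(range(r)), 1e-12)
  # stride-2 map is the subsampled stride-1 map
  sub <- new("Micrograph",
             intensity = values2d(ch$img)[1:60, 1:60], pixelSize = 10)
  r1 <- values2d(scanMicrograph(ch$net, sub, stride = 1))
  r2 <- values2d(scanMicrograph(ch$net, sub, stride = 2))
  expect_equal(r2, r1[seq(1, nrow(r1), 2), seq(1, ncol(r1), 2)])
})

test_that("a single rendered tip is localized within half a tip width", {
  ch <- trainedChain()
  one <- TipSet(cbind(600, 400), c(0, 1200, 0, 1200))
  img <- renderMicrograph(one, pixelSize = 10, tipWidth = 110,
                          peakIntensity = 180, backgroundLevel = 40,
                          noiseSd = 8, seed = 77)
  rmap <- scanMicrograph(ch$net, img, stride = 1)
  det <- detectTips(rmap, threshold = 0.5, minSeparation = 100)
  expect_gte(nTips(det), 1)
  d <- sqrt((tipCoords(det)[, 1] - 600)^2 + (tipCoords(det)[, 2] - 400)^2)
  expect_lt(min(d), 55)
})

test_that("detection prunes sub-threshold and crowded responses", {
  mkmap <- function(m, px = 10) new("ResponseMap", response = m,
                                    stride = 1L, pixelSize = px,
                                    anchorRows = seq_len(nrow(m)),
                                    anchorCols = seq_len(ncol(m)))
  low <- mkmap(matrix(0.2, 20, 20))
  expect_equal(nTips(detectTips(low, threshold = 0.5)), 0)

  # two maxima 40 nm apart with min separation 100: the higher one wins
  m <- matrix(0.05, 20, 20)
  m[10, 10] <- 0.9
  m[10, 14] <- 0.8
  det <- detectTips(mkmap(m), threshold = 0.5, minSeparation = 100)
  expect_equal(nTips(det), 1)
  expect_equal(unname(tipCoords(det)[1, 1]), (10 + 5) * 10)  # col of 0.9
})
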