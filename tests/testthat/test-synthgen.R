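test_that("hard-core patterns never violate the exclusion radius", {
  specs <- list(
    list(density = 11, w = 5000, h = 5000, excl = 150, spacing = NULL,
         jit = 0, seed = 11),
    list(density = 10, w = 4000, h = 4000, excl = 150, spacing = 306,
         jit = 35, seed = 12),
    list(density = 8, w = 4000, h = 6000, excl = 200, spacing = NULL,
         jit = 20, seed = 13))
  for (s in specs) {
    ts <- generatePattern(s$density, s$w, s$h, exclusionRadius = s$excl,
                          spacing = s$spacing, jitterSd = s$jit,
                          seed = s$seed)
    xy <- tipCoords(ts)
    expect_gte(min(dist(xy)), s$excl)             # brute-force all pairs
    e <- fieldExtent(ts)
    expect_true(all(xy[, 1] >= e[1] & xy[, 1] <= e[2] &
                    xy[, 2] >= e[3] & xy[, 2] <= e[4]))
    # realized density within sampling error (Poisson count)
    expN <- s$density * s$w * s$h / 1e6
    expect_lt(abs(nTips(ts) - expN), 5 * sqrt(expN))
  }
})

test_that("identical spec and seed give bitwise-identical patterns", {
  a <- generatePattern(10, 4000, 4000, exclusionRadius = 150, spacing = 306,
                       jitterSd = 30, bundleProb = 0.3, seed = 99)
  b <- generatePattern(10, 4000, 4000, exclusionRadius = 150, spacing = 306,
                       jitterSd = 30, bundleProb = 0.3, seed = 99)
  expect_identical(tipCoords(a), tipCoords(b))
  c <- generatePattern(10, 4000, 4000, exclusionRadius = 150, seed = 100)
  expect_false(identical(dim(tipCoords(a)), dim(tipCoords(c))) &&
               identical(tipCoords(a), tipCoords(c)))
})

test_that("density 11 with 150 nm exclusion on 5 x 5 um yields ~275 tips", {
  ts <- generatePattern(11, 5000, 5000, exclusionRadius = 150, seed = 42)
  expect_lt(abs(nTips(ts) - 275), 5 * sqrt(275))
  expect_gte(min(dist(tipCoords(ts))), 150)
})

test_that("infeasible packing densities raise an informative error", {
  # hexagonal maximum at 400 nm exclusion is ~7.2 tips/um^2
  expect_error(generatePattern(10, 5000, 5000, exclusionRadius = 400,
                               seed = 1),
               "maximum packing density")
})

test_that("CSR limit: nearest-neighbour distances follow the Poisson law", {
  ts <- generatePattern(20, 10000, 10000, seed = 7)
  xy <- tipCoords(ts)
  D <- as.matrix(dist(xy))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  interior <- xy[, 1] > 400 & xy[, 1] < 9600 & xy[, 2] > 400 & xy[, 2] < 9600
  lambda <- nrow(xy) / 1e8                     # tips per nm^2
  ks <- suppressWarnings(
    stats::ks.test(nn[interior], function(r) 1 - exp(-lambda * pi * r^2)))
  expect_gt(ks$p.value, 0.001)
})

test_that("renders place one bright blob per tip", {
  # single tip at field centre, no noise: argmax at the centre pixel
  one <- TipSet(cbind(1000, 1000), c(0, 2000, 0, 2000))
  img <- renderMicrograph(one, pixelSize = 10, tipWidth = 110, noiseSd = 0)
  m <- values2d(img)
  peak <- which(m == max(m), arr.ind = TRUE)
  expect_true(any(abs(peak[, 1] - 100.5) <= 1 & abs(peak[, 2] - 100.5) <= 1))

  # zero tips: mean stays at the background level
  none <- TipSet(matrix(numeric(0), 0, 2), c(0, 2000, 0, 2000))
  img0 <- renderMicrograph(none, pixelSize = 10, tipWidth = 110,
                           backgroundLevel = 40, noiseSd = 5, seed = 1)
  expect_lt(abs(mean(values2d(img0)) - 40), 3 * 5 / sqrt(200 * 200))

  # N well-separated tips, no noise: exactly N local maxima above background
  ts <- generatePattern(4, 3000, 3000, exclusionRadius = 400, seed = 5)
  imgN <- renderMicrograph(ts, pixelSize = 10, tipWidth = 110,
                           backgroundLevel = 40, noiseSd = 0)
  m <- values2d(imgN)
  nloc <- 0
  for (i in 2:(nrow(m) - 1)) for (j in 2:(ncol(m) - 1)) {
    nb <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (m[i, j] > 41 && m[i, j] >= max(nb) && sum(nb == m[i, j]) == 1)
      nloc <- nloc + 1
  }
  expect_equal(nloc, nTips(ts))
})

test_that("render guards resolution and reproducibility", {
  ts <- TipSet(cbind(500, 500), c(0, 1000, 0, 1000))
  expect_error(renderMicrograph(ts, pixelSize = 50, tipWidth = 110),
               "3 px")
  a <- renderMicrograph(ts, pixelSize = 10, tipWidth = 110, seed = 3)
  b <- renderMicrograph(ts, pixelSize = 10, tipWidth = 110, seed = 3)
  expect_identical(values2d(a), values2d(b))
})

test_that("height maps reproduce the drawn summit heights", {
  ts <- generatePattern(8, 2500, 2500, exclusionRadius = 250, seed = 21)
  hm <- generateHeightMap(ts, heightMean = 500, heightSd = 0,
                          pixelSize = 10, seed = 1)
  h <- values2d(hm)
  xy <- tipCoords(ts)
  summit <- vapply(seq_len(nrow(xy)), function(k)
    h[round(xy[k, 2] / 10 + 0.5), round(xy[k, 1] / 10 + 0.5)], numeric(1))
  # sd = 0: all summits equal up to the sub-pixel offset of the tip centre
  expect_true(all(abs(summit - 500) < 5))
  expect_lt(diff(range(summit)), 5)

  # flat map (no tips) gives zero roughness downstream
  none <- TipSet(matrix(numeric(0), 0, 2), c(0, 1000, 0, 1000))
  flat <- generateHeightMap(none, heightMean = 500, pixelSize = 10)
  expect_equal(unname(roughness(flat)), c(0, 0))
})

test_that("summit heights recover the nominal 836.8 +/- 91.2 nm population", {
  ts <- generatePattern(8, 6000, 6000, exclusionRadius = 250, seed = 31)
  hm <- generateHeightMap(ts, heightMean = 836.8, heightSd = 91.2,
                          pixelSize = 10, seed = 32)
  h <- values2d(hm)
  xy <- tipCoords(ts)
  summit <- vapply(seq_len(nrow(xy)), function(k)
    h[round(xy[k, 2] / 10 + 0.5), round(xy[k, 1] / 10 + 0.5)], numeric(1))
  se <- 91.2 / sqrt(length(summit))
  expect_lt(abs(mean(summit) - 836.8), 2 * se)
})

test_that("viability tables honour the kill fraction at the extremes", {
  v0 <- generateViability(1e6, killFraction = 0, replicates = 8,
                          countNoiseCv = 0.1, seed = 51)
  tt <- pairedTTest(v0@counts$control_cfu, v0@counts$surface_cfu)
  expect_gt(tt$p, 0.01)                         # indistinguishable pairs

  v1 <- generateViability(1e6, killFraction = 1, replicates = 5,
                          countNoiseCv = 0.1, seed = 52)
  expect_true(all(v1@counts$surface_cfu == 0))
})

test_that("a fully killed inoculum of 7.02e6 in 180 min gives 3.9e4/min/cm2", {
  v <- generateViability(7.02e6, killFraction = 1, areaCm2 = 1,
                         incubationMin = 180, replicates = 3,
                         countNoiseCv = 0, seed = 1)
  eff <- bactericidalEfficiency(v)
  expect_equal(eff@mean, 39000)
  expect_equal(eff@deadFraction, 1)
})
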