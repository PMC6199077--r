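test_that("density is count over area in tips per um^2", {
  set.seed(3)
  xy <- cbind(runif(275, 0, 5000), runif(275, 0, 5000))
  expect_equal(tipDensity(TipSet(xy, c(0, 5000, 0, 5000))), 11)
  empty <- TipSet(matrix(numeric(0), 0, 2), c(0, 5000, 0, 5000))
  expect_equal(tipDensity(empty), 0)
})

test_that("generator patterns recover their nominal density", {
  ts <- generatePattern(8, 8000, 8000, seed = 61)
  expN <- 8 * 64
  expect_lt(abs(nTips(ts) - expN), 4 * sqrt(expN))
})

test_that("binned pair counts equal brute-force enumeration exactly", {
  set.seed(17)
  for (rep in 1:3) {
    n <- sample(10:50, 1)
    xy <- cbind(runif(n, 0, 2000), runif(n, 0, 2000))
    g <- pairCorrelation(TipSet(xy, c(0, 2000, 0, 2000)),
                         binWidth = 30, rMax = 900)
    expect_identical(as.numeric(g@pairs),
                     bruteForcePairCounts(xy, g@breaks))
  }
})

test_that("pair counts are invariant under rigid rotation of the pattern", {
  set.seed(23)
  xy <- cbind(runif(40, 0, 2000), runif(40, 0, 2000))
  rot <- cbind(2000 - xy[, 2], xy[, 1])        # 90 degrees within the square
  ext <- c(0, 2000, 0, 2000)
  g1 <- pairCorrelation(TipSet(xy, ext), binWidth = 25, rMax = 800)
  g2 <- pairCorrelation(TipSet(rot, ext), binWidth = 25, rMax = 800)
  expect_identical(g1@pairs, g2@pairs)
  expect_equal(g1@g, g2@g, tolerance = 1e-9)   # isotropic edge weights too
})

test_that("four tips on a 300-nm square bin into the enumerated distances", {
  # pairwise distances: 300 x4 and 424.26 x2
  xy <- rbind(c(100, 100), c(400, 100), c(100, 400), c(400, 400))
  g <- pairCorrelation(TipSet(xy, c(0, 1000, 0, 1000)),
                       binWidth = 50, rMax = 500)
  expected <- numeric(10)
  expected[6] <- 4                              # (250, 300]
  expected[9] <- 2                              # (400, 450]
  expect_identical(as.numeric(g@pairs), expected)
})

test_that("Ripley edge weights match a numeric circle-sampling oracle", {
  set.seed(4)
  ext <- c(0, 2000, 0, 1500)
  th <- seq(0, 2 * pi, length.out = 40001)[-1]
  for (k in 1:10) {
    x <- runif(1, 0, 2000); y <- runif(1, 0, 1500); r <- runif(1, 10, 740)
    fracNum <- mean(x + r * cos(th) >= ext[1] & x + r * cos(th) <= ext[2] &
                    y + r * sin(th) >= ext[3] & y + r * sin(th) <= ext[4])
    fracAna <- 1 / nanopillar:::.ripleyWeight(x, y, r, ext)
    expect_lt(abs(fracNum - fracAna), 2e-4)
  }
  # point exactly at a corner: quarter of the circle is inside
  expect_equal(1 / nanopillar:::.ripleyWeight(0, 0, 100, ext), 0.25)
})

test_that("CSR patterns normalize to g = 1 and hard cores empty the origin", {
  csr <- generatePattern(10, 12000, 12000, seed = 71)
  g <- pairCorrelation(csr, binWidth = 20, rMax = 1000)
  mids <- (g@breaks[-1] + g@breaks[-length(g@breaks)]) / 2
  topq <- mids > 750
  se <- sd(g@g[topq]) / sqrt(sum(topq))
  expect_lt(abs(mean(g@g[topq]) - 1), 3 * se)

  hc <- generatePattern(10, 8000, 8000, exclusionRadius = 150, seed = 72)
  ghc <- pairCorrelation(hc, binWidth = 20, rMax = 1000)
  below <- which(ghc@breaks[-1] <= 150)         # bins entirely below the core
  expect_true(all(ghc@g[below] == 0))
})

test_that("rMax beyond half the field and degenerate inputs error", {
  ts <- generatePattern(10, 1500, 1500, seed = 2)
  expect_error(pairCorrelation(ts, binWidth = 20, rMax = 1000),
               "half the shorter field side")
  one <- TipSet(cbind(100, 100), c(0, 1000, 0, 1000))
  expect_error(pairCorrelation(one, rMax = 400), "at least 2")
})

test_that("small patterns carry a normalization warning in metadata", {
  set.seed(9)
  xy <- cbind(runif(12, 0, 2000), runif(12, 0, 2000))
  g <- pairCorrelation(TipSet(xy, c(0, 2000, 0, 2000)), rMax = 900)
  expect_match(g@metadata$warning, "unstable")
})

test_that("first-peak search interpolates the parabola vertex", {
  # flat sub-unity baseline with a triangular bump spanning bins 15-17;
  # closed-form vertex at 312 nm (frozen hand arithmetic)
  breaks <- seq(0, 1000, by = 20)
  gv <- rep(0.9, 50)
  gv[15] <- 1.2; gv[16] <- 1.5; gv[17] <- 1.3
  g <- new("PairCorrelation", breaks = breaks, g = gv,
           pairs = rep(1, 50), rho0 = 1e-5, metadata = list())
  pk <- firstPeak(g, minR = 100)
  expect_true(pk$found)
  expect_equal(pk$RPeak, 312)
  expect_equal(pk$gPeak, 1.5)
})

test_that("monotone decreasing g reports no peak", {
  breaks <- seq(0, 1000, by = 20)
  g <- new("PairCorrelation", breaks = breaks,
           g = seq(0.99, 0.5, length.out = 50),
           pairs = rep(1, 50), rho0 = 1e-5, metadata = list())
  pk <- firstPeak(g, minR = 100)
  expect_false(pk$found)
  expect_true(is.na(pk$RPeak))
})

test_that("neighbour counts respect the cutoff strictly", {
  ext <- c(0, 3000, 0, 3000)
  near <- TipSet(rbind(c(1300, 1500), c(1700, 1500)), ext)   # 400 nm apart
  far <- TipSet(rbind(c(1200, 1500), c(1800, 1500)), ext)    # 600 nm apart
  expect_equal(neighborCounts(neighborDistribution(near, 500)), c(1L, 1L))
  expect_equal(neighborCounts(neighborDistribution(far, 500)), c(0L, 0L))
})

test_that("CSR neighbour mean matches the Poisson expectation", {
  ts <- generatePattern(10, 10000, 10000, seed = 81)
  nd <- neighborDistribution(ts, cutoff = 500)
  expected <- nTips(ts) / 1e8 * pi * 500^2
  counts <- neighborCounts(nd)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("denser patterns shift the neighbour distribution upward", {
  lo <- neighborDistribution(
    generatePattern(8, 10000, 10000, exclusionRadius = 150, seed = 91), 500)
  hi <- neighborDistribution(
    generatePattern(11, 10000, 10000, exclusionRadius = 150, seed = 92), 500)
  cmp <- compareNeighborDistributions(lo, hi)
  expect_gt(cmp$meanShift, 0)
  expect_true(cmp$bDominatesA)
  same <- compareNeighborDistributions(lo, lo)
  expect_true(same$equal)
  expect_false(same$bDominatesA)
  expect_equal(same$meanShift, 0)
})
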