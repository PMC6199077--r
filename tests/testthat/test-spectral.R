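test_that("a constant image has zero magnitude off DC", {
  img <- new("Micrograph", intensity = matrix(50, 80, 80), pixelSize = 10)
  af <- tiledFFT(img, tileSize = 64, stride = 16)
  m <- values2d(af)
  ctr <- 33
  m[ctr, ctr] <- 0                              # DC (replaced) aside
  expect_lt(max(m), 1e-6)
  expect_equal(af@dcValue, 50 * 64 * 64)        # DC = sum of intensities
})

test_that("tile counting follows the stride grid, small images error", {
  img <- new("Micrograph", intensity = matrix(runif(150 * 150), 150),
             pixelSize = 10)
  af <- tiledFFT(img, tileSize = 64, stride = 32)
  expect_equal(af@tileCount, 9L)                # 3 x 3 anchors fit
  expect_error(tiledFFT(img, tileSize = 256), "smaller than one")
})

test_that("Parseval holds for the single-tile spectrum", {
  set.seed(6)
  tile <- matrix(runif(64 * 64, 0, 255), 64)
  img <- new("Micrograph", intensity = tile, pixelSize = 10)
  af <- tiledFFT(img, tileSize = 64, stride = 64)
  m <- values2d(af)
  m[33, 33] <- af@dcValue                       # undo the display replacement
  expect_equal(sum(m^2), 64^2 * sum(tile^2), tolerance = 1e-10)
})

test_that("a pure sinusoid peaks at its wave number", {
  # period 32 px at 10 nm/px: q = 2*pi*(8/256)/10 = 0.0196 nm^-1
  x <- matrix(rep(1:300, each = 300), 300)
  img <- new("Micrograph",
             intensity = 100 + 50 * sin(2 * pi * x / 32), pixelSize = 10)
  af <- tiledFFT(img, tileSize = 256, stride = 300)
  hp <- haloPeak(radialSpectrum(af), qMin = 0.01)
  expect_true(hp$found)
  expect_lt(abs(hp$qPeak - 0.019634954084936207), 0.0013)
})

test_that("white noise yields a flat radial spectrum", {
  set.seed(10)
  img <- new("Micrograph", intensity = matrix(rnorm(256^2, 100, 20), 256),
             pixelSize = 10)
  rs <- radialSpectrum(tiledFFT(img, tileSize = 128, stride = 32))
  sel <- rs@q > 0.05                            # away from the DC skirt
  expect_lt(sd(rs@magnitude[sel]) / mean(rs@magnitude[sel]), 0.1)
})

test_that("tile averaging reduces spectral variance", {
  # stationary texture: smoothed noise; compare across-seed variance of a
  # mid-band bin between single-tile and averaged spectra
  bandMag <- function(seed, averaged) {
    set.seed(seed)
    raw <- matrix(rnorm(160 * 160), 160)
    f1 <- stats::filter(raw, rep(1 / 5, 5), circular = TRUE)
    f2 <- t(stats::filter(t(matrix(f1, 160)), rep(1 / 5, 5),
                          circular = TRUE))
    img <- new("Micrograph", intensity = 100 + 10 * matrix(f2, 160),
               pixelSize = 10)
    af <- if (averaged) tiledFFT(img, tileSize = 64, stride = 12)
          else tiledFFT(img, tileSize = 64, stride = 1000)
    rs <- radialSpectrum(af)
    mean(rs@magnitude[rs@q > 0.04 & rs@q < 0.08])
  }
  seeds <- 301:308
  vSingle <- var(vapply(seeds, bandMag, numeric(1), averaged = FALSE))
  vAvg <- var(vapply(seeds, bandMag, numeric(1), averaged = TRUE))
  expect_lt(vAvg / vSingle, 1)
})

test_that("radial spectrum is invariant under 90-degree image rotation", {
  ts <- generatePattern(10, 2000, 2000, exclusionRadius = 150, seed = 15)
  img <- renderMicrograph(ts, pixelSize = 10, tipWidth = 110, seed = 16)
  m <- values2d(img)
  rot <- t(m[nrow(m):1, ])
  rs1 <- radialSpectrum(tiledFFT(img, tileSize = 128, stride = 36))
  rs2 <- radialSpectrum(tiledFFT(
    new("Micrograph", intensity = rot, pixelSize = 10),
    tileSize = 128, stride = 36))
  expect_equal(rs1@q, rs2@q)
  expect_equal(rs1@magnitude, rs2@magnitude, tolerance = 1e-9)
})

test_that("an isotropic ring spectrum peaks at the ring radius", {
  N <- 512
  ctr <- N %/% 2 + 1
  f <- (seq_len(N) - ctr) / N
  q <- 2 * pi * sqrt(outer(f^2, f^2, "+")) / 10
  mag <- exp(-((q - 0.02) / 0.002)^2) * 100 + 1
  af <- new("AveragedFFT", magnitude = mag, tileSize = as.integer(N),
            stride = 1L, tileCount = 1L, pixelSize = 10,
            dcValue = mag[ctr, ctr])
  hp <- haloPeak(radialSpectrum(af), qMin = 0.005)
  expect_true(hp$found)
  expect_lt(abs(hp$qPeak - 0.02), 0.002)
})

test_that("a monotone spectrum reports no halo", {
  rs <- new("RadialSpectrum", q = seq(0.005, 0.1, length.out = 50),
            magnitude = exp(-seq(0.005, 0.1, length.out = 50) * 50),
            pixelSize = 10)
  hp <- haloPeak(rs, qMin = 0.01)
  expect_false(hp$found)
})

test_that("wave-number conversion uses the 2*pi convention and round-trips", {
  expect_equal(qToR(0.0205), 306.49, tolerance = 1e-4)
  expect_equal(RToQ(306), 0.020535, tolerance = 1e-4)
  expect_equal(qToR(0.016), 392.699, tolerance = 1e-5)
  for (x in c(0.001, 0.02, 5, 300)) expect_equal(RToQ(qToR(x)), x)
  expect_error(qToR(0), "positive")
  expect_error(RToQ(-5), "positive")
})
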