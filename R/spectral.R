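#' @include AllClasses.R
NULL

# Quadrant swap putting the DC bin at (n/2 + 1, n/2 + 1) for even n.
.fftShift <- function(m) {
  n <- nrow(m)
  h <- n %/% 2
  idx <- c((h + 1):n, 1:h)
  m[idx, idx]
}

#' Tile-averaged Fourier magnitude spectrum of a micrograph
#'
#' Cuts square tiles from the image on a regular grid (top-left anchored,
#' partial tiles discarded), Fourier-transforms each tile, and averages the
#' magnitude spectra. Averaging over displaced tiles of a stationary texture
#' suppresses the tile-to-tile variance of the spectrum while preserving the
#' structural halo of characteristic spacings. The DC bin of the returned
#' DC-centred spectrum is replaced by the mean of its 8 neighbours (a pure
#' display convention; the original value is retained in the object).
#'
#' @param image a \linkS4class{Micrograph} at least one tile in size.
#' @param tileSize tile side, px (512 for full-size SEM frames).
#' @param stride displacement between tile anchors, px.
#' @param window \code{"none"} (default) or \code{"hann"} apodization.
#' @return an \linkS4class{AveragedFFT}.
#' @examples
#' ts <- generatePattern(10, 3000, 3000, exclusionRadius = 150, seed = 1)
#' img <- renderMicrograph(ts, pixelSize = 10, seed = 2)
#' af <- tiledFFT(img, tileSize = 256, stride = 22)
#' af
#' @export
tiledFFT <- function(image, tileSize = 512, stride = 100,
                     window = c("none", "hann")) {
  stopifnot(is(image, "Micrograph"), tileSize >= 4, tileSize %% 2 == 0,
            stride >= 1)
  window <- match.arg(window)
  m <- values2d(image)
  if (nrow(m) < tileSize || ncol(m) < tileSize)
    stop(sprintf("image (%d x %d) smaller than one %d px tile",
                 nrow(m), ncol(m), tileSize))
  ra <- seq(1L, nrow(m) - tileSize + 1L, by = as.integer(stride))
  ca <- seq(1L, ncol(m) - tileSize + 1L, by = as.integer(stride))
  w2d <- NULL
  if (window == "hann") {
    h <- 0.5 * (1 - cos(2 * pi * (0:(tileSize - 1)) / (tileSize - 1)))
    w2d <- outer(h, h)
  }
  acc <- matrix(0, tileSize, tileSize)
  for (r in ra) for (cc in ca) {
    tile <- m[r:(r + tileSize - 1L), cc:(cc + tileSize - 1L)]
    if (!is.null(w2d)) tile <- tile * w2d
    acc <- acc + Mod(stats::fft(tile))
  }
  avg <- .fftShift(acc / (length(ra) * length(ca)))
  ctr <- tileSize %/% 2 + 1L
  dcValue <- avg[ctr, ctr]
  nb <- avg[(ctr - 1):(ctr + 1), (ctr - 1):(ctr + 1)]
  avg[ctr, ctr] <- (sum(nb) - dcValue) / 8
  new("AveragedFFT", magnitude = avg, tileSize = as.integer(tileSize),
      stride = as.integer(stride),
      tileCount = as.integer(length(ra) * length(ca)),
      pixelSize = pixelSize(image), dcValue = dcValue)
}

#' Radially average a 2-D spectrum
#'
#' Averages the DC-centred magnitude over annuli of constant wave number
#' \eqn{q = 2\pi f / pixelSize} (f in cycles per px), up to the Nyquist
#' wave number \eqn{\pi / pixelSize}.
#'
#' @param fft an \linkS4class{AveragedFFT}.
#' @param nBins number of q bins; defaults to tileSize / 2 (one bin per
#'   frequency step).
#' @return a \linkS4class{RadialSpectrum} with q in nm\eqn{^{-1}}.
#' @export
radialSpectrum <- function(fft, nBins = NULL) {
  stopifnot(is(fft, "AveragedFFT"))
  N <- fft@tileSize
  if (is.null(nBins)) nBins <- N %/% 2
  stopifnot(nBins >= 2)
  px <- fft@pixelSize
  k <- seq_len(N) - (N %/% 2 + 1L)          # frequency index offsets
  f <- k / N                                 # cycles per px
  q2 <- outer(f^2, f^2, "+")
  q <- 2 * pi * sqrt(q2) / px
  qNyq <- pi / px
  edges <- seq(0, qNyq, length.out = nBins + 1)
  bin <- findInterval(q, edges, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= nBins & q > 0
  sums <- numeric(nBins)
  rs <- rowsum(fft@magnitude[ok], bin[ok])
  sums[as.integer(rownames(rs))] <- rs[, 1]
  cnts <- tabulate(bin[ok], nBins)
  keep <- which(cnts > 0)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  new("RadialSpectrum", q = centres[keep],
      magnitude = sums[keep] / cnts[keep], pixelSize = px)
}

#' Halo-ring peak of a radial spectrum
#'
#' Finds the wave number of maximal magnitude beyond \code{qMin} (which must
#' exclude the low-q envelope around DC) and refines it with parabolic
#' sub-bin interpolation. A spectrum whose maximum sits at the search
#' boundary (monotone over the search range) yields no halo.
#'
#' @param spec a \linkS4class{RadialSpectrum}.
#' @param qMin smallest wave number searched, nm\eqn{^{-1}}.
#' @return list with \code{found}, \code{qPeak} (nm\eqn{^{-1}}),
#'   \code{magnitude} and \code{REquivalent} (= 2\eqn{\pi}/qPeak, nm).
#' @export
haloPeak <- function(spec, qMin = 0.005) {
  stopifnot(is(spec, "RadialSpectrum"), qMin >= 0)
  sel <- which(spec@q >= qMin)
  if (length(sel) < 3)
    return(list(found = FALSE, qPeak = NA_real_, magnitude = NA_real_,
                REquivalent = NA_real_))
  qs <- spec@q[sel]
  ms <- spec@magnitude[sel]
  i <- which.max(ms)
  if (i == 1 || i == length(ms))
    return(list(found = FALSE, qPeak = NA_real_, magnitude = NA_real_,
                REquivalent = NA_real_))
  qPeak <- .parabolaVertex(qs[i], qs[i + 1] - qs[i],
                           ms[i - 1], ms[i], ms[i + 1])
  list(found = TRUE, qPeak = qPeak, magnitude = ms[i],
       REquivalent = 2 * pi / qPeak)
}

#' Convert between wave number and real-space spacing
#'
#' Uses the \eqn{2\pi} convention \eqn{R = 2\pi / q}: a real-space spacing
#' of 306 nm corresponds to q = 0.0205 nm\eqn{^{-1}}. The two functions are
#' exact inverses.
#'
#' @param q wave number, nm\eqn{^{-1}} (positive).
#' @param R real-space spacing, nm (positive).
#' @return the corresponding spacing (nm) or wave number (nm\eqn{^{-1}}).
#' @examples
#' qToR(0.0205)
#' RToQ(306)
#' @export
qToR <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be positive")
  2 * pi / q
}

#' @rdname qToR
#' @export
RToQ <- function(R) {
  if (any(!is.finite(R)) || any(R <= 0)) stop("R must be positive")
  2 * pi / R
}
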