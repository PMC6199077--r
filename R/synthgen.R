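#' @include AllClasses.R
NULL

# Maximum hard-core packing density (hexagonal) for minimum distance d (nm),
# in tips per nm^2.
.hexMaxDensity <- function(d) 2 / (sqrt(3) * d^2)

# One soft-disk repulsion pass: every ordered pair closer than `radius`
# pushes both points apart along the pair axis by step * (radius - d) / 2.
# Returns the updated coordinate matrix, clamped to the field.
.repelStep <- function(xy, radius, step, extent) {
  dx <- outer(xy[, 1], xy[, 1], "-")
  dy <- outer(xy[, 2], xy[, 2], "-")
  d <- sqrt(dx^2 + dy^2)
  hit <- d < radius & d > 0
  if (!any(hit)) return(list(xy = xy, moved = 0))
  f <- matrix(0, nrow(xy), nrow(xy))
  f[hit] <- step * (radius - d[hit]) / d[hit] / 2
  mx <- rowSums(f * dx)
  my <- rowSums(f * dy)
  xy[, 1] <- pmin(pmax(xy[, 1] + mx, extent[1]), extent[2])
  xy[, 2] <- pmin(pmax(xy[, 2] + my, extent[3]), extent[4])
  list(xy = xy, moved = max(abs(c(mx, my))))
}

.minPairDist <- function(xy) {
  if (nrow(xy) < 2) return(Inf)
  min(dist(xy))
}

#' Generate a synthetic pillar-tip point pattern
#'
#' Samples tip positions on a rectangular field with a hard-core exclusion
#' radius (each pillar exposes an excluded area to its neighbours) and an
#' optional short-range-ordering step that relaxes the pattern toward a
#' characteristic neighbour spacing, emulating the statistical structure of
#' black-silicon nanopillar forests (8-11 tips per \eqn{\mu m^2}, first
#' pair-correlation peak near 300-400 nm).
#'
#' The point count is drawn as Poisson(density x area). Initial placement is
#' dart throwing (sequential rejection at the exclusion radius). When
#' \code{spacing} is given, an iterative soft-disk repulsion with interaction
#' radius \code{spacing} then pushes neighbours apart until they sit close to
#' the target spacing or the pattern jams, producing a liquid-like
#' short-range order whose g(R) first peak falls at approximately
#' \code{spacing}. Optional Gaussian jitter and pair bundling (tips closer
#' than 1.5 x the exclusion radius merge into their midpoint with probability
#' \code{bundleProb}, mimicking pillar bundles detected as single objects)
#' are applied afterwards; the hard core is re-enforced as the final step, so
#' the returned pattern always satisfies min pairwise distance >=
#' \code{exclusionRadius}.
#'
#' @param density target tip density, tips per \eqn{\mu m^2}.
#' @param fieldWidth,fieldHeight field of view, nm.
#' @param exclusionRadius hard-core minimum inter-tip distance, nm.
#' @param spacing characteristic neighbour spacing to relax toward, nm,
#'   or \code{NULL} to skip ordering (pure hard-core / CSR pattern).
#' @param jitterSd standard deviation of positional jitter, nm.
#' @param bundleProb probability in [0, 1] that a close tip pair is merged
#'   into one bundle object.
#' @param seed integer seed; fixed seed gives identical coordinates.
#' @param relaxIter maximum number of repulsion passes for the ordering step.
#' @param relaxStep relaxation step factor in (0, 1].
#' @return a \linkS4class{TipSet}; the generator call and realized minimum
#'   pair distance are recorded in its metadata.
#' @examples
#' ts <- generatePattern(10, 5000, 5000, exclusionRadius = 150, seed = 1)
#' tipDensity(ts)
#' @export
generatePattern <- function(density, fieldWidth, fieldHeight,
                            exclusionRadius = 0, spacing = NULL,
                            jitterSd = 0, bundleProb = 0, seed = NULL,
                            relaxIter = 200, relaxStep = 0.3) {
  stopifnot(density > 0, fieldWidth > 0, fieldHeight > 0,
            exclusionRadius >= 0, jitterSd >= 0,
            bundleProb >= 0, bundleProb <= 1)
  areaNm2 <- fieldWidth * fieldHeight
  lambda <- density / 1e6            # tips per nm^2
  if (lambda * areaNm2 < 1)
    stop("expected tip count below 1; enlarge the field or raise density")
  if (exclusionRadius > 0 && lambda > .hexMaxDensity(exclusionRadius))
    stop(sprintf(
      "density %.3g tips/um^2 exceeds the maximum packing density %.3g tips/um^2 for exclusion radius %.0f nm",
      density, .hexMaxDensity(exclusionRadius) * 1e6, exclusionRadius))
  extent <- c(0, fieldWidth, 0, fieldHeight)

  .withSeed(seed, function() {
    n <- stats::rpois(1, lambda * areaNm2)
    if (n < 1) n <- 1
    if (exclusionRadius <= 0) {
      xy <- cbind(stats::runif(n, 0, fieldWidth),
                  stats::runif(n, 0, fieldHeight))
    } else {
      xy <- matrix(NA_real_, n, 2)
      placed <- 0L
      attempts <- 0L
      maxAttempts <- 2000L * n
      while (placed < n) {
        attempts <- attempts + 1L
        if (attempts > maxAttempts)
          stop(sprintf(
            "dart-throwing stalled after %d attempts: density %.3g tips/um^2 is too close to the maximum packing density %.3g tips/um^2 for exclusion radius %.0f nm",
            attempts, density, .hexMaxDensity(exclusionRadius) * 1e6,
            exclusionRadius))
        p <- c(stats::runif(1, 0, fieldWidth), stats::runif(1, 0, fieldHeight))
        if (placed == 0L ||
            min((xy[seq_len(placed), 1] - p[1])^2 +
                (xy[seq_len(placed), 2] - p[2])^2) >= exclusionRadius^2) {
          placed <- placed + 1L
          xy[placed, ] <- p
        }
      }
    }

    # short-range ordering: soft-disk repulsion toward the target spacing
    if (!is.null(spacing) && is.finite(spacing) && spacing > 0 &&
        nrow(xy) >= 2) {
      for (it in seq_len(relaxIter)) {
        st <- .repelStep(xy, spacing, relaxStep, extent)
        xy <- st$xy
        if (st$moved < 0.05) break
      }
    }

    if (jitterSd > 0) {
      xy[, 1] <- pmin(pmax(xy[, 1] + stats::rnorm(nrow(xy), 0, jitterSd),
                           extent[1]), extent[2])
      xy[, 2] <- pmin(pmax(xy[, 2] + stats::rnorm(nrow(xy), 0, jitterSd),
                           extent[3]), extent[4])
    }

    # bundling: close pairs collapse to their midpoint (single pass,
    # nearest pairs first); ground truth records the merged object
    if (bundleProb > 0 && exclusionRadius > 0 && nrow(xy) >= 2) {
      D <- as.matrix(dist(xy))
      diag(D) <- Inf
      close <- which(D < 1.5 * exclusionRadius & upper.tri(D), arr.ind = TRUE)
      if (nrow(close)) {
        close <- close[order(D[close]), , drop = FALSE]
        drop <- rep(FALSE, nrow(xy))
        for (k in seq_len(nrow(close))) {
          i <- close[k, 1]; j <- close[k, 2]
          if (drop[i] || drop[j]) next
          if (stats::runif(1) < bundleProb) {
            xy[i, ] <- (xy[i, ] + xy[j, ]) / 2
            drop[j] <- TRUE
          }
        }
        xy <- xy[!drop, , drop = FALSE]
      }
    }

    # re-enforce the hard core after jitter / bundling
    if (exclusionRadius > 0 && nrow(xy) >= 2) {
      for (it in 1:200) {
        if (.minPairDist(xy) >= exclusionRadius) break
        xy <- .repelStep(xy, exclusionRadius * 1.0001, 0.6, extent)$xy
      }
      if (.minPairDist(xy) < exclusionRadius) {
        # clamping at field corners can pin a pair; drop one of each offender
        D <- as.matrix(dist(xy)); diag(D) <- Inf
        bad <- which(D < exclusionRadius & upper.tri(D), arr.ind = TRUE)
        if (nrow(bad)) {
          warning("dropped ", length(unique(bad[, 2])),
                  " tips to restore the hard-core condition")
          xy <- xy[-unique(bad[, 2]), , drop = FALSE]
        }
      }
    }

    TipSet(xy, extent, metadata = list(
      generator = "generatePattern",
      density = density, exclusionRadius = exclusionRadius,
      spacing = spacing, jitterSd = jitterSd, bundleProb = bundleProb,
      seed = seed, minPairDistance = .minPairDist(xy)))
  })
}

#' Render a SEM-like micrograph of a tip pattern
#'
#' Draws one isotropic Gaussian bright blob per tip (FWHM = \code{tipWidth})
#' on a uniform background, adds white Gaussian read noise and clips to the
#' 8-bit gray range [0, 255]. This emulates the appearance of pillar tips in
#' top-view secondary-electron images well enough to exercise the detection
#' and spectral pipelines against known ground truth; it is not a physical
#' SEM simulation (no charging, edge brightening or tilt projection).
#'
#' @param tips a \linkS4class{TipSet}.
#' @param pixelSize nm per pixel of the rendered image.
#' @param tipWidth blob full width at half maximum, nm; must span at least
#'   3 px at the chosen pixel size.
#' @param peakIntensity blob amplitude above background, gray levels.
#' @param backgroundLevel background gray level.
#' @param noiseSd additive Gaussian noise standard deviation, gray levels.
#' @param seed integer seed for the noise.
#' @return a \linkS4class{Micrograph}.
#' @examples
#' ts <- generatePattern(8, 2000, 2000, exclusionRadius = 150, seed = 1)
#' img <- renderMicrograph(ts, pixelSize = 10, seed = 2)
#' img
#' @export
renderMicrograph <- function(tips, pixelSize = 10, tipWidth = 110,
                             peakIntensity = 180, backgroundLevel = 40,
                             noiseSd = 8, seed = NULL) {
  stopifnot(is(tips, "TipSet"), pixelSize > 0, tipWidth > 0, noiseSd >= 0)
  if (tipWidth / pixelSize < 3)
    stop("tipWidth must span at least 3 px; decrease pixelSize")
  e <- fieldExtent(tips)
  nc <- max(1L, round((e[2] - e[1]) / pixelSize))
  nr <- max(1L, round((e[4] - e[3]) / pixelSize))
  if (as.numeric(nr) * nc > 5e7)
    stop(sprintf("rendered image would need %d x %d pixels; field too large",
                 nr, nc))
  img <- matrix(backgroundLevel, nr, nc)
  sigma <- (tipWidth / pixelSize) / (2 * sqrt(2 * log(2)))
  rad <- ceiling(4 * sigma)
  xy <- tipCoords(tips)
  for (k in seq_len(nrow(xy))) {
    cx <- (xy[k, 1] - e[1]) / pixelSize + 0.5   # fractional pixel index
    cy <- (xy[k, 2] - e[3]) / pixelSize + 0.5
    js <- max(1L, floor(cx - rad)):min(nc, ceiling(cx + rad))
    is <- max(1L, floor(cy - rad)):min(nr, ceiling(cy + rad))
    if (!length(js) || !length(is)) next
    blob <- peakIntensity *
      exp(-(outer((is - cy)^2, (js - cx)^2, "+")) / (2 * sigma^2))
    img[is, js] <- img[is, js] + blob
  }
  img <- .withSeed(seed, function() {
    if (noiseSd > 0) img + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
    else img
  })
  img <- pmin(pmax(img, 0), 255)
  new("Micrograph", intensity = img, pixelSize = pixelSize)
}

#' Generate an AFM-like pillar-forest height map
#'
#' Places one smooth pillar (Gaussian cross-section bump, FWHM
#' \code{pillarWidth}) per tip on a zero baseline. Per-pillar summit heights
#' are drawn from Normal(\code{heightMean}, \code{heightSd}) truncated at 0;
#' overlapping pillars compose by maximum, so each summit height equals its
#' drawn value.
#'
#' @param tips a \linkS4class{TipSet}.
#' @param heightMean,heightSd summit height distribution, nm.
#' @param pixelSize nm per pixel of the map.
#' @param pillarWidth pillar cross-section FWHM, nm.
#' @param seed integer seed for the height draws.
#' @return a \linkS4class{HeightMap}.
#' @examples
#' ts <- generatePattern(8, 2500, 2500, exclusionRadius = 150, seed = 1)
#' hm <- generateHeightMap(ts, heightMean = 836.8, heightSd = 91.2,
#'                         pixelSize = 10, seed = 2)
#' roughness(hm)
#' @export
generateHeightMap <- function(tips, heightMean, heightSd = 0, pixelSize = 10,
                              pillarWidth = 150, seed = NULL) {
  stopifnot(is(tips, "TipSet"), heightMean > 0, heightSd >= 0,
            pixelSize > 0, pillarWidth > 0)
  e <- fieldExtent(tips)
  nc <- max(1L, round((e[2] - e[1]) / pixelSize))
  nr <- max(1L, round((e[4] - e[3]) / pixelSize))
  if (as.numeric(nr) * nc > 5e7) stop("height map too large")
  xy <- tipCoords(tips)
  heights <- .withSeed(seed, function()
    pmax(stats::rnorm(nrow(xy), heightMean, heightSd), 0))
  h <- matrix(0, nr, nc)
  sigma <- (pillarWidth / pixelSize) / (2 * sqrt(2 * log(2)))
  rad <- ceiling(4 * sigma)
  for (k in seq_len(nrow(xy))) {
    cx <- (xy[k, 1] - e[1]) / pixelSize + 0.5
    cy <- (xy[k, 2] - e[3]) / pixelSize + 0.5
    js <- max(1L, floor(cx - rad)):min(nc, ceiling(cx + rad))
    is <- max(1L, floor(cy - rad)):min(nr, ceiling(cy + rad))
    if (!length(js) || !length(is)) next
    bump <- heights[k] *
      exp(-(outer((is - cy)^2, (js - cx)^2, "+")) / (2 * sigma^2))
    h[is, js] <- pmax(h[is, js], bump)
  }
  new("HeightMap", height = h, pixelSize = pixelSize)
}

#' Generate a synthetic plate-count viability table
#'
#' Simulates a paired control/surface colony-count assay with a known kill
#' fraction: per replicate, control counts scatter around the inoculum with
#' multiplicative Gaussian noise (coefficient of variation
#' \code{countNoiseCv}) and surface counts around
#' inoculum x (1 - \code{killFraction}).
#'
#' @param inoculumCfu expected control CFU count per replicate.
#' @param killFraction true fraction of cells killed on the surface, [0, 1].
#' @param areaCm2 assayed area, cm^2.
#' @param incubationMin incubation time, minutes.
#' @param replicates number of paired replicates.
#' @param countNoiseCv coefficient of variation of the counting noise.
#' @param strain strain label carried through to reports.
#' @param seed integer seed.
#' @return a \linkS4class{ViabilityTable}.
#' @examples
#' v <- generateViability(7.02e6, killFraction = 0.93, replicates = 5, seed = 1)
#' bactericidalEfficiency(v)
#' @export
generateViability <- function(inoculumCfu, killFraction, areaCm2 = 1,
                              incubationMin = 180, replicates = 5,
                              countNoiseCv = 0.1, strain = "synthetic",
                              seed = NULL) {
  stopifnot(inoculumCfu >= 0, killFraction >= 0, killFraction <= 1,
            areaCm2 > 0, incubationMin > 0, replicates >= 1,
            countNoiseCv >= 0)
  .withSeed(seed, function() {
    noise <- function(mu) {
      if (mu == 0) return(rep(0, replicates))
      round(pmax(mu * (1 + stats::rnorm(replicates, 0, countNoiseCv)), 0))
    }
    d <- data.frame(replicate = seq_len(replicates),
                    control_cfu = noise(inoculumCfu),
                    surface_cfu = noise(inoculumCfu * (1 - killFraction)),
                    dilution = 1)
    new("ViabilityTable", counts = d, areaCm2 = areaCm2,
        incubationMin = incubationMin, strain = strain)
  })
}
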