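#' @include AllClasses.R
NULL

#' @describeIn tipDensity tips per square micrometre of the field of view
#' @export
setMethod("tipDensity", "TipSet", function(x) {
  e <- fieldExtent(x)
  area <- (e[2] - e[1]) * (e[4] - e[3])     # nm^2
  if (area <= 0) stop("field extent has zero area")
  nrow(tipCoords(x)) / area * 1e6
})

# Ripley isotropic edge-correction weight for circles of radius r centred at
# (x, y) inside the rectangle `extent`: the reciprocal of the fraction of
# the circle circumference that lies inside the field. Valid for
# r <= min(width, height) / 2, where a circle can cross at most one vertical
# edge, one horizontal edge and the corner between them. Vectorized over
# points/radii.
.ripleyWeight <- function(x, y, r, extent) {
  dx <- pmin(x - extent[1], extent[2] - x)
  dy <- pmin(y - extent[3], extent[4] - y)
  cx <- pmin(dx / r, 1)
  cy <- pmin(dy / r, 1)
  ext <- ifelse(dx < r, 2 * acos(cx), 0) + ifelse(dy < r, 2 * acos(cy), 0)
  corner <- dx^2 + dy^2 < r^2
  ext <- ext - ifelse(corner, acos(cx) - asin(cy), 0)
  1 / (1 - ext / (2 * pi))
}

#' Pair-correlation function of a tip pattern
#'
#' Estimates g(R), the average tip number density at inter-tip distance R
#' normalized by the global density \eqn{\rho_0} so that g(R) tends to 1 at
#' large distances. For each annulus [R, R + dR) the estimator sums
#' Ripley-isotropic edge-correction weights over all ordered tip pairs at
#' that distance and divides by \eqn{n \rho_0} times the annulus area, with
#' \eqn{\rho_0 = n / |A|}.
#'
#' @param tips a \linkS4class{TipSet} with at least 2 tips.
#' @param binWidth annulus width, nm. The default 20 nm resolves the
#'   300-400 nm first peak of nanopillar patterns while keeping pair counts
#'   per bin stable at densities of 8-11 tips per \eqn{\mu m^2}.
#' @param rMax largest distance evaluated, nm; must not exceed half the
#'   shorter field side (edge-correction validity).
#' @return a \linkS4class{PairCorrelation}. If the pattern has fewer than
#'   30 tips a note about unstable normalization is recorded in the
#'   metadata.
#' @examples
#' ts <- generatePattern(10, 4000, 4000, seed = 1)
#' g <- pairCorrelation(ts, binWidth = 20, rMax = 1000)
#' g
#' @export
pairCorrelation <- function(tips, binWidth = 20, rMax = 1000) {
  stopifnot(is(tips, "TipSet"), binWidth > 0, rMax > binWidth)
  e <- fieldExtent(tips)
  W <- e[2] - e[1]; H <- e[4] - e[3]
  if (rMax > min(W, H) / 2 + 1e-9)
    stop("rMax must not exceed half the shorter field side")
  xy <- tipCoords(tips)
  n <- nrow(xy)
  if (n < 2) stop("need at least 2 tips")
  nBins <- ceiling(rMax / binWidth)
  breaks <- seq(0, nBins * binWidth, by = binWidth)

  D <- as.matrix(dist(xy))
  sel <- which(D > 0 & D <= breaks[nBins + 1], arr.ind = TRUE)  # ordered pairs
  S <- numeric(nBins)
  cnt <- numeric(nBins)
  if (nrow(sel)) {
    r <- D[sel]
    w <- .ripleyWeight(xy[sel[, 1], 1], xy[sel[, 1], 2], r, e)
    bin <- pmin(ceiling(r / binWidth), nBins)
    rs <- rowsum(w, bin)
    S[as.integer(rownames(rs))] <- rs[, 1]
    cnt <- tabulate(bin, nBins)
  }
  rho0 <- n / (W * H)
  aBin <- pi * diff(breaks^2)
  g <- S / (n * rho0 * aBin)
  meta <- list(n = n, areaNm2 = W * H, binWidth = binWidth)
  if (n < 30)
    meta$warning <- "fewer than 30 tips: normalization rho0 is unstable"
  new("PairCorrelation", breaks = breaks, g = g, pairs = cnt / 2,
      rho0 = rho0, metadata = meta)
}

#' First peak of a pair-correlation function
#'
#' Locates the first local maximum of g(R) that exceeds 1, searching beyond
#' \code{minR} (which should exclude the excluded-area zone where g = 0),
#' and refines the position by fitting a parabola through the maximal bin
#' and its two neighbours.
#'
#' @param g a \linkS4class{PairCorrelation}.
#' @param minR smallest R considered, nm.
#' @return list with \code{found} (logical), \code{RPeak} and \code{gPeak}
#'   (NA when no bin beyond \code{minR} rises above 1).
#' @examples
#' ts <- generatePattern(10, 8000, 8000, exclusionRadius = 150,
#'                       spacing = 306, seed = 1)
#' firstPeak(pairCorrelation(ts), minR = 100)
#' @export
firstPeak <- function(g, minR = 100) {
  stopifnot(is(g, "PairCorrelation"))
  mids <- (g@breaks[-1] + g@breaks[-length(g@breaks)]) / 2
  gv <- g@g
  nb <- length(gv)
  cand <- which(mids >= minR & gv > 1)
  for (i in cand) {
    lo <- if (i > 1) gv[i - 1] else -Inf
    hi <- if (i < nb) gv[i + 1] else -Inf
    if (gv[i] >= lo && gv[i] >= hi) {
      h <- diff(g@breaks[1:2])
      RPeak <- if (i > 1 && i < nb)
        .parabolaVertex(mids[i], h, gv[i - 1], gv[i], gv[i + 1])
      else mids[i]
      return(list(found = TRUE, RPeak = RPeak, gPeak = gv[i]))
    }
  }
  list(found = FALSE, RPeak = NA_real_, gPeak = NA_real_)
}

#' Neighbour-count distribution within a cutoff
#'
#' Counts, for every interior tip (at least one cutoff away from each field
#' edge, so the counting disc lies fully inside the field), the number of
#' other tips at distance strictly less than \code{cutoff}. The 500-nm
#' default covers the first peak of typical nanopillar pair correlations.
#'
#' @param tips a \linkS4class{TipSet}.
#' @param cutoff neighbourhood radius, nm.
#' @return a \linkS4class{NeighborDistribution}.
#' @examples
#' ts <- generatePattern(10, 5000, 5000, seed = 1)
#' nd <- neighborDistribution(ts, cutoff = 500)
#' mean(neighborCounts(nd))
#' @export
neighborDistribution <- function(tips, cutoff = 500) {
  stopifnot(is(tips, "TipSet"), cutoff > 0)
  e <- fieldExtent(tips)
  xy <- tipCoords(tips)
  inner <- xy[, 1] >= e[1] + cutoff & xy[, 1] <= e[2] - cutoff &
           xy[, 2] >= e[3] + cutoff & xy[, 2] <= e[4] - cutoff
  counts <- integer(sum(inner))
  if (any(inner) && nrow(xy) >= 2) {
    ii <- which(inner)
    d2 <- outer(xy[ii, 1], xy[, 1], "-")^2 + outer(xy[ii, 2], xy[, 2], "-")^2
    counts <- as.integer(rowSums(d2 < cutoff^2) - 1L)   # minus self
  }
  new("NeighborDistribution", cutoff = cutoff, counts = counts,
      nTotal = nrow(xy))
}

#' Neighbour counts of a NeighborDistribution
#'
#' @param x a \linkS4class{NeighborDistribution}.
#' @return integer vector of per-interior-tip neighbour counts.
#' @export
neighborCounts <- function(x) {
  stopifnot(is(x, "NeighborDistribution"))
  x@counts
}

#' Compare two neighbour-count distributions
#'
#' Tests whether the second distribution is stochastically larger than the
#' first (first-order dominance: its empirical CDF lies at or below the
#' first's everywhere, strictly below somewhere), the ordering expected when
#' pillar density increases.
#'
#' @param a,b \linkS4class{NeighborDistribution}s (same cutoff expected).
#' @return list with \code{meanA}, \code{meanB}, \code{meanShift}
#'   (meanB - meanA), \code{bDominatesA}, \code{equal} and the two CDFs
#'   evaluated on the common support.
#' @export
compareNeighborDistributions <- function(a, b) {
  stopifnot(is(a, "NeighborDistribution"), is(b, "NeighborDistribution"))
  if (a@cutoff != b@cutoff)
    warning("comparing distributions with different cutoffs")
  support <- 0:max(1, a@counts, b@counts)
  cdfA <- stats::ecdf(a@counts)(support)
  cdfB <- stats::ecdf(b@counts)(support)
  equal <- isTRUE(all.equal(cdfA, cdfB))
  dom <- !equal && all(cdfB <= cdfA + 1e-12) && any(cdfB < cdfA - 1e-12)
  list(meanA = mean(a@counts), meanB = mean(b@counts),
       meanShift = mean(b@counts) - mean(a@counts),
       bDominatesA = dom, equal = equal,
       support = support, cdfA = cdfA, cdfB = cdfB)
}

#' Coerce spatial results to data frames
#'
#' @param x a \linkS4class{PairCorrelation}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns \code{r_nm} (bin centres), \code{g},
#'   \code{pairs}.
#' @export
as.data.frame.PairCorrelation <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(r_nm = (x@breaks[-1] + x@breaks[-length(x@breaks)]) / 2,
             g = x@g, pairs = x@pairs)
}
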