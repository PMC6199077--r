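#' @include AllClasses.R
NULL

#' Areal surface roughness
#'
#' Computes the areal average roughness Ra (mean absolute deviation of
#' heights from their mean) and root-mean-square roughness Rq of a height
#' map. Rq >= Ra always (Cauchy-Schwarz), with equality only when all
#' deviations share one magnitude. An optional first-order plane fit can be
#' subtracted first (off by default; synthetic maps are already level).
#'
#' @param h a \linkS4class{HeightMap} with at least 2 samples.
#' @param flatten subtract a least-squares plane before evaluating.
#' @return named numeric vector \code{c(Ra = ..., Rq = ...)} in nm; a
#'   constant map gives \code{c(0, 0)}.
#' @examples
#' hm <- new("HeightMap", height = matrix(c(0, 2, 0, 2), 2), pixelSize = 10)
#' roughness(hm)   # Ra = Rq = 1
#' @export
roughness <- function(h, flatten = FALSE) {
  stopifnot(is(h, "HeightMap"))
  z <- values2d(h)
  if (length(z) < 2) stop("need at least 2 height samples")
  if (flatten) {
    ij <- expand.grid(i = seq_len(nrow(z)), j = seq_len(ncol(z)))
    fit <- stats::lm.fit(cbind(1, ij$i, ij$j), as.numeric(z))
    z <- matrix(fit$residuals, nrow(z))
  }
  dev <- z - mean(z)
  c(Ra = mean(abs(dev)), Rq = sqrt(mean(dev^2)))
}

#' Abbott-Firestone bearing curve of a height map
#'
#' For a grid of height levels descending from the summit, reports the
#' bearing area fraction: the fraction of the evaluated area lying at or
#' above each level (the exceedance distribution of heights). The fraction
#' rises monotonically from 0 (just above the summit) to 1 (at the lowest
#' point); for a pillar forest it plateaus once the level descends below the
#' pillar bases, at a level set by the pillar height.
#'
#' @param h a \linkS4class{HeightMap}.
#' @param nLevels number of levels spanning [min, max] (>= 2); one extra
#'   level just above the summit anchors the fraction at 0.
#' @return data.frame with columns \code{level_nm} (descending) and
#'   \code{fraction}.
#' @examples
#' hm <- new("HeightMap", height = matrix(100, 4, 4), pixelSize = 10)
#' bearingCurve(hm, nLevels = 3)
#' @export
bearingCurve <- function(h, nLevels = 101) {
  stopifnot(is(h, "HeightMap"), nLevels >= 2)
  z <- values2d(h)
  zmin <- min(z); zmax <- max(z)
  span <- zmax - zmin
  eps <- max(span, abs(zmax), 1) * 1e-9
  levels <- c(zmax + eps,
              seq(zmax, zmin, length.out = as.integer(nLevels)))
  frac <- vapply(levels, function(l) mean(z >= l), numeric(1))
  data.frame(level_nm = levels, fraction = frac)
}

#' Pillar aspect ratio
#'
#' Height divided by tip width, the dimensionless slenderness measure used
#' to summarize nanopillar geometry (black-silicon surfaces span roughly
#' 6 to 9).
#'
#' @param height pillar height, nm, or a \linkS4class{PillarGeometry}.
#' @param tipWidth pillar tip width, nm (ignored when \code{height} is a
#'   \linkS4class{PillarGeometry}).
#' @return dimensionless ratio.
#' @examples
#' aspectRatio(657.9, 110.3)   # ~6.0
#' @export
aspectRatio <- function(height, tipWidth) {
  if (is(height, "PillarGeometry")) return(height@aspectRatio)
  if (any(tipWidth <= 0)) stop("tip width must be positive")
  if (any(height <= 0)) stop("height must be positive")
  height / tipWidth
}
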