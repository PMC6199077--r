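#' @include utils.R
NULL

#' Pixel-size calibration of a calibrated image object
#'
#' Physical size of one pixel in nanometres, as recorded for a
#' \linkS4class{Micrograph}, \linkS4class{HeightMap},
#' \linkS4class{ResponseMap} or \linkS4class{AveragedFFT}.
#'
#' @param x a calibrated object.
#' @return numeric(1), nm per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Tip coordinates of a TipSet
#'
#' @param x a \linkS4class{TipSet}.
#' @return two-column numeric matrix with columns \code{x_nm}, \code{y_nm}.
#' @export
setGeneric("tipCoords", function(x) standardGeneric("tipCoords"))

#' Field-of-view extent
#'
#' Rectangle containing the analysed field, as
#' \code{c(xmin, xmax, ymin, ymax)} in nm.
#'
#' @param x a \linkS4class{TipSet}.
#' @return numeric(4).
#' @export
setGeneric("fieldExtent", function(x) standardGeneric("fieldExtent"))

#' Number of tips
#'
#' @param x a \linkS4class{TipSet}.
#' @return integer(1).
#' @export
setGeneric("nTips", function(x) standardGeneric("nTips"))

#' Tip density in tips per square micrometre
#'
#' Number of tips divided by the field-of-view area, converted to
#' \eqn{\mu m^{-2}} (the unit used for nanopillar surface summaries).
#'
#' @param x a \linkS4class{TipSet}.
#' @return numeric(1), tips per \eqn{\mu m^2}.
#' @export
setGeneric("tipDensity", function(x) standardGeneric("tipDensity"))

#' Raw numeric values of an image-like object
#'
#' @param x a \linkS4class{Micrograph}, \linkS4class{HeightMap},
#'   \linkS4class{ResponseMap} or \linkS4class{AveragedFFT}.
#' @return numeric matrix (gray levels, nm heights, activations or
#'   spectral magnitudes respectively).
#' @export
setGeneric("values2d", function(x) standardGeneric("values2d"))
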