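#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Calibrated images
## ---------------------------------------------------------------------------

#' Calibrated grayscale micrograph
#'
#' A 2-D grayscale intensity field (SEM-like image) together with its
#' pixel-size calibration in nm per pixel. Matrix rows run along the y axis
#' (row 1 at y = 0) and columns along x; the centre of pixel \code{[i, j]}
#' sits at \code{((j - 0.5) * pixelSize, (i - 0.5) * pixelSize)} nm.
#'
#' @slot intensity numeric matrix of gray levels.
#' @slot pixelSize numeric(1), nm per pixel.
#' @seealso [renderMicrograph()], [scanMicrograph()], [tiledFFT()]
#' @export
setClass("Micrograph",
  representation(intensity = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      return("pixelSize must be a single positive number (nm/px)")
    if (!is.numeric(object@intensity))
      return("intensity must be a numeric matrix")
    if (anyNA(object@intensity))
      return("intensity must not contain NA")
    TRUE
  })

#' Calibrated height map
#'
#' AFM-style surface height field in nm, with a pixel-size calibration.
#' Baseline (substrate) height is 0.
#'
#' @slot height numeric matrix of heights (nm).
#' @slot pixelSize numeric(1), nm per pixel.
#' @seealso [generateHeightMap()], [roughness()], [bearingCurve()]
#' @export
setClass("HeightMap",
  representation(height = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      return("pixelSize must be a single positive number (nm/px)")
    if (!all(is.finite(object@height)))
      return("height values must all be finite")
    TRUE
  })

## ---------------------------------------------------------------------------
## Point patterns
## ---------------------------------------------------------------------------

#' Set of pillar-tip positions
#'
#' Detected or ground-truth pillar tip coordinates in physical units (nm),
#' together with the rectangular field of view they were observed in.
#'
#' @slot coords two-column numeric matrix (\code{x_nm}, \code{y_nm}).
#' @slot extent numeric(4), \code{c(xmin, xmax, ymin, ymax)} in nm.
#' @slot metadata list of provenance (generator spec, seed, detector
#'   parameters, warnings).
#' @seealso [generatePattern()], [detectTips()], [pairCorrelation()]
#' @export
setClass("TipSet",
  representation(coords = "matrix", extent = "numeric", metadata = "list"),
  validity = function(object) {
    e <- object@extent
    if (length(e) != 4L || !all(is.finite(e)))
      return("extent must be numeric(4): xmin, xmax, ymin, ymax")
    if (e[2] <= e[1] || e[4] <= e[3])
      return("extent must enclose a rectangle of positive area")
    xy <- object@coords
    if (ncol(xy) != 2L)
      return("coords must have two columns (x_nm, y_nm)")
    if (nrow(xy) > 0) {
      if (!all(is.finite(xy))) return("coordinates must be finite")
      tol <- 1e-9 * max(e[2] - e[1], e[4] - e[3])
      if (any(xy[, 1] < e[1] - tol | xy[, 1] > e[2] + tol |
              xy[, 2] < e[3] - tol | xy[, 2] > e[4] + tol))
        return("all tips must lie inside the field extent")
    }
    TRUE
  })

#' Construct a TipSet
#'
#' @param coords two-column matrix or data frame of (x, y) positions in nm.
#' @param extent numeric(4): \code{c(xmin, xmax, ymin, ymax)} in nm.
#' @param metadata optional list of provenance information.
#' @return a \linkS4class{TipSet}.
#' @examples
#' ts <- TipSet(cbind(c(100, 400), c(100, 400)), extent = c(0, 500, 0, 500))
#' nTips(ts)
#' @export
TipSet <- function(coords, extent, metadata = list()) {
  coords <- as.matrix(coords)
  if (nrow(coords) > 0) storage.mode(coords) <- "double"
  if (ncol(coords) == 0L) coords <- matrix(numeric(0), 0, 2)
  colnames(coords) <- c("x_nm", "y_nm")
  new("TipSet", coords = coords, extent = as.numeric(extent),
      metadata = metadata)
}

## ---------------------------------------------------------------------------
## Spatial statistics results
## ---------------------------------------------------------------------------

#' Pair-correlation function estimate
#'
#' Binned estimate of the pair-correlation function g(R) of a tip pattern:
#' the density of other tips at inter-tip distance R relative to the global
#' density \eqn{\rho_0}, so that g = 1 for complete spatial randomness,
#' g = 0 inside an excluded area and g > 1 at preferred spacings.
#'
#' @slot breaks bin edges in nm (strictly increasing, starting at 0).
#' @slot g dimensionless g value per bin.
#' @slot pairs unordered pair count per bin (unweighted).
#' @slot rho0 normalization density, tips per nm^2 (N / area).
#' @slot metadata list (n, area, bin width, warnings).
#' @seealso [pairCorrelation()], [firstPeak()]
#' @export
setClass("PairCorrelation",
  representation(breaks = "numeric", g = "numeric", pairs = "numeric",
                 rho0 = "numeric", metadata = "list"),
  validity = function(object) {
    if (any(diff(object@breaks) <= 0))
      return("bin edges must be strictly increasing")
    if (length(object@g) != length(object@breaks) - 1L)
      return("g must have one value per bin")
    if (any(object@g < 0, na.rm = TRUE)) return("g must be non-negative")
    if (any(object@pairs < 0)) return("pair counts must be non-negative")
    TRUE
  })

#' Neighbor-count distribution
#'
#' Per-tip counts of other tips within a cutoff distance, computed for
#' interior tips only (tips at least one cutoff away from every field edge)
#' to avoid edge bias.
#'
#' @slot cutoff neighbourhood radius in nm.
#' @slot counts integer vector, one neighbour count per interior tip.
#' @slot nTotal total number of tips in the pattern.
#' @seealso [neighborDistribution()], [compareNeighborDistributions()]
#' @export
setClass("NeighborDistribution",
  representation(cutoff = "numeric", counts = "integer", nTotal = "integer"),
  validity = function(object) {
    if (object@cutoff <= 0) return("cutoff must be positive")
    if (any(object@counts < 0)) return("neighbour counts must be >= 0")
    TRUE
  })

## ---------------------------------------------------------------------------
## Spectral analysis
## ---------------------------------------------------------------------------

#' Tile-averaged 2-D Fourier magnitude spectrum
#'
#' Mean magnitude spectrum over square tiles cut from a micrograph on a
#' regular stride grid, DC-centred. The DC pixel is replaced by the mean of
#' its 8 neighbours (the original value is kept in \code{dcValue}).
#'
#' @slot magnitude DC-centred mean magnitude matrix (tile x tile).
#' @slot tileSize tile side in px.
#' @slot stride tile displacement in px.
#' @slot tileCount number of tiles averaged.
#' @slot pixelSize nm per pixel of the source image.
#' @slot dcValue original (unreplaced) DC magnitude.
#' @seealso [tiledFFT()], [radialSpectrum()]
#' @export
setClass("AveragedFFT",
  representation(magnitude = "matrix", tileSize = "integer",
                 stride = "integer", tileCount = "integer",
                 pixelSize = "numeric", dcValue = "numeric"),
  validity = function(object) {
    if (object@tileCount < 1L) return("tileCount must be >= 1")
    if (any(object@magnitude < 0)) return("magnitudes must be non-negative")
    TRUE
  })

#' Radially averaged Fourier spectrum
#'
#' Mean spectral magnitude over annuli of constant wave number
#' \eqn{q = 2\pi f / pixelSize} (nm\eqn{^{-1}}, with f in cycles per px).
#'
#' @slot q wave-number bin centres, nm^-1, strictly increasing, > 0.
#' @slot magnitude mean magnitude per bin.
#' @slot pixelSize nm per pixel of the source image.
#' @seealso [radialSpectrum()], [haloPeak()]
#' @export
setClass("RadialSpectrum",
  representation(q = "numeric", magnitude = "numeric", pixelSize = "numeric"),
  validity = function(object) {
    if (length(object@q) != length(object@magnitude))
      return("q and magnitude must have equal length")
    if (length(object@q) && (any(object@q <= 0) || any(diff(object@q) <= 0)))
      return("q must be strictly increasing and positive")
    if (any(object@magnitude < 0)) return("magnitudes must be non-negative")
    TRUE
  })

## ---------------------------------------------------------------------------
## Neural-network tip detector
## ---------------------------------------------------------------------------

#' Weights of the three-layer tip-classifier network
#'
#' Fully connected 432-24-2 multilayer perceptron with logistic-sigmoid
#' activations throughout. Inputs are 12 x 12 pixel patches with three
#' colour channels (channels are replicated for grayscale sources); the two
#' outputs correspond to the classes E (empty space between pillars) and
#' P (pillar tip).
#'
#' @slot W1 input-to-hidden weights, 432 x 24.
#' @slot b1 hidden biases, length 24.
#' @slot W2 hidden-to-output weights, 24 x 2.
#' @slot b2 output biases, length 2.
#' @slot metadata list (seed, learning rate, per-epoch loss curve, ...).
#' @seealso [initNetwork()], [trainNetwork()], [nnForward()], [scanMicrograph()]
#' @export
setClass("NetworkWeights",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix",
                 b2 = "numeric", metadata = "list"),
  validity = function(object) {
    if (!identical(dim(object@W1), c(432L, 24L)))
      return("W1 must be 432 x 24")
    if (length(object@b1) != 24L) return("b1 must have length 24")
    if (!identical(dim(object@W2), c(24L, 2L))) return("W2 must be 24 x 2")
    if (length(object@b2) != 2L) return("b2 must have length 2")
    if (!all(is.finite(object@W1)) || !all(is.finite(object@b1)) ||
        !all(is.finite(object@W2)) || !all(is.finite(object@b2)))
      return("all weights must be finite")
    TRUE
  })

#' Labelled set of 12 x 12 training patches
#'
#' Patches are stored as rows of a n x 144 matrix (column-major pixel order,
#' intensities in [0, 1]); at the network input each patch is replicated
#' into three identical colour channels (432 values).
#'
#' @slot patches numeric matrix, one 144-pixel patch per row, values in [0,1].
#' @slot labels factor with levels \code{E} (empty) and \code{P} (pillar tip).
#' @slot metadata list (source image, augmentation parameters, ...).
#' @seealso [samplePatches()], [augmentPatches()], [trainNetwork()]
#' @export
setClass("PatchSet",
  representation(patches = "matrix", labels = "factor", metadata = "list"),
  validity = function(object) {
    if (ncol(object@patches) != 144L)
      return("patches must have 144 columns (12 x 12 pixels)")
    if (nrow(object@patches) != length(object@labels))
      return("one label per patch required")
    if (!identical(levels(object@labels), c("E", "P")))
      return("labels must be a factor with levels E, P")
    if (nrow(object@patches) &&
        (min(object@patches) < -1e-9 || max(object@patches) > 1 + 1e-9))
      return("patch intensities must lie in [0, 1]")
    TRUE
  })

#' Sliding-window response map
#'
#' Activation of the pillar-tip output neuron (class P) at each scanned
#' 12 x 12 window anchor of a micrograph. The response at matrix position
#' \code{[i, j]} belongs to the window whose anchor is pixel
#' \code{(1 + (i-1) * stride, 1 + (j-1) * stride)} and whose centre lies at
#' \code{(anchor + 5) * pixelSize} nm.
#'
#' @slot response numeric matrix of P activations in (0, 1).
#' @slot stride scan stride in px.
#' @slot pixelSize nm per pixel.
#' @slot anchorRows,anchorCols pixel indices of window anchors.
#' @seealso [scanMicrograph()], [detectTips()]
#' @export
setClass("ResponseMap",
  representation(response = "matrix", stride = "integer",
                 pixelSize = "numeric", anchorRows = "integer",
                 anchorCols = "integer"),
  validity = function(object) {
    r <- object@response
    if (any(r <= 0 | r >= 1)) return("responses must lie in (0, 1)")
    if (object@stride < 1L) return("stride must be >= 1")
    TRUE
  })

## ---------------------------------------------------------------------------
## Viability / efficiency
## ---------------------------------------------------------------------------

#' Paired plate-count viability table
#'
#' Per-replicate colony-forming-unit (CFU) counts on a control surface and
#' on the nanostructured test surface, with the assay geometry needed to
#' convert count differences into a bactericidal efficiency.
#'
#' @slot counts data.frame with columns \code{replicate}, \code{control_cfu},
#'   \code{surface_cfu} and optionally \code{dilution} (default 1).
#' @slot areaCm2 assayed surface area, cm^2.
#' @slot incubationMin incubation time, minutes.
#' @slot strain character label of the bacterial strain.
#' @seealso [generateViability()], [bactericidalEfficiency()]
#' @export
setClass("ViabilityTable",
  representation(counts = "data.frame", areaCm2 = "numeric",
                 incubationMin = "numeric", strain = "character"),
  validity = function(object) {
    d <- object@counts
    need <- c("replicate", "control_cfu", "surface_cfu")
    if (!all(need %in% names(d)))
      return("counts needs columns replicate, control_cfu, surface_cfu")
    if (nrow(d) < 1L) return("at least one replicate required")
    if (any(d$control_cfu < 0) || any(d$surface_cfu < 0))
      return("CFU counts must be >= 0")
    if (object@areaCm2 <= 0 || object@incubationMin <= 0)
      return("area and incubation time must be positive")
    TRUE
  })

#' Bactericidal efficiency estimate
#'
#' Cells inactivated per cm^2 of surface per minute of incubation, relative
#' to the control, summarised across replicates (mean +/- SEM) with a
#' two-tailed paired t test of control vs surface counts.
#'
#' @slot perReplicate per-replicate efficiencies (cells/min/cm^2); negative
#'   values (surface > control) are retained, not truncated.
#' @slot mean,sem replicate mean and standard error of the mean.
#' @slot deadFraction pooled killed fraction, clipped to [0, 1].
#' @slot tStatistic,pValue paired t test of control vs surface counts
#'   (NA with an explanation in \code{notes} when not computable).
#' @slot notes character vector of caveats (negative replicates, zero
#'   variance, single replicate).
#' @seealso [bactericidalEfficiency()]
#' @export
setClass("EfficiencyResult",
  representation(perReplicate = "numeric", mean = "numeric", sem = "numeric",
                 deadFraction = "numeric", tStatistic = "numeric",
                 pValue = "numeric", notes = "character"),
  validity = function(object) {
    if (!is.na(object@sem) && object@sem < 0) return("SEM must be >= 0")
    if (!is.na(object@deadFraction) &&
        (object@deadFraction < 0 || object@deadFraction > 1))
      return("dead fraction must lie in [0, 1]")
    TRUE
  })

## ---------------------------------------------------------------------------
## Pillar geometry
## ---------------------------------------------------------------------------

#' Geometric summary of a pillar population
#'
#' Mean pillar height, tip width and interpillar distance (all nm), plus the
#' derived aspect ratio (height / tip width).
#'
#' @slot height,tipWidth,interpillarDistance nm.
#' @slot aspectRatio dimensionless, height / tipWidth.
#' @seealso [pillarGeometry()], [aspectRatio()]
#' @export
setClass("PillarGeometry",
  representation(height = "numeric", tipWidth = "numeric",
                 interpillarDistance = "numeric", aspectRatio = "numeric"),
  validity = function(object) {
    if (object@height <= 0 || object@tipWidth <= 0)
      return("height and tip width must be positive")
    if (!is.na(object@interpillarDistance) && object@interpillarDistance <= 0)
      return("interpillar distance must be positive")
    if (abs(object@aspectRatio - object@height / object@tipWidth) > 1e-9)
      return("aspectRatio must equal height / tipWidth")
    TRUE
  })

#' Construct a PillarGeometry
#'
#' @param height,tipWidth,interpillarDistance pillar dimensions in nm
#'   (interpillar distance optional).
#' @return a \linkS4class{PillarGeometry} with the aspect ratio filled in.
#' @examples
#' pillarGeometry(height = 657.9, tipWidth = 110.3)
#' @export
pillarGeometry <- function(height, tipWidth, interpillarDistance = NA_real_) {
  new("PillarGeometry", height = height, tipWidth = tipWidth,
      interpillarDistance = interpillarDistance,
      aspectRatio = height / tipWidth)
}

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' @describeIn pixelSize micrograph calibration
#' @export
setMethod("pixelSize", "Micrograph", function(x) x@pixelSize)
#' @describeIn pixelSize height-map calibration
#' @export
setMethod("pixelSize", "HeightMap", function(x) x@pixelSize)
#' @describeIn pixelSize response-map calibration
#' @export
setMethod("pixelSize", "ResponseMap", function(x) x@pixelSize)
#' @describeIn pixelSize source-image calibration of an averaged spectrum
#' @export
setMethod("pixelSize", "AveragedFFT", function(x) x@pixelSize)

#' @describeIn values2d gray levels of a micrograph
#' @export
setMethod("values2d", "Micrograph", function(x) x@intensity)
#' @describeIn values2d heights (nm) of a height map
#' @export
setMethod("values2d", "HeightMap", function(x) x@height)
#' @describeIn values2d P-neuron activations of a response map
#' @export
setMethod("values2d", "ResponseMap", function(x) x@response)
#' @describeIn values2d DC-centred magnitudes of an averaged spectrum
#' @export
setMethod("values2d", "AveragedFFT", function(x) x@magnitude)

#' @describeIn tipCoords coordinate matrix accessor
#' @export
setMethod("tipCoords", "TipSet", function(x) x@coords)
#' @describeIn fieldExtent extent accessor
#' @export
setMethod("fieldExtent", "TipSet", function(x) x@extent)
#' @describeIn nTips tip count accessor
#' @export
setMethod("nTips", "TipSet", function(x) nrow(x@coords))

setMethod("show", "Micrograph", function(object) {
  cat(sprintf("Micrograph: %d x %d px at %.3g nm/px (%.2f x %.2f um)\n",
              nrow(object@intensity), ncol(object@intensity),
              object@pixelSize,
              ncol(object@intensity) * object@pixelSize / 1000,
              nrow(object@intensity) * object@pixelSize / 1000))
  cat(sprintf("  gray levels: [%.1f, %.1f]\n",
              min(object@intensity), max(object@intensity)))
})

setMethod("show", "HeightMap", function(object) {
  cat(sprintf("HeightMap: %d x %d px at %.3g nm/px, heights [%.1f, %.1f] nm\n",
              nrow(object@height), ncol(object@height), object@pixelSize,
              min(object@height), max(object@height)))
})

setMethod("show", "TipSet", function(object) {
  e <- object@extent
  cat(sprintf("TipSet: %d tips on %.2f x %.2f um field (%.2f tips/um^2)\n",
              nrow(object@coords), (e[2] - e[1]) / 1000, (e[4] - e[3]) / 1000,
              tipDensity(object)))
})

setMethod("show", "PairCorrelation", function(object) {
  nb <- length(object@g)
  cat(sprintf(
    "PairCorrelation: %d bins of %.3g nm up to %.4g nm, rho0 = %.3g /nm^2\n",
    nb, diff(object@breaks[1:2]), max(object@breaks), object@rho0))
})

setMethod("show", "NeighborDistribution", function(object) {
  cat(sprintf(
    "NeighborDistribution: cutoff %.4g nm, %d interior of %d tips, mean %.2f\n",
    object@cutoff, length(object@counts), object@nTotal,
    mean(object@counts)))
})

setMethod("show", "AveragedFFT", function(object) {
  cat(sprintf("AveragedFFT: %d tiles of %d px (stride %d) at %.3g nm/px\n",
              object@tileCount, object@tileSize, object@stride,
              object@pixelSize))
})

setMethod("show", "RadialSpectrum", function(object) {
  cat(sprintf("RadialSpectrum: %d bins, q in [%.4g, %.4g] nm^-1\n",
              length(object@q), min(object@q), max(object@q)))
})

setMethod("show", "NetworkWeights", function(object) {
  tr <- object@metadata$epochs
  cat(sprintf("NetworkWeights: 432-24-2 logistic MLP (%s)\n",
              if (is.null(tr)) "untrained" else
                sprintf("trained %d epochs, final MSE %.4g", tr,
                        utils::tail(object@metadata$lossCurve, 1))))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches (E: %d, P: %d)\n", nrow(object@patches),
              sum(object@labels == "E"), sum(object@labels == "P")))
})

setMethod("show", "ResponseMap", function(object) {
  cat(sprintf("ResponseMap: %d x %d anchors, stride %d px, max P = %.3f\n",
              nrow(object@response), ncol(object@response), object@stride,
              max(object@response)))
})

setMethod("show", "ViabilityTable", function(object) {
  cat(sprintf(
    "ViabilityTable (%s): %d replicates, %.3g cm^2, %.0f min incubation\n",
    object@strain, nrow(object@counts), object@areaCm2, object@incubationMin))
})

setMethod("show", "EfficiencyResult", function(object) {
  cat(sprintf(
    "EfficiencyResult: %.4g +/- %.3g cells/min/cm^2 (dead fraction %.3f)\n",
    object@mean, object@sem, object@deadFraction))
  if (!is.na(object@pValue))
    cat(sprintf("  paired t = %.3f, two-tailed p = %.3g\n",
                object@tStatistic, object@pValue))
  for (n in object@notes) cat("  note:", n, "\n")
})

setMethod("show", "PillarGeometry", function(object) {
  cat(sprintf(
    "PillarGeometry: height %.1f nm, tip width %.1f nm, aspect ratio %.2f\n",
    object@height, object@tipWidth, object@aspectRatio))
})
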