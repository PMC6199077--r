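#' @include AllClasses.R
NULL

.sidecarPath <- function(path)
  paste0(tools::file_path_sans_ext(path), ".json")

#' Read and write tip sets
#'
#' Tip sets are exchanged as a CSV with header \code{x_nm,y_nm} plus a JSON
#' sidecar (same basename, \code{.json}) holding the field extent:
#' \code{{"extent_nm": [xmin, xmax, ymin, ymax]}}.
#'
#' @param tips a \linkS4class{TipSet}.
#' @param path CSV file path.
#' @return \code{readTipSet} returns a \linkS4class{TipSet};
#'   \code{writeTipSet} invisibly returns \code{path}.
#' @export
writeTipSet <- function(tips, path) {
  stopifnot(is(tips, "TipSet"))
  utils::write.csv(as.data.frame(tipCoords(tips)), path, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(extent_nm = fieldExtent(tips)),
                       .sidecarPath(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeTipSet
#' @param extent optional numeric(4) overriding the sidecar extent.
#' @export
readTipSet <- function(path, extent = NULL) {
  if (!file.exists(path)) stop("tip set file not found: ", path)
  d <- utils::read.csv(path)
  if (is.null(extent)) {
    sc <- .sidecarPath(path)
    if (!file.exists(sc))
      stop("extent sidecar not found: ", sc)
    extent <- as.numeric(jsonlite::read_json(sc,
                                             simplifyVector = TRUE)$extent_nm)
  }
  TipSet(as.matrix(d[, c("x_nm", "y_nm")]), extent)
}

#' Read and write calibrated micrographs
#'
#' Micrographs are stored as grayscale PNG (8- or 16-bit) or, when the
#' \pkg{tiff} package is available, TIFF; the nm-per-pixel calibration goes
#' into a JSON sidecar \code{{"pixel_size_nm": ...}}. Gray levels are mapped
#' linearly between 0..255 and the file's unit range.
#'
#' @param image a \linkS4class{Micrograph}.
#' @param path output path (.png, .tif or .tiff).
#' @param bitDepth 8 or 16; 16-bit output requires a TIFF path.
#' @return \code{readMicrograph} returns a \linkS4class{Micrograph};
#'   \code{writeMicrograph} invisibly returns \code{path}.
#' @export
writeMicrograph <- function(image, path, bitDepth = 8) {
  stopifnot(is(image, "Micrograph"), bitDepth %in% c(8, 16))
  m <- pmin(pmax(values2d(image) / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF files")
    tiff::writeTIFF(m, path, bits.per.sample = bitDepth)
  } else {
    if (bitDepth != 8)
      stop("16-bit output requires a .tif/.tiff path")
    png::writePNG(m, path, dpi = NULL)
  }
  jsonlite::write_json(list(pixel_size_nm = pixelSize(image)),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMicrograph
#' @param pixelSizeNm calibration override when no sidecar exists.
#' @export
readMicrograph <- function(path, pixelSizeNm = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF files")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (is.null(pixelSizeNm)) {
    sc <- .sidecarPath(path)
    if (!file.exists(sc))
      stop("pixel-size sidecar not found: ", sc,
           " (or pass pixelSizeNm explicitly)")
    pixelSizeNm <- jsonlite::read_json(sc,
                                       simplifyVector = TRUE)$pixel_size_nm
  }
  new("Micrograph", intensity = m * 255, pixelSize = as.numeric(pixelSizeNm))
}

#' Read and write height maps
#'
#' Height maps are stored as a headerless matrix CSV of heights in nm plus a
#' JSON sidecar \code{{"pixel_size_nm": ...}}.
#'
#' @param h a \linkS4class{HeightMap}.
#' @param path CSV file path.
#' @return \code{readHeightMap} returns a \linkS4class{HeightMap};
#'   \code{writeHeightMap} invisibly returns \code{path}.
#' @export
writeHeightMap <- function(h, path) {
  stopifnot(is(h, "HeightMap"))
  utils::write.table(values2d(h), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(pixel_size_nm = pixelSize(h)),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeHeightMap
#' @param pixelSizeNm calibration override when no sidecar exists.
#' @export
readHeightMap <- function(path, pixelSizeNm = NULL) {
  if (!file.exists(path)) stop("height map file not found: ", path)
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  if (is.null(pixelSizeNm)) {
    sc <- .sidecarPath(path)
    if (!file.exists(sc)) stop("pixel-size sidecar not found: ", sc)
    pixelSizeNm <- jsonlite::read_json(sc,
                                       simplifyVector = TRUE)$pixel_size_nm
  }
  new("HeightMap", height = m, pixelSize = as.numeric(pixelSizeNm))
}

#' Read and write viability tables
#'
#' Counts go into a CSV \code{replicate,control_cfu,surface_cfu[,dilution]};
#' assay metadata (\code{area_cm2}, \code{incubation_min}, \code{strain})
#' into a JSON sidecar.
#'
#' @param v a \linkS4class{ViabilityTable}.
#' @param path CSV file path.
#' @return \code{readViabilityTable} returns a \linkS4class{ViabilityTable};
#'   \code{writeViabilityTable} invisibly returns \code{path}.
#' @export
writeViabilityTable <- function(v, path) {
  stopifnot(is(v, "ViabilityTable"))
  utils::write.csv(v@counts, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(area_cm2 = v@areaCm2,
                            incubation_min = v@incubationMin,
                            strain = v@strain),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeViabilityTable
#' @param areaCm2,incubationMin,strain metadata overrides when no sidecar
#'   exists.
#' @export
readViabilityTable <- function(path, areaCm2 = NULL, incubationMin = NULL,
                               strain = "unknown") {
  if (!file.exists(path)) stop("viability file not found: ", path)
  d <- utils::read.csv(path)
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(areaCm2)) areaCm2 <- meta$area_cm2
    if (is.null(incubationMin)) incubationMin <- meta$incubation_min
    if (!is.null(meta$strain)) strain <- meta$strain
  }
  if (is.null(areaCm2) || is.null(incubationMin))
    stop("area/incubation metadata missing; provide a sidecar or arguments")
  if (!"dilution" %in% names(d)) d$dilution <- 1
  new("ViabilityTable", counts = d, areaCm2 = as.numeric(areaCm2),
      incubationMin = as.numeric(incubationMin), strain = strain)
}

#' Serialize network weights to JSON
#'
#' The JSON document stores the architecture, flat weight arrays in
#' column-major order and the training metadata (seed, learning rate, loss
#' curve), and round-trips through [readNetworkWeights()].
#'
#' @param weights a \linkS4class{NetworkWeights}.
#' @param path JSON file path.
#' @return \code{readNetworkWeights} returns a
#'   \linkS4class{NetworkWeights}; \code{writeNetworkWeights} invisibly
#'   returns \code{path}.
#' @export
writeNetworkWeights <- function(weights, path) {
  stopifnot(is(weights, "NetworkWeights"))
  jsonlite::write_json(list(
    architecture = c(432L, 24L, 2L),
    activation = "logistic",
    W1 = as.numeric(weights@W1), b1 = weights@b1,
    W2 = as.numeric(weights@W2), b2 = weights@b2,
    metadata = weights@metadata), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNetworkWeights
#' @export
readNetworkWeights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(j$architecture), c(432L, 24L, 2L)))
    stop("unsupported architecture in ", path)
  new("NetworkWeights",
      W1 = matrix(j$W1, 432, 24), b1 = as.numeric(j$b1),
      W2 = matrix(j$W2, 24, 2), b2 = as.numeric(j$b2),
      metadata = if (is.null(j$metadata)) list() else as.list(j$metadata))
}
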