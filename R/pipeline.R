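#' @include AllClasses.R
NULL

#' Per-surface analysis report
#'
#' Summary metrics of one (synthetic or imaged) nanopillar surface: tip
#' density, pair-correlation first peak, spectral halo peak, neighbour mean,
#' roughness, aspect ratio and bactericidal efficiency, plus provenance
#' (config hash and the seeds of every random stage).
#'
#' @slot label surface label.
#' @slot metrics named list of numeric summaries.
#' @slot provenance list: config hash, seeds, package version.
#' @seealso [runPipeline()], [compareSurfaces()]
#' @export
setClass("SurfaceReport",
  representation(label = "character", metrics = "list",
                 provenance = "list"))

setMethod("show", "SurfaceReport", function(object) {
  cat(sprintf("SurfaceReport '%s'\n", object@label))
  m <- object@metrics
  for (k in names(m))
    cat(sprintf("  %-22s %s\n", k,
                if (is.na(m[[k]])) "NA" else format(m[[k]], digits = 5)))
})

## ---- config validation -----------------------------------------------------

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")))
}

.defaultAnalysis <- function() list(
  binWidth = 20, rMax = 1000, minRPeak = 100, neighborCutoff = 500,
  fftTileSize = 512, fftStride = 100, qMin = 0.01, bearingLevels = 101)

.validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  .checkKeys(config, c("schemaVersion", "seed", "surfaces", "analysis"),
             "top level")
  if (is.null(config$seed)) stop("config must set an explicit seed")
  if (is.null(config$surfaces) || !length(config$surfaces))
    stop("config must define at least one surface")
  an <- .defaultAnalysis()
  if (!is.null(config$analysis)) {
    .checkKeys(config$analysis, names(an), "analysis")
    an[names(config$analysis)] <- config$analysis
  }
  config$analysis <- an
  surfs <- config$surfaces
  if (!is.null(names(surfs)) && all(nzchar(names(surfs))))
    surfs <- lapply(names(surfs), function(nm) c(list(label = nm), surfs[[nm]]))
  config$surfaces <- lapply(seq_along(surfs), function(i) {
    s <- surfs[[i]]
    .checkKeys(s, c("label", "image", "pattern", "render", "heightmap",
                    "viability", "detect"), sprintf("surface %d", i))
    if (is.null(s$label)) s$label <- sprintf("surface%d", i)
    if (is.null(s$pattern) && is.null(s$image))
      stop(sprintf("surface '%s' needs a pattern block or an image path",
                   s$label))
    if (!is.null(s$pattern))
      .checkKeys(s$pattern, c("density", "exclusionRadius", "spacing",
                              "jitterSd", "bundleProb", "fieldWidth",
                              "fieldHeight"),
                 paste0(s$label, "/pattern"))
    if (!is.null(s$render))
      .checkKeys(s$render, c("pixelSize", "tipWidth", "peakIntensity",
                             "backgroundLevel", "noiseSd"),
                 paste0(s$label, "/render"))
    if (!is.null(s$heightmap))
      .checkKeys(s$heightmap, c("heightMean", "heightSd", "pillarWidth",
                                "pixelSize"),
                 paste0(s$label, "/heightmap"))
    if (!is.null(s$viability))
      .checkKeys(s$viability, c("inoculumCfu", "killFraction", "areaCm2",
                                "incubationMin", "replicates",
                                "countNoiseCv", "strain"),
                 paste0(s$label, "/viability"))
    if (!is.null(s$detect))
      .checkKeys(s$detect, c("enabled", "stride", "threshold",
                             "minSeparation", "epochs", "learningRate",
                             "nPerClass"),
                 paste0(s$label, "/detect"))
    if (!is.null(s$image))
      .checkKeys(s$image, c("path", "pixelSizeNm"),
                 paste0(s$label, "/image"))
    s
  })
  config
}

.stage <- function(label, name, logCon, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for surface '%s': %s",
                 name, label, conditionMessage(e)), call. = FALSE))
  if (!is.null(logCon)) {
    writeLines(jsonlite::toJSON(list(
      surface = label, stage = name,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), auto_unbox = TRUE),
      logCon)
    flush(logCon)
  }
  message(sprintf("[%s] %s done (%.2fs)", label, name,
                  proc.time()[["elapsed"]] - t0))
  res
}

## ---- the pipeline ----------------------------------------------------------

#' Run the synthesize-detect-analyse pipeline
#'
#' For every surface in the configuration: generate (or load) the tip
#' pattern and micrograph, optionally run the full neural-network detection
#' chain (sample + augment training patches, train, scan, locate tips),
#' then compute spatial statistics, the tiled-FFT radial spectrum, height
#' metrology and the bactericidal efficiency, collecting everything into a
#' \linkS4class{SurfaceReport}. Deterministic for a fixed config: every
#' random stage draws its own sub-seed derived from \code{config$seed} and
#' the surface label.
#'
#' @param config a config list, or path to a JSON config. Top-level keys:
#'   \code{schemaVersion}, \code{seed} (required), \code{surfaces} (list of
#'   per-surface blocks with \code{label} and \code{pattern}/\code{render}/
#'   \code{heightmap}/\code{viability}/\code{detect} or \code{image}
#'   sub-blocks) and \code{analysis} (bin widths, cutoffs, FFT tiling).
#'   Unknown keys are rejected.
#' @param outDir optional directory for artifacts (per-surface tips CSV,
#'   image PNG, g(R) CSV, report JSON, and a JSON-lines run log).
#' @return named list of \linkS4class{SurfaceReport}s.
#' @seealso [compareSurfaces()]
#' @export
runPipeline <- function(config, outDir = NULL) {
  config <- .validateConfig(config)
  an <- config$analysis
  cfgHash <- .contentHash(as.character(jsonlite::toJSON(config, digits = NA,
                                                        auto_unbox = TRUE)))
  logCon <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logCon <- file(file.path(outDir, "run_log.jsonl"), open = "a")
    on.exit(close(logCon), add = TRUE)
  }

  reports <- lapply(config$surfaces, function(s) {
    lab <- s$label
    sd <- function(stage) .deriveSeed(config$seed, paste0(lab, "/", stage))
    seeds <- list()

    ## pattern + image
    if (!is.null(s$image)) {
      img <- .stage(lab, "load_image", logCon,
                    do.call(readMicrograph, s$image))
      tipsTruth <- NULL
      if (is.null(s$detect)) s$detect <- list(enabled = TRUE)
      s$detect$enabled <- TRUE
    } else {
      seeds$pattern <- sd("pattern")
      tipsTruth <- .stage(lab, "pattern", logCon, do.call(generatePattern,
        c(s$pattern, list(seed = seeds$pattern))))
      seeds$render <- sd("render")
      img <- if (!is.null(s$render))
        .stage(lab, "render", logCon, do.call(renderMicrograph,
          c(list(tips = tipsTruth), s$render, list(seed = seeds$render))))
      else NULL
    }

    ## detection chain or ground truth
    det <- s$detect
    useDetect <- !is.null(det) && isTRUE(det$enabled)
    if (useDetect) {
      if (is.null(img)) stop("detection requested but no image available")
      if (is.null(tipsTruth))
        stop("detection on external images requires pre-trained weights; ",
             "not configured in this pipeline")
      seeds$train <- sd("train")
      nPer <- det$nPerClass %||% 7
      base <- .stage(lab, "patches", logCon,
                     samplePatches(img, tipsTruth, nPerClass = nPer,
                                   seed = seeds$train))
      aug <- .stage(lab, "augment", logCon, augmentPatches(base))
      net <- .stage(lab, "train", logCon,
                    trainNetwork(initNetwork(seed = seeds$train), aug,
                                 epochs = det$epochs %||% 2000,
                                 learningRate = det$learningRate %||% 0.1,
                                 seed = seeds$train))
      rmap <- .stage(lab, "scan", logCon,
                     scanMicrograph(net, img, stride = det$stride %||% 2))
      tips <- .stage(lab, "detect", logCon,
                     detectTips(rmap, threshold = det$threshold %||% 0.5,
                                minSeparation = det$minSeparation %||% 100))
    } else tips <- tipsTruth

    ## spatial statistics
    e <- fieldExtent(tips)
    rMax <- min(an$rMax, (min(e[2] - e[1], e[4] - e[3])) / 2)
    g <- .stage(lab, "pair_correlation", logCon,
                pairCorrelation(tips, binWidth = an$binWidth, rMax = rMax))
    pk <- firstPeak(g, minR = an$minRPeak)
    nd <- neighborDistribution(tips, cutoff = an$neighborCutoff)

    ## spectral
    qPeak <- NA_real_
    if (!is.null(img) &&
        min(dim(values2d(img))) >= an$fftTileSize) {
      af <- .stage(lab, "tiled_fft", logCon,
                   tiledFFT(img, tileSize = an$fftTileSize,
                            stride = an$fftStride))
      hp <- haloPeak(radialSpectrum(af), qMin = an$qMin)
      if (hp$found) qPeak <- hp$qPeak
    }

    ## height metrology
    Ra <- Rq <- NA_real_
    aspect <- NA_real_
    if (!is.null(s$heightmap) && !is.null(tipsTruth)) {
      seeds$heightmap <- sd("heightmap")
      hmArgs <- s$heightmap
      hm <- .stage(lab, "heightmap", logCon, do.call(generateHeightMap,
        c(list(tips = tipsTruth), hmArgs, list(seed = seeds$heightmap))))
      rr <- roughness(hm)
      Ra <- rr[["Ra"]]; Rq <- rr[["Rq"]]
      tw <- s$render$tipWidth %||% 110
      aspect <- aspectRatio(hmArgs$heightMean, tw)
    }

    ## viability
    effMean <- effSem <- deadFrac <- NA_real_
    if (!is.null(s$viability)) {
      seeds$viability <- sd("viability")
      v <- .stage(lab, "viability", logCon, do.call(generateViability,
        c(s$viability, list(seed = seeds$viability))))
      eff <- bactericidalEfficiency(v)
      effMean <- eff@mean; effSem <- eff@sem; deadFrac <- eff@deadFraction
    }

    rep <- new("SurfaceReport", label = lab,
      metrics = list(
        density = tipDensity(tips),
        nTips = nTips(tips),
        RPeak = pk$RPeak,
        qPeak = qPeak,
        neighborMean = if (length(neighborCounts(nd)))
          mean(neighborCounts(nd)) else NA_real_,
        Ra = Ra, Rq = Rq, aspectRatio = aspect,
        efficiency = effMean, efficiencySem = effSem,
        deadFraction = deadFrac),
      provenance = list(configHash = cfgHash, seeds = seeds,
                        packageVersion = as.character(
                          utils::packageVersion("nanopillar"))))

    if (!is.null(outDir)) {
      sdir <- file.path(outDir, lab)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      writeTipSet(tips, file.path(sdir, "tips.csv"))
      if (!is.null(img)) writeMicrograph(img, file.path(sdir, "image.png"))
      utils::write.csv(as.data.frame(g), file.path(sdir, "g.csv"),
                       row.names = FALSE)
      writeSurfaceReport(rep, file.path(sdir, "report.json"))
    }
    rep
  })
  names(reports) <- vapply(config$surfaces, `[[`, "", "label")
  reports
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a SurfaceReport as JSON
#'
#' @param report a \linkS4class{SurfaceReport}.
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
writeSurfaceReport <- function(report, path) {
  stopifnot(is(report, "SurfaceReport"))
  jsonlite::write_json(list(label = report@label, metrics = report@metrics,
                            provenance = report@provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compare surface reports
#'
#' Builds a side-by-side metric table for two or more surfaces and computes
#' Spearman rank correlations between the bactericidal efficiency and every
#' topographic metric. Metrics that are constant across surfaces are
#' reported separately (a rank correlation is undefined for them).
#'
#' @param reports list of \linkS4class{SurfaceReport}s (length >= 2).
#' @return list with \code{table} (metrics x surfaces data.frame),
#'   \code{correlations} (data.frame metric/rho) and
#'   \code{constantMetrics} (character).
#' @export
compareSurfaces <- function(reports) {
  stopifnot(length(reports) >= 2)
  lapply(reports, function(r) stopifnot(is(r, "SurfaceReport")))
  labs <- vapply(reports, function(r) r@label, "")
  keys <- unique(unlist(lapply(reports, function(r) names(r@metrics))))
  tab <- as.data.frame(lapply(reports, function(r)
    vapply(keys, function(k) {
      v <- r@metrics[[k]]
      if (is.null(v) || !length(v)) NA_real_ else as.numeric(v)
    }, numeric(1))))
  names(tab) <- labs
  rownames(tab) <- keys

  eff <- as.numeric(tab["efficiency", ])
  topo <- setdiff(keys, c("efficiency", "efficiencySem", "nTips"))
  isConst <- vapply(topo, function(k) {
    v <- as.numeric(tab[k, ])
    all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0 ||
      !is.finite(stats::sd(v, na.rm = TRUE))
  }, logical(1))
  constant <- topo[isConst]
  corrs <- data.frame(metric = character(0), rho = numeric(0))
  if (!all(is.na(eff)) && stats::sd(eff, na.rm = TRUE) > 0) {
    for (k in setdiff(topo, constant)) {
      v <- as.numeric(tab[k, ])
      rho <- suppressWarnings(
        stats::cor(eff, v, method = "spearman", use = "complete.obs"))
      corrs <- rbind(corrs, data.frame(metric = k, rho = rho))
    }
  } else constant <- union(constant, "efficiency")
  list(table = tab, correlations = corrs, constantMetrics = constant)
}
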