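#' @include AllClasses.R
NULL

## Core MLP arithmetic, written for arbitrary layer sizes so that the same
## code path can be checked against hand calculations and finite
## differences on tiny networks.

.mlpForward <- function(x, W1, b1, W2, b2) {
  h <- stats::plogis(drop(crossprod(W1, x)) + b1)
  o <- stats::plogis(drop(crossprod(W2, h)) + b2)
  list(h = h, o = o)
}

# Back-propagation gradients of the squared-error loss
# L = 0.5 * sum((o - target)^2) for logistic activations in both layers.
.mlpGradients <- function(x, target, W1, b1, W2, b2) {
  fw <- .mlpForward(x, W1, b1, W2, b2)
  h <- fw$h; o <- fw$o
  dOut <- (o - target) * o * (1 - o)
  dHid <- drop(W2 %*% dOut) * h * (1 - h)
  list(W1 = tcrossprod(x, dHid), b1 = dHid,
       W2 = tcrossprod(h, dOut), b2 = dOut,
       loss = 0.5 * sum((o - target)^2), out = o)
}

# Expand a 144-pixel grayscale patch row into the 432-long network input
# (three identical colour channels, stacked).
.expandChannels <- function(p) c(p, p, p)

.labelTarget <- function(label) {
  # target signals: [1, 0] for E (empty), [0, 1] for P (pillar tip)
  if (label == "P") c(0, 1) else c(1, 0)
}

#' Initialize tip-classifier network weights
#'
#' Creates a fully connected 432-24-2 logistic-sigmoid network (12 x 12
#' pixel patches with three colour channels in, classes E and P out) with
#' weights and biases drawn from Uniform(-0.5, 0.5).
#'
#' @param seed integer seed for the weight draw.
#' @return a \linkS4class{NetworkWeights}.
#' @examples
#' net <- initNetwork(seed = 1)
#' net
#' @export
initNetwork <- function(seed = NULL) {
  .withSeed(seed, function() {
    new("NetworkWeights",
        W1 = matrix(stats::runif(432 * 24, -0.5, 0.5), 432, 24),
        b1 = stats::runif(24, -0.5, 0.5),
        W2 = matrix(stats::runif(24 * 2, -0.5, 0.5), 24, 2),
        b2 = stats::runif(2, -0.5, 0.5),
        metadata = list(seed = seed))
  })
}

#' Forward-pass a patch through the network
#'
#' @param weights a \linkS4class{NetworkWeights}.
#' @param patch a 12 x 12 matrix, a 144-vector (grayscale; replicated into
#'   three channels) or a 432-vector (explicit channels), intensities
#'   expected in [0, 1].
#' @return named numeric vector \code{c(E = ..., P = ...)}, both strictly
#'   inside (0, 1).
#' @examples
#' net <- initNetwork(seed = 1)
#' nnForward(net, matrix(0.5, 12, 12))
#' @export
nnForward <- function(weights, patch) {
  stopifnot(is(weights, "NetworkWeights"))
  x <- as.numeric(patch)
  if (!all(is.finite(x))) stop("patch contains non-finite values")
  if (length(x) == 144L) x <- .expandChannels(x)
  if (length(x) != 432L)
    stop("patch must have 144 (grayscale) or 432 (3-channel) values")
  o <- .mlpForward(x, weights@W1, weights@b1, weights@W2, weights@b2)$o
  c(E = o[1], P = o[2])
}

#' Resample a patch by rotation and rescaling
#'
#' Rotates a 12 x 12 patch about its centre and rescales it, resampling back
#' onto the 12 x 12 grid with bilinear interpolation and mirror reflection
#' beyond the patch borders. Rotation by 0 degrees at scale 1 reproduces the
#' input exactly.
#'
#' @param patch 12 x 12 numeric matrix (any square matrix is accepted).
#' @param angle rotation angle, degrees.
#' @param scale linear magnification factor (> 0).
#' @return resampled matrix of the same size.
#' @export
resamplePatch <- function(patch, angle, scale = 1) {
  stopifnot(is.matrix(patch), nrow(patch) == ncol(patch), scale > 0)
  n <- nrow(patch)
  c0 <- (n + 1) / 2
  off <- seq_len(n) - c0
  u <- matrix(off, n, n, byrow = TRUE)   # x (column) offset of target pixel
  v <- matrix(off, n, n)                 # y (row) offset
  th <- angle * pi / 180
  us <- (cos(th) * u + sin(th) * v) / scale
  vs <- (-sin(th) * u + cos(th) * v) / scale
  .bilinearReflect(patch, vs + c0, us + c0)
}

#' Extract labelled training patches from a micrograph
#'
#' Cuts 12 x 12 patches centred on known tip positions (class P) and on
#' random background positions at least \code{clearance} nm away from every
#' tip (class E). Intensities are normalized to [0, 1] by the global image
#' min-max, the same normalization the scanner applies.
#'
#' @param image a \linkS4class{Micrograph}.
#' @param tips ground-truth or detected \linkS4class{TipSet} for the image.
#' @param nPerClass patches per class (the classic workflow uses 7).
#' @param clearance minimum distance of an E patch centre from any tip, nm;
#'   defaults to one patch width.
#' @param seed integer seed for the choice of positions.
#' @return a \linkS4class{PatchSet}.
#' @export
samplePatches <- function(image, tips, nPerClass = 7,
                          clearance = 12 * pixelSize(image), seed = NULL) {
  stopifnot(is(image, "Micrograph"), is(tips, "TipSet"), nPerClass >= 1)
  m <- values2d(image)
  px <- pixelSize(image)
  rng <- range(m)
  mn <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  nr <- nrow(m); nc <- ncol(m)
  xy <- tipCoords(tips)
  e <- fieldExtent(tips)

  cutPatch <- function(cx, cy) {     # centre in nm -> 144-vector or NULL
    j0 <- round((cx - e[1]) / px + 0.5) - 5L
    i0 <- round((cy - e[3]) / px + 0.5) - 5L
    if (i0 < 1 || j0 < 1 || i0 + 11 > nr || j0 + 11 > nc) return(NULL)
    as.numeric(mn[i0:(i0 + 11), j0:(j0 + 11)])
  }

  .withSeed(seed, function() {
    pRows <- list()
    ord <- sample.int(nrow(xy))
    for (k in ord) {
      p <- cutPatch(xy[k, 1], xy[k, 2])
      if (!is.null(p)) pRows[[length(pRows) + 1L]] <- p
      if (length(pRows) == nPerClass) break
    }
    if (length(pRows) < nPerClass)
      stop("not enough tips fully inside the image to cut P patches")
    eRows <- list()
    tries <- 0
    while (length(eRows) < nPerClass && tries < 10000) {
      tries <- tries + 1
      cx <- stats::runif(1, e[1], e[2])
      cy <- stats::runif(1, e[3], e[4])
      if (nrow(xy) &&
          min((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2) < clearance^2) next
      p <- cutPatch(cx, cy)
      if (!is.null(p)) eRows[[length(eRows) + 1L]] <- p
    }
    if (length(eRows) < nPerClass)
      stop("could not place background (E) patches; lower 'clearance'")
    new("PatchSet",
        patches = do.call(rbind, c(pRows, eRows)),
        labels = factor(rep(c("P", "E"), each = nPerClass),
                        levels = c("E", "P")),
        metadata = list(pixelSize = px, clearance = clearance, seed = seed))
  })
}

#' Augment a patch set by rotation and rescaling
#'
#' Expands each base patch into \code{nAngles} equidistant rotations at each
#' of the given scale factors (default 24 angles x scales 0.90/1.00/1.10
#' = 72 variants per base patch, so 7 base patches per class become 504).
#'
#' @param patches a \linkS4class{PatchSet} of base patches.
#' @param nAngles number of equidistant rotation angles.
#' @param scales linear rescale factors.
#' @return an augmented \linkS4class{PatchSet}.
#' @examples
#' base <- new("PatchSet", patches = matrix(runif(2 * 144), 2),
#'             labels = factor(c("E", "P"), levels = c("E", "P")),
#'             metadata = list())
#' nrow(augmentPatches(base)@patches)  # 2 * 24 * 3 = 144
#' @export
augmentPatches <- function(patches, nAngles = 24, scales = c(0.9, 1, 1.1)) {
  stopifnot(is(patches, "PatchSet"), nAngles >= 1, all(scales > 0))
  if (any(12 * scales < 1))
    stop("rescaled patch would collapse below one pixel")
  base <- patches@patches
  angles <- seq(0, 360, length.out = nAngles + 1)[seq_len(nAngles)]
  nOut <- nrow(base) * nAngles * length(scales)
  out <- matrix(NA_real_, nOut, 144)
  lab <- character(nOut)
  r <- 0L
  for (k in seq_len(nrow(base))) {
    p <- matrix(base[k, ], 12, 12)
    for (s in scales) for (a in angles) {
      r <- r + 1L
      out[r, ] <- as.numeric(resamplePatch(p, a, s))
      lab[r] <- as.character(patches@labels[k])
    }
  }
  out <- pmin(pmax(out, 0), 1)
  new("PatchSet", patches = out, labels = factor(lab, levels = c("E", "P")),
      metadata = c(patches@metadata,
                   list(nAngles = nAngles, scales = scales)))
}

#' Train the tip classifier by on-line back-propagation
#'
#' Stochastic (per-pattern) gradient descent on the squared-error loss
#' against the target signals [1, 0] for class E and [0, 1] for class P,
#' with logistic activations in both layers. One epoch presents every patch
#' once in a freshly shuffled order with a full error back-propagation and
#' weight update after each forward pass.
#'
#' @param weights starting \linkS4class{NetworkWeights} (see
#'   [initNetwork()]).
#' @param patches a \linkS4class{PatchSet} containing both classes.
#' @param epochs passes over the patch set (the classic recipe uses 2000;
#'   far fewer suffice for well-separated synthetic patches).
#' @param learningRate gradient step size; the default 0.1 is stable for
#'   inputs in [0, 1].
#' @param seed integer seed controlling the pattern shuffling.
#' @param minAccuracy optional training-set accuracy threshold in [0, 1];
#'   a warning is raised if the trained network falls below it.
#' @return a trained \linkS4class{NetworkWeights}; the per-epoch mean
#'   squared error is stored in \code{metadata$lossCurve}.
#' @export
trainNetwork <- function(weights, patches, epochs = 2000,
                         learningRate = 0.1, seed = NULL,
                         minAccuracy = NULL) {
  stopifnot(is(weights, "NetworkWeights"), is(patches, "PatchSet"),
            epochs >= 0, learningRate > 0)
  n <- nrow(patches@patches)
  if (n == 0) stop("empty training set")
  if (nlevels(droplevels(patches@labels)) < 2)
    stop("training set must contain both classes")
  X <- cbind(patches@patches, patches@patches, patches@patches)
  targets <- rbind(E = c(1, 0), P = c(0, 1))
  tIdx <- as.integer(patches@labels)   # 1 = E, 2 = P
  W1 <- weights@W1; b1 <- weights@b1
  W2 <- weights@W2; b2 <- weights@b2
  lr <- learningRate
  lossCurve <- numeric(epochs)

  .withSeed(seed, function() {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      lossSum <- 0
      for (i in ord) {
        g <- .mlpGradients(X[i, ], targets[tIdx[i], ], W1, b1, W2, b2)
        W1 <<- W1 - lr * g$W1; b1 <<- b1 - lr * g$b1
        W2 <<- W2 - lr * g$W2; b2 <<- b2 - lr * g$b2
        lossSum <- lossSum + g$loss
      }
      if (!is.finite(lossSum))
        stop("training diverged (non-finite loss); reduce learningRate")
      lossCurve[ep] <<- lossSum / n
    }
    NULL
  })

  trained <- new("NetworkWeights", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 metadata = c(weights@metadata,
                              list(epochs = epochs,
                                   learningRate = learningRate,
                                   trainSeed = seed,
                                   lossCurve = lossCurve)))
  if (!is.null(minAccuracy)) {
    acc <- mean(classifyPatches(trained, patches) == patches@labels)
    if (acc < minAccuracy)
      warning(sprintf("training accuracy %.3f below requested %.3f",
                      acc, minAccuracy))
  }
  trained
}

#' Classify patches with a trained network
#'
#' The class with the larger output activation wins; exact ties go to E
#' (conservative: fewer false tips).
#'
#' @param weights a \linkS4class{NetworkWeights}.
#' @param patches a \linkS4class{PatchSet}.
#' @return factor of predicted labels with levels \code{E}, \code{P}.
#' @export
classifyPatches <- function(weights, patches) {
  stopifnot(is(weights, "NetworkWeights"), is(patches, "PatchSet"))
  out <- vapply(seq_len(nrow(patches@patches)), function(i)
    nnForward(weights, patches@patches[i, ]), numeric(2))
  factor(ifelse(out["P", ] > out["E", ], "P", "E"), levels = c("E", "P"))
}

#' Scan a micrograph with the sliding-window classifier
#'
#' Forward-passes every 12 x 12 window on a stride grid through the network
#' and records the activation of the P (pillar tip) output neuron. The image
#' is min-max normalized to [0, 1] first, matching the training
#' normalization.
#'
#' @param weights a trained \linkS4class{NetworkWeights}.
#' @param image a \linkS4class{Micrograph} of at least 12 x 12 px.
#' @param stride window step in px.
#' @return a \linkS4class{ResponseMap}.
#' @export
scanMicrograph <- function(weights, image, stride = 2) {
  stopifnot(is(weights, "NetworkWeights"), is(image, "Micrograph"),
            stride >= 1)
  m <- values2d(image)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 12 || nc < 12) stop("image smaller than one 12 x 12 window")
  rng <- range(m)
  mn <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  ra <- seq(1L, nr - 11L, by = as.integer(stride))
  ca <- seq(1L, nc - 11L, by = as.integer(stride))
  # grayscale channels are identical, so the three channel blocks of W1
  # collapse into one effective 144 x 24 weight matrix for scanning
  W1e <- weights@W1[1:144, ] + weights@W1[145:288, ] + weights@W1[289:432, ]
  A <- length(ra); B <- length(ca)
  resp <- matrix(NA_real_, A, B)
  blocks <- split(seq_len(B), ceiling(seq_len(B) / max(1L, 2e6 %/% (A * 9L))))
  for (bl in blocks) {
    cb <- ca[bl]
    X <- matrix(NA_real_, A * length(cb), 144L)
    k <- 0L
    for (jcol in 0:11) for (irow in 0:11) {
      k <- k + 1L
      X[, (jcol * 12L + irow + 1L)] <-
        as.vector(mn[ra + irow, cb + jcol, drop = FALSE])
    }
    H <- stats::plogis(sweep(X %*% W1e, 2, weights@b1, "+"))
    O <- stats::plogis(sweep(H %*% weights@W2, 2, weights@b2, "+"))
    resp[, bl] <- matrix(O[, 2], A, length(cb))
  }
  eps <- 1e-12
  resp <- pmin(pmax(resp, eps), 1 - eps)   # keep inside the open interval
  new("ResponseMap", response = resp, stride = as.integer(stride),
      pixelSize = pixelSize(image), anchorRows = ra, anchorCols = ca)
}

#' Locate pillar tips from a response map
#'
#' Finds local maxima (8-neighbourhood, ties included) of the P response
#' above a threshold, then greedily prunes them so that no two detections
#' lie closer than \code{minSeparation} (the higher response wins),
#' mirroring how leaning pillar bundles are reported as single tip objects.
#'
#' @param response a \linkS4class{ResponseMap}.
#' @param threshold minimum P activation for a detection, in [0, 1].
#' @param minSeparation minimum distance between detections, nm; the
#'   default of 100 nm is approximately one tip width.
#' @return a \linkS4class{TipSet} in nm, with the scanned window-centre
#'   region as its extent.
#' @export
detectTips <- function(response, threshold = 0.5, minSeparation = 100) {
  stopifnot(is(response, "ResponseMap"), threshold >= 0, threshold <= 1,
            minSeparation >= 0)
  r <- response@response
  px <- response@pixelSize
  A <- nrow(r); B <- ncol(r)
  pad <- matrix(-Inf, A + 2, B + 2)
  pad[2:(A + 1), 2:(B + 1)] <- r
  isMax <- r >= threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    isMax <- isMax & (r >= pad[2:(A + 1) + di, 2:(B + 1) + dj])
  }
  idx <- which(isMax, arr.ind = TRUE)
  ext <- c((response@anchorCols[1] + 5 - 0.5) * px,
           (response@anchorCols[B] + 5 + 0.5) * px,
           (response@anchorRows[1] + 5 - 0.5) * px,
           (response@anchorRows[A] + 5 + 0.5) * px)
  if (nrow(idx) == 0)
    return(TipSet(matrix(numeric(0), 0, 2), ext,
                  metadata = list(threshold = threshold,
                                  minSeparation = minSeparation)))
  resp <- r[idx]
  ord <- order(resp, decreasing = TRUE)
  x <- (response@anchorCols[idx[ord, 2]] + 5) * px
  y <- (response@anchorRows[idx[ord, 1]] + 5) * px
  keep <- logical(length(ord))
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_along(ord)) {
    if (length(kx) == 0 ||
        min((kx - x[i])^2 + (ky - y[i])^2) >= minSeparation^2) {
      keep[i] <- TRUE
      kx <- c(kx, x[i]); ky <- c(ky, y[i])
    }
  }
  TipSet(cbind(x[keep], y[keep]), ext,
         metadata = list(threshold = threshold,
                         minSeparation = minSeparation,
                         responses = resp[ord][keep]))
}

#' Match detections against ground truth
#'
#' Greedy nearest-first matching of detected to true tip positions within a
#' tolerance radius, reporting precision, recall and F1.
#'
#' @param detected,truth \linkS4class{TipSet}s.
#' @param radius maximum match distance, nm (typically one tip width).
#' @return list with \code{nMatched}, \code{precision}, \code{recall},
#'   \code{f1}.
#' @export
matchTips <- function(detected, truth, radius) {
  stopifnot(is(detected, "TipSet"), is(truth, "TipSet"), radius > 0)
  dxy <- tipCoords(detected); txy <- tipCoords(truth)
  nd <- nrow(dxy); nt <- nrow(txy)
  if (nd == 0 || nt == 0)
    return(list(nMatched = 0L, precision = 0, recall = 0, f1 = 0))
  D <- sqrt(outer(dxy[, 1], txy[, 1], "-")^2 +
            outer(dxy[, 2], txy[, 2], "-")^2)
  matched <- 0L
  repeat {
    mi <- which.min(D)
    if (!length(mi) || D[mi] > radius) break
    i <- (mi - 1L) %% nd + 1L
    j <- (mi - 1L) %/% nd + 1L
    matched <- matched + 1L
    D[i, ] <- Inf
    D[, j] <- Inf
  }
  prec <- matched / nd
  rec <- matched / nt
  list(nMatched = matched, precision = prec, recall = rec,
       f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}
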