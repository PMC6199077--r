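# Internal helpers: seeded evaluation, seed derivation, small numeric utilities.

# Evaluate `fn()` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` evaluates as-is.
.withSeed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  fn()
}

# Deterministic 31-bit sub-seed from a master seed and a stage label, so that
# every random stage of a pipeline draws from its own stream.  Documented
# stream-splitting order: the salt is "<surface label>/<stage name>".
.deriveSeed <- function(seed, salt) {
  h <- 0
  for (b in utf8ToInt(as.character(salt))) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483546 + 1)
}

# Rolling 31-bit content hash used for provenance stamps (not cryptographic).
.contentHash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Mirror-reflect a fractional index into [1, n] (period 2(n-1)).
.reflectIndex <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  per <- 2 * (n - 1)
  n - abs((x - 1) %% per - (n - 1))
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions,
# with mirror reflection beyond the borders.
.bilinearReflect <- function(m, is, js) {
  nr <- nrow(m); nc <- ncol(m)
  dms <- dim(is)
  is <- as.vector(is); js <- as.vector(js)
  i0 <- floor(is); j0 <- floor(js)
  fi <- is - i0;  fj <- js - j0
  ri0 <- round(.reflectIndex(i0, nr));     rj0 <- round(.reflectIndex(j0, nc))
  ri1 <- round(.reflectIndex(i0 + 1, nr)); rj1 <- round(.reflectIndex(j0 + 1, nc))
  v00 <- m[cbind(ri0, rj0)]; v01 <- m[cbind(ri0, rj1)]
  v10 <- m[cbind(ri1, rj0)]; v11 <- m[cbind(ri1, rj1)]
  out <- (1 - fi) * ((1 - fj) * v00 + fj * v01) + fi * ((1 - fj) * v10 + fj * v11)
  matrix(out, dms[1], dms[2])
}

# Vertex of the parabola through three equally spaced points; returns the
# x position. Degenerate (flat) triples return the middle x.
.parabolaVertex <- function(x0, h, ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * 100) return(x0)
  x0 + h / 2 * (ym1 - yp1) / denom
}
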