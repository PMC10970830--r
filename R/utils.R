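# Internal numerical helpers shared across modules.

# Evaluate expr with a local RNG state; the caller's stream is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Round half away from zero (commercial rounding), matching printed percent
# tables; base round() rounds half to even.
roundHalfUp <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

clampPixels <- function(x, maxValue = 255) {
  pmin(pmax(x, 0), maxValue)
}

# Round + clip an arbitrary numeric array into the 8-bit range.
quantise8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# Apply a function channel-wise over a RasterImage's planes, returning a
# new RasterImage in the same colour space (fn: matrix -> matrix).
mapChannels <- function(img, fn) {
  px <- img@pixels
  if (length(dim(px)) == 2L) {
    out <- fn(px)
  } else {
    planes <- lapply(seq_len(dim(px)[3L]), function(k) fn(px[, , k]))
    out <- array(0, dim = c(dim(planes[[1L]]), length(planes)))
    for (k in seq_along(planes)) out[, , k] <- planes[[k]]
  }
  RasterImage(out, colorspace = img@colorspace, bitDepth = img@bitDepth)
}

asGrayMatrix <- function(x) {
  if (is(x, "RasterImage")) x <- luminance(x)@pixels
  if (!is.matrix(x)) stop("expected a grayscale plane (2-D matrix)")
  storage.mode(x) <- "double"
  x
}

# Symmetric (mirror, edge included) pad indices for length n and margin r;
# handles r >= n by folding repeatedly.
reflectIndex <- function(n, r) {
  idx <- seq.int(1L - r, n + r)
  period <- 2L * n
  m <- ((idx - 1L) %% period + period) %% period   # 0 .. 2n-1
  ifelse(m < n, m + 1L, 2L * n - m)
}

# 2-D correlation of a matrix with a (2r+1)^2 kernel under symmetric
# padding, via vectorised shifted sums (kernels here are symmetric, so
# correlation equals convolution).
convolveReflect <- function(m, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  n1 <- nrow(m); n2 <- ncol(m)
  pad <- m[reflectIndex(n1, r), reflectIndex(n2, r), drop = FALSE]
  out <- matrix(0, n1, n2)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * pad[(i - 1L) + seq_len(n1), (j - 1L) + seq_len(n2)]
    }
  }
  out
}

# Separable correlation with a 1-D kernel along rows then columns, under
# the same symmetric padding as convolveReflect.
convolveReflectSep <- function(m, g) {
  r <- (length(g) - 1L) %/% 2L
  pass <- function(mm) {
    pad <- mm[reflectIndex(nrow(mm), r), , drop = FALSE]
    out <- matrix(0, nrow(mm), ncol(mm))
    for (i in seq_along(g))
      out <- out + g[i] * pad[(i - 1L) + seq_len(nrow(mm)), , drop = FALSE]
    out
  }
  t(pass(t(pass(m))))
}

# "Valid" (no padding) correlation: output is (n1-2r) x (n2-2r).
convolveValid <- function(m, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  n1 <- nrow(m) - 2L * r; n2 <- ncol(m) - 2L * r
  out <- matrix(0, n1, n2)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * m[(i - 1L) + seq_len(n1), (j - 1L) + seq_len(n2)]
    }
  }
  out
}

# Truncation at 4 sigma keeps the truncated kernel's frequency-domain
# sidelobes (~e^-8) below the true Gaussian response at half-Nyquist for
# the sigmas used here, so stronger blur always passes less high frequency.
gaussianKernel1d <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  g <- exp(-seq.int(-radius, radius)^2 / (2 * sigma^2))
  g / sum(g)
}

gaussianKernel2d <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  g <- exp(-seq.int(-radius, radius)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

diskKernel2d <- function(radius) {
  r <- max(1L, ceiling(radius))
  x <- seq.int(-r, r)
  d2 <- outer(x^2, x^2, "+")
  k <- (d2 <= radius^2) * 1
  if (sum(k) == 0) k[r + 1L, r + 1L] <- 1
  k / sum(k)
}

# --- 1-D resampling kernels -------------------------------------------------

# Keys cubic-convolution kernel, a = -0.5 (the SR-literature standard).
keysCubic <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

triangleKernel <- function(t) pmax(0, 1 - abs(t))

lanczosKernel <- function(t, a = 3) {
  out <- rep(0, length(t))
  inside <- abs(t) < a
  tt <- t[inside]
  s <- ifelse(tt == 0, 1, sin(pi * tt) / (pi * tt))
  sa <- ifelse(tt == 0, 1, sin(pi * tt / a) / (pi * tt / a))
  out[inside] <- s * sa
  out
}

# Dense 1-D interpolation weight matrix W (nOut x nIn) for given 0-based
# source coordinates, with out-of-range taps clamped to the border sample.
# Rows are normalised so constants are reproduced exactly (partition of
# unity after clamping; required for lanczos, harmless for the
# exactly-normalised kernels).
weightsForCoords <- function(srcCoords, nIn, kernel, support) {
  W <- matrix(0, length(srcCoords), nIn)
  for (i in seq_along(srcCoords)) {
    src <- srcCoords[i]
    k0 <- floor(src) - support + 1L
    taps <- seq.int(k0, floor(src) + support)
    w <- kernel(src - taps)
    taps <- pmin(pmax(taps, 0L), nIn - 1L)  # clamp to border
    for (j in seq_along(taps))
      W[i, taps[j] + 1L] <- W[i, taps[j] + 1L] + w[j]
  }
  sweep(W, 1L, rowSums(W), "/")
}

# Centre-aligned mapping src = (i + 0.5) * nIn/nOut - 0.5 (0-based), the
# convention of mainstream imaging libraries; the identity when
# nOut == nIn.
resampleWeights <- function(nOut, nIn, kernel, support) {
  weightsForCoords((seq_len(nOut) - 0.5) * nIn / nOut - 0.5, nIn,
                   kernel, support)
}

resampleKernelFor <- function(method) {
  switch(method,
    bilinear = list(kernel = triangleKernel, support = 1L),
    bicubic  = list(kernel = keysCubic, support = 2L),
    lanczos  = list(kernel = function(t) lanczosKernel(t, 3), support = 3L),
    stop(sprintf("unknown method '%s'; valid methods: %s", method,
                 "nearest, bilinear, bicubic, lanczos")))
}

# Resample a single plane to (rowsOut, colsOut) with the given method.
resamplePlane <- function(m, rowsOut, colsOut, method) {
  if (method == "nearest") {
    ri <- floor((seq_len(rowsOut) - 0.5) * nrow(m) / rowsOut) + 1L
    ci <- floor((seq_len(colsOut) - 0.5) * ncol(m) / colsOut) + 1L
    return(m[pmin(pmax(ri, 1L), nrow(m)), pmin(pmax(ci, 1L), ncol(m)),
             drop = FALSE])
  }
  k <- resampleKernelFor(method)
  Wr <- resampleWeights(rowsOut, nrow(m), k$kernel, k$support)
  Wc <- resampleWeights(colsOut, ncol(m), k$kernel, k$support)
  Wr %*% m %*% t(Wc)
}
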