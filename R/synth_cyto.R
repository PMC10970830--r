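#' @include AllClasses.R AllGenerics.R image_io.R degrade_restore.R
NULL

# Logical ellipse mask: centre (cy, cx), semi-axes (a, b), rotation theta.
.ellipseMask <- function(shape, cy, cx, a, b, theta) {
  y <- outer(seq_len(shape[1L]) - cy, rep(1, shape[2L]))
  x <- outer(rep(1, shape[1L]), seq_len(shape[2L]) - cx)
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  (xr / a)^2 + (yr / b)^2 <= 1
}

# Smooth random field in [-1, 1]: coarse white noise upsampled bilinearly.
.smoothField <- function(shape, coarse = 8L) {
  z <- matrix(stats::runif(coarse^2, -1, 1), coarse, coarse)
  resamplePlane(z, shape[1L], shape[2L], "bilinear")
}

#' Generate one synthetic cytology scene
#'
#' Renders a stained-aspirate-like scene: a pale textured background,
#' \code{nCells} rotated elliptical cells with darker inner nuclei, a
#' smooth texture field over the cytoplasm, and additive Gaussian sensor
#' noise. Cell centres are drawn with bounded rejection sampling so the
#' cytoplasm ellipses are pairwise disjoint; if the canvas cannot fit all
#' requested cells, fewer are rendered and a warning reports the count.
#' Generation is fully deterministic given the spec (the caller's RNG
#' stream is untouched).
#'
#' The ground-truth masks are the cytoplasm ellipses, one
#' \linkS4class{InstanceMask} per rendered cell, labelled \code{"cell"}.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return A list with \code{image} (an RGB \linkS4class{RasterImage}) and
#'   \code{masks} (list of \linkS4class{InstanceMask}s).
#' @examples
#' sc <- generateScene(SceneSpec(shape = c(64, 64), nCells = 3, seed = 2))
#' length(sc$masks)
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  withSeed(spec@seed, {
    shape <- spec@shape
    pal <- spec@palette
    amp <- spec@textureAmplitude
    # background: base colour + shared smooth texture + per-channel jitter
    field <- .smoothField(shape)
    img <- array(0, dim = c(shape, 3L))
    for (k in 1:3)
      img[, , k] <- pal$background[k] + amp * 0.5 * field
    # place cells with disjoint bounding discs
    centres <- matrix(numeric(0), ncol = 2L)
    axes <- matrix(numeric(0), ncol = 2L)
    thetas <- numeric(0)
    for (i in seq_len(spec@nCells)) {
      placed <- FALSE
      for (try in seq_len(120L)) {
        a <- stats::runif(1, spec@axisRange[1L], spec@axisRange[2L])
        b <- stats::runif(1, spec@axisRange[1L], a)
        margin <- a + 1       # the cell itself must fit the canvas
        cy <- stats::runif(1, margin, shape[1L] - margin)
        cx <- stats::runif(1, margin, shape[2L] - margin)
        if (nrow(centres) == 0L ||
            all(sqrt((centres[, 1L] - cy)^2 + (centres[, 2L] - cx)^2) >
                a + axes[, 1L] + 1)) {
          centres <- rbind(centres, c(cy, cx))
          axes <- rbind(axes, c(a, b))
          thetas <- c(thetas, stats::runif(1, 0, pi))
          placed <- TRUE
          break
        }
      }
      if (!placed) break
    }
    if (nrow(centres) < spec@nCells)
      warning(sprintf("placed %d of %d requested cells (canvas too crowded)",
                      nrow(centres), spec@nCells))
    masks <- vector("list", nrow(centres))
    cellField <- .smoothField(shape, coarse = 16L)
    for (i in seq_len(nrow(centres))) {
      cy <- centres[i, 1L]; cx <- centres[i, 2L]
      a <- axes[i, 1L]; b <- axes[i, 2L]; th <- thetas[i]
      cyto <- .ellipseMask(shape, cy, cx, a, b, th)
      nuc <- .ellipseMask(shape, cy, cx, 0.45 * a, 0.45 * b, th)
      for (k in 1:3) {
        plane <- img[, , k]
        plane[cyto] <- pal$cytoplasm[k] + amp * cellField[cyto]
        plane[nuc] <- pal$nucleus[k] + amp * 0.8 * cellField[nuc]
        img[, , k] <- plane
      }
      masks[[i]] <- InstanceMask(cyto, label = "cell")
    }
    noise <- array(stats::rnorm(prod(shape) * 3L, 0, spec@noiseSigma),
                   dim = c(shape, 3L))
    out <- RasterImage(quantise8(img + noise), colorspace = "RGB")
    list(image = out, masks = masks)
  })
}

#' Generate paired sharp/defocused samples
#'
#' For each scene spec, renders the reference image and produces a
#' defocused partner with a blur severity drawn from the
#' \linkS4class{SpectrumSpec}; the pairwise PSNR is computed and cached on
#' every pair. A wide severity range yields a paired dataset whose
#' PSNR histogram spans a wide interval — including pairs that would count
#' as good quality in terms of pixel loss — which is what field-collected
#' focus-degradation datasets look like.
#'
#' @param sceneSpecs non-empty list of \linkS4class{SceneSpec}s.
#' @param spectrum a \linkS4class{SpectrumSpec}.
#' @return A list of \linkS4class{PairedSample}s; each carries attribute
#'   \code{severity} (the drawn sigma/radius) retrievable via
#'   \code{attr(pairs, "severity")} on the list.
#' @export
generatePairs <- function(sceneSpecs, spectrum = SpectrumSpec()) {
  if (!length(sceneSpecs)) stop("sceneSpecs must be non-empty")
  stopifnot(is(spectrum, "SpectrumSpec"))
  n <- length(sceneSpecs)
  sev <- withSeed(spectrum@seed,
    switch(spectrum@drawLaw,
      uniform = stats::runif(n, spectrum@range[1L], spectrum@range[2L]),
      fixed = rep(spectrum@range[1L], n)))
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generateScene(sceneSpecs[[i]])
    deg <- if (spectrum@blurKind == "gaussian")
      defocus(sc$image, sigma = sev[i])
    else defocus(sc$image, radius = sev[i])
    pairs[[i]] <- PairedSample(sc$image, deg,
                               pairId = sprintf("scene%03d", i),
                               psnrDb = TRUE)
  }
  attr(pairs, "severity") <- sev
  pairs
}

#' Partition paired samples by pairwise PSNR
#'
#' Realises narrow/wide dataset-spectrum experiments: \code{narrow_high}
#' keeps the top tercile by PSNR (mildly degraded pairs),
#' \code{narrow_low} the bottom tercile (heavily degraded), and
#' \code{wide} the full list. Tercile edges sit at the empirical 1/3 and
#' 2/3 quantiles; ties on an edge go to the lower segment. With fewer than
#' 3 pairs the tercile modes are undefined.
#'
#' @param pairs list of \linkS4class{PairedSample}s, all carrying a cached
#'   PSNR.
#' @param mode \code{"narrow_high"}, \code{"narrow_low"} or \code{"wide"}.
#' @return The selected subset, in input order.
#' @export
partitionByPSNR <- function(pairs,
                            mode = c("wide", "narrow_high", "narrow_low")) {
  mode <- match.arg(mode)
  p <- vapply(pairs, psnrDb, numeric(1L))
  if (anyNA(p)) stop("all pairs must carry a cached psnrDb")
  if (mode == "wide") return(pairs)
  if (length(pairs) < 3L)
    stop("tercile modes need at least 3 pairs")
  q <- stats::quantile(p, c(1, 2) / 3, type = 1L, names = FALSE)
  keep <- if (mode == "narrow_low") p <= q[1L] else p > q[2L]
  if (mode == "narrow_high" && !any(keep))
    warning("all PSNR values tie at the lower edge; narrow_high is empty")
  pairs[keep]
}
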