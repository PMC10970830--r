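#' @include AllClasses.R AllGenerics.R utils.R image_io.R ring_spectrum.R
NULL

#' Decimate an image
#'
#' Per-axis subsampling that keeps the samples at indices congruent to 0
#' modulo \code{s} on each axis (offset-0 convention). The output shape is
#' \code{(ceiling(rows/s), ceiling(cols/s))}.
#'
#' @param img a \linkS4class{RasterImage}.
#' @param s integer decimation factor >= 2, at most each dimension.
#' @return The decimated \linkS4class{RasterImage}.
#' @export
decimate <- function(img, s) {
  stopifnot(is(img, "RasterImage"))
  s <- as.integer(s)
  if (s < 2L) stop("decimation factor s must be >= 2")
  d <- dim(img@pixels)
  if (s > min(d[1:2]))
    stop(sprintf("s = %d exceeds an image dimension (%d x %d)", s,
                 d[1L], d[2L]))
  mapChannels(img, function(m)
    m[seq.int(1L, nrow(m), by = s), seq.int(1L, ncol(m), by = s),
      drop = FALSE])
}

#' Resize an image with a classical resampler
#'
#' Separable resampling with the chosen kernel under a centre-aligned
#' coordinate mapping (resizing to the input shape is the identity).
#' Out-of-range kernel taps are clamped to the border sample, and the
#' result is rounded and clipped to [0, 255]. Kernels: Keys cubic
#' convolution with a = -0.5 (\code{bicubic}), tent (\code{bilinear}),
#' 3-lobe Lanczos (\code{lanczos}), replication (\code{nearest}). Plain
#' interpolation, no antialias prefilter.
#'
#' @param img a \linkS4class{RasterImage}.
#' @param outShape integer (rows, cols) target shape.
#' @param method one of \code{nearest}, \code{bilinear}, \code{bicubic},
#'   \code{lanczos}.
#' @return The resized \linkS4class{RasterImage}.
#' @export
resizeImage <- function(img, outShape, method = "bicubic") {
  stopifnot(is(img, "RasterImage"))
  outShape <- as.integer(outShape)
  if (length(outShape) != 2L || any(outShape < 1L))
    stop("outShape must be two positive integers")
  d <- dim(img@pixels)
  if (method != "nearest") {
    for (ax in 1:2)
      if (outShape[ax] != d[ax] && min(outShape[ax], d[ax]) < 4L)
        stop("resampled dimensions must be >= 4 (kernel support)")
  }
  mapChannels(img, function(m)
    quantise8(resamplePlane(m, outShape[1L], outShape[2L], method)))
}

#' Bicubic resize
#'
#' Keys cubic-convolution resize (a = -0.5); see \code{\link{resizeImage}}.
#'
#' @inheritParams resizeImage
#' @return The resized \linkS4class{RasterImage}.
#' @export
bicubicResize <- function(img, outShape) resizeImage(img, outShape, "bicubic")

#' Decimation--bicubic degradation cycle
#'
#' Decimates by factor \code{s} and bicubically interpolates back to the
#' original shape: the canonical known-degradation benchmark. The
#' interpolation is carried out on the decimation grid (kept sample j sits
#' at original index \code{j*s}, so output index i reads the Keys kernel at
#' source coordinate \code{i/s}); kept samples are reproduced exactly and
#' the only loss is the information discarded by decimation. Larger
#' factors discard more, so PSNR/SSIM of the output against the original
#' decrease with \code{s} on textured images.
#'
#' @param img a \linkS4class{RasterImage}.
#' @param s integer factor >= 2 (the benchmark sweep uses 2..5).
#' @return A degraded \linkS4class{RasterImage} of the input's shape.
#' @export
bicubicCycle <- function(img, s) {
  stopifnot(is(img, "RasterImage"))
  s <- as.integer(s)
  if (s < 2L) stop("bicubic cycle factor s must be >= 2")
  d <- dim(img@pixels)[1:2]
  small <- decimate(img, s)
  ds <- dim(small@pixels)[1:2]
  Wr <- weightsForCoords((seq_len(d[1L]) - 1L) / s, ds[1L], keysCubic, 2L)
  Wc <- weightsForCoords((seq_len(d[2L]) - 1L) / s, ds[2L], keysCubic, 2L)
  mapChannels(small, function(m) quantise8(Wr %*% m %*% t(Wc)))
}

#' Defocus blur
#'
#' Channel-wise convolution with a normalised Gaussian or disk
#' (pillbox) kernel under reflected-boundary padding, emulating a
#' microscope whose focus is set inaccurately (or set on the background
#' rather than the cells). The kernel sums to 1, so constant images pass
#' through unchanged and the mean intensity is conserved. The output is
#' clipped to the 8-bit range but deliberately not re-quantised: rounding
#' would inject broadband quantisation noise on top of the blur, which
#' corrupts frequency-domain sharpness readings of heavily defocused
#' images.
#'
#' @param img a \linkS4class{RasterImage}.
#' @param spec a \linkS4class{DegradationSpec} of kind
#'   \code{defocus_gaussian} or \code{defocus_disk}; alternatively give
#'   \code{sigma} or \code{radius} directly.
#' @param sigma Gaussian sd in pixels (> 0).
#' @param radius disk radius in pixels (> 0).
#' @return The blurred \linkS4class{RasterImage}.
#' @examples
#' img <- RasterImage(matrix(rep(c(0, 255), 32), 8, 8))
#' blurred <- defocus(img, sigma = 2)
#' @export
defocus <- function(img, spec = NULL, sigma = NULL, radius = NULL) {
  stopifnot(is(img, "RasterImage"))
  if (!is.null(spec)) {
    stopifnot(is(spec, "DegradationSpec"))
    if (!spec@kind %in% c("defocus_gaussian", "defocus_disk"))
      stop("defocus expects a defocus_gaussian or defocus_disk spec")
    sigma <- spec@params$sigma
    radius <- spec@params$radius
  }
  if (!is.null(sigma)) {
    if (sigma <= 0) stop("sigma must be positive")
    g <- gaussianKernel1d(sigma)
    return(mapChannels(img, function(m)
      clampPixels(convolveReflectSep(m, g))))
  }
  if (is.null(radius)) stop("give a spec, sigma or radius")
  if (radius <= 0) stop("radius must be positive")
  kernel <- diskKernel2d(radius)
  mapChannels(img, function(m) clampPixels(convolveReflect(m, kernel)))
}

#' Apply a named degradation
#'
#' Dispatches a \linkS4class{DegradationSpec} to its simulator:
#' \describe{
#'   \item{bicubic_cycle}{\code{\link{bicubicCycle}} with \code{factor}.}
#'   \item{defocus_gaussian / defocus_disk}{\code{\link{defocus}}.}
#'   \item{dark_lighting}{global gain < 1 (param \code{gain}, default 0.5):
#'     an under-lit lamp or a dark room.}
#'   \item{vignette}{radial falloff (param \code{falloff}, default 0.6):
#'     the sample imaged off the lens axis, dark edges.}
#'   \item{closed_aperture}{gain plus contrast compression about mid-grey
#'     (params \code{gain} 0.7, \code{contrast} 0.6): a closed aperture or
#'     a mis-set condenser.}
#' }
#' All simulators are deterministic given the spec.
#'
#' @param img a \linkS4class{RasterImage}.
#' @param spec a \linkS4class{DegradationSpec}.
#' @return The degraded \linkS4class{RasterImage}.
#' @export
degrade <- function(img, spec) {
  stopifnot(is(img, "RasterImage"), is(spec, "DegradationSpec"))
  p <- spec@params
  switch(spec@kind,
    bicubic_cycle = bicubicCycle(img, p$factor),
    defocus_gaussian = , defocus_disk = defocus(img, spec),
    dark_lighting = {
      gain <- if (is.null(p$gain)) 0.5 else p$gain
      mapChannels(img, function(m) quantise8(m * gain))
    },
    vignette = {
      falloff <- if (is.null(p$falloff)) 0.6 else p$falloff
      d <- dim(img@pixels)
      cy <- (d[1L] + 1) / 2; cx <- (d[2L] + 1) / 2
      dist2 <- outer((seq_len(d[1L]) - cy)^2, (seq_len(d[2L]) - cx)^2, "+")
      fac <- 1 - falloff * dist2 / max(dist2)
      mapChannels(img, function(m) quantise8(m * fac))
    },
    closed_aperture = {
      gain <- if (is.null(p$gain)) 0.7 else p$gain
      contrast <- if (is.null(p$contrast)) 0.6 else p$contrast
      mapChannels(img, function(m)
        quantise8(gain * (128 + (m - 128) * contrast)))
    })
}

#' Classical upsampling
#'
#' Integer-factor upscaling with a classical resampler; the output shape is
#' the input shape times \code{scale} on each axis.
#'
#' @param img a \linkS4class{RasterImage}.
#' @param scale integer factor >= 2.
#' @param method \code{nearest}, \code{bilinear}, \code{bicubic} or
#'   \code{lanczos} (3 lobes).
#' @return The upscaled \linkS4class{RasterImage}.
#' @export
classicalUpsample <- function(img, scale, method = "bicubic") {
  stopifnot(is(img, "RasterImage"))
  scale <- as.integer(scale)
  if (scale < 2L) stop("scale must be >= 2")
  if (method != "nearest") resampleKernelFor(method)  # validate name early
  resizeImage(img, dim(img@pixels)[1:2] * scale, method)
}

# Run an external enhancement command on an image: template with {in}/{out}
# placeholders, exit 0 + readable output file signal success.
.runHook <- function(img, template) {
  inFile <- tempfile(fileext = ".png")
  outFile <- tempfile(fileext = ".png")
  on.exit(unlink(c(inFile, outFile)))
  writeRaster(img, inFile)
  cmd <- gsub("{out}", outFile, gsub("{in}", inFile, template, fixed = TRUE),
              fixed = TRUE)
  res <- suppressWarnings(system(cmd, intern = TRUE, ignore.stderr = FALSE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop(sprintf("enhancement hook failed (exit %d): %s\n%s", status, cmd,
                 paste(res, collapse = "\n")))
  if (!file.exists(outFile))
    stop(sprintf("enhancement hook produced no output file: %s", cmd))
  readRaster(outFile)
}

# Resolve an upsampler slot (method name, function(img, scale), or hook
# command template) into function(img, targetShape).
.resolveUpsampler <- function(upsampler, scale) {
  if (is.function(upsampler))
    return(function(img, target) {
      out <- upsampler(img, scale)
      if (!identical(dim(out@pixels)[1:2], target))
        out <- bicubicResize(out, target)
      out
    })
  if (is.character(upsampler) && grepl("{in}", upsampler, fixed = TRUE))
    return(function(img, target) {
      out <- .runHook(img, upsampler)
      if (!identical(dim(out@pixels)[1:2], target))
        out <- bicubicResize(out, target)
      out
    })
  if (is.character(upsampler)) {
    if (upsampler != "nearest") resampleKernelFor(upsampler)
    return(function(img, target) resizeImage(img, target, upsampler))
  }
  stop("upsampler must be a method name, a function(img, scale), or a command template with {in}/{out}")
}

#' Order-of-operations restoration pipeline
#'
#' Composes upsampling (super-resolution or a classical stand-in) with
#' subsampling in either order at the same factor: \code{sr_first}
#' upsamples by \code{scale} and then decimates by \code{scale};
#' \code{subsample_first} decimates first and then upsamples back. Both
#' orders return an image of the input's shape, so the two variants can be
#' scored against the original with full-reference metrics. Subsampling
#' first discards information that the upsampler cannot recover, which is
#' why the order matters.
#'
#' The upsampler slot accepts a classical method name, a function
#' \code{(img, scale) -> RasterImage}, or an external command template with
#' \code{{in}}/\code{{out}} placeholders, so deep SR models can be plugged
#' in without being a dependency.
#'
#' @param img a \linkS4class{RasterImage}.
#' @param order \code{"sr_first"} or \code{"subsample_first"}.
#' @param scale integer factor >= 2 (benchmarks use 2 and 4).
#' @param upsampler upsampler slot (default \code{"bicubic"}).
#' @return A \linkS4class{RasterImage} of the input's shape.
#' @export
orderedPipeline <- function(img, order = c("sr_first", "subsample_first"),
                            scale = 2L, upsampler = "bicubic") {
  stopifnot(is(img, "RasterImage"))
  order <- match.arg(order)
  scale <- as.integer(scale)
  if (scale < 2L) stop("pipeline scale must be >= 2")
  d <- dim(img@pixels)[1:2]
  up <- .resolveUpsampler(upsampler, scale)
  if (order == "sr_first") {
    decimate(up(img, d * scale), scale)
  } else {
    up(decimate(img, scale), d)
  }
}
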