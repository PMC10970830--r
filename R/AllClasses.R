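#' @import methods
NULL

#' RasterImage: an 8-bit raster with an explicit colour-space tag
#'
#' The universal currency of the toolkit: a 2-D (grayscale) or
#' rows x cols x 3 (colour) intensity array together with its bit depth and
#' colour space. All coordinates are (row, col), origin top-left. Intensities
#' are stored as base-R numerics but are always integer-valued and confined
#' to [0, 2^bitDepth - 1]; every operation that could produce fractional
#' values rounds and clips before constructing its result.
#'
#' @slot pixels numeric array, 2-D for \code{GRAY}, 3-D with three channels
#'   for \code{RGB} / \code{YCBCR}.
#' @slot bitDepth integer scalar; 8 is canonical.
#' @slot colorspace one of \code{"RGB"}, \code{"GRAY"}, \code{"YCBCR"}.
#' @exportClass RasterImage
setClass("RasterImage",
  representation(pixels = "array", bitDepth = "integer",
                 colorspace = "character"))

setValidity("RasterImage", function(object) {
  cs <- object@colorspace
  px <- object@pixels
  if (length(cs) != 1L || !cs %in% c("RGB", "GRAY", "YCBCR"))
    return("colorspace must be one of 'RGB', 'GRAY', 'YCBCR'")
  nd <- length(dim(px))
  if (cs == "GRAY" && nd != 2L)
    return("GRAY images must be 2-D")
  if (cs != "GRAY" && !(nd == 3L && dim(px)[3L] == 3L))
    return(sprintf("%s images must have 3 channels", cs))
  if (length(object@bitDepth) != 1L || object@bitDepth < 1L)
    return("bitDepth must be a positive integer scalar")
  if (anyNA(px))
    return("pixels must not contain NA")
  lim <- 2^object@bitDepth - 1
  rng <- range(px)
  if (rng[1L] < 0 || rng[2L] > lim)
    return(sprintf("intensities must lie in [0, %d]", as.integer(lim)))
  TRUE
})

#' Construct a RasterImage
#'
#' @param pixels numeric matrix (grayscale) or rows x cols x 3 array.
#' @param colorspace colour-space tag; inferred from dimensionality when
#'   missing (2-D gives \code{GRAY}, 3 channels give \code{RGB}).
#' @param bitDepth bit depth (default 8).
#' @return A \linkS4class{RasterImage}.
#' @examples
#' img <- RasterImage(matrix(0:24, 5, 5))
#' dim(img)
#' @export
RasterImage <- function(pixels, colorspace = NULL, bitDepth = 8L) {
  pixels <- as.array(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(colorspace))
    colorspace <- if (length(dim(pixels)) == 2L) "GRAY" else "RGB"
  new("RasterImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      colorspace = colorspace)
}

#' @describeIn RasterImage dimensions of the pixel array
#' @param x a RasterImage
#' @export
setMethod("dim", "RasterImage", function(x) dim(x@pixels))

setMethod("show", "RasterImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RasterImage %s, %d x %d%s, %d-bit\n", object@colorspace,
              d[1L], d[2L],
              if (length(d) == 3L) sprintf(" x %d", d[3L]) else "",
              object@bitDepth))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@pixels), max(object@pixels)))
})

#' PairedSample: an aligned (reference, degraded) image pair
#'
#' The unit of dataset handling for restoration benchmarks: a sharp
#' reference image and its degraded counterpart, matched by acquisition.
#' The pairwise PSNR may be cached on the object (\code{NA} when not yet
#' computed); when present it always equals \code{\link{psnr}(reference,
#' degraded)} under this package's convention.
#'
#' @slot reference,degraded \linkS4class{RasterImage} objects of identical
#'   shape.
#' @slot pairId character identifier.
#' @slot psnrDb cached pairwise PSNR in dB, or \code{NA}.
#' @exportClass PairedSample
setClass("PairedSample",
  representation(reference = "RasterImage", degraded = "RasterImage",
                 pairId = "character", psnrDb = "numeric"))

setValidity("PairedSample", function(object) {
  if (!identical(dim(object@reference), dim(object@degraded)))
    return("reference and degraded must have identical shape")
  if (length(object@pairId) != 1L)
    return("pairId must be a single string")
  if (length(object@psnrDb) != 1L)
    return("psnrDb must be a single value (possibly NA)")
  TRUE
})

#' Construct a PairedSample
#'
#' @param reference,degraded \linkS4class{RasterImage}s of identical shape.
#' @param pairId identifier string.
#' @param psnrDb cached pairwise PSNR; if \code{TRUE}, computed now.
#' @return A \linkS4class{PairedSample}.
#' @export
PairedSample <- function(reference, degraded, pairId, psnrDb = NA_real_) {
  if (isTRUE(psnrDb)) psnrDb <- psnr(reference, degraded)
  new("PairedSample", reference = reference, degraded = degraded,
      pairId = as.character(pairId), psnrDb = as.numeric(psnrDb))
}

setMethod("show", "PairedSample", function(object) {
  cat(sprintf("PairedSample '%s', %s, PSNR %s dB\n", object@pairId,
              paste(dim(object@reference)[1:2], collapse = " x "),
              if (is.na(object@psnrDb)) "not cached"
              else formatC(object@psnrDb, digits = 2, format = "f")))
})

#' RingMaskSet: a radial partition of the centred frequency plane
#'
#' Assigns every bin of a centred 2-D DFT to exactly one ring-shaped mask.
#' Radii are measured in normalised frequency (cycles/pixel) computed
#' per axis, so rings are circular in frequency and elliptical in index
#' space for non-square images; the per-axis Nyquist frequency is 0.5.
#'
#' @slot shape integer (rows, cols).
#' @slot nRings number of rings (>= 2).
#' @slot edges sorted radii, \code{edges[1] = 0} to the maximum attainable
#'   radius on the grid; length \code{nRings + 1}.
#' @slot assignment integer matrix of ring indices in 1..nRings; ring 1
#'   contains the DC bin.
#' @exportClass RingMaskSet
setClass("RingMaskSet",
  representation(shape = "integer", nRings = "integer", edges = "numeric",
                 assignment = "matrix"))

setValidity("RingMaskSet", function(object) {
  if (object@nRings < 2L) return("nRings must be >= 2")
  if (length(object@edges) != object@nRings + 1L)
    return("edges must have length nRings + 1")
  if (is.unsorted(object@edges) || object@edges[1L] != 0)
    return("edges must be sorted and start at 0")
  if (!identical(dim(object@assignment), as.integer(object@shape)))
    return("assignment shape must match shape")
  a <- object@assignment
  if (anyNA(a) || min(a) < 1L || max(a) > object@nRings)
    return("every bin must be assigned a ring index in 1..nRings")
  TRUE
})

setMethod("show", "RingMaskSet", function(object) {
  cat(sprintf("RingMaskSet %d x %d, %d rings, edges [0, %.4f]\n",
              object@shape[1L], object@shape[2L], object@nRings,
              object@edges[length(object@edges)]))
})

#' RingSpectrum: per-ring absolute-magnitude sums of a centred DFT
#'
#' The output of the frequency-ring sharpness analysis: for each ring of a
#' \linkS4class{RingMaskSet}, the sum of absolute DFT magnitudes over the
#' bins the ring contains. The ring energies always sum to the total
#' spectral magnitude of the plane (the rings partition the spectrum).
#'
#' @slot energies non-negative numeric vector, one entry per ring.
#' @slot edges ring edges in normalised frequency, length
#'   \code{length(energies) + 1}.
#' @slot total sum of all magnitudes over the plane.
#' @exportClass RingSpectrum
setClass("RingSpectrum",
  representation(energies = "numeric", edges = "numeric", total = "numeric"))

setValidity("RingSpectrum", function(object) {
  if (length(object@edges) != length(object@energies) + 1L)
    return("edges must have length(energies) + 1")
  if (any(object@energies < 0)) return("energies must be non-negative")
  tol <- 1e-6 * max(object@total, 1)
  if (abs(sum(object@energies) - object@total) > tol)
    return("sum(energies) must equal total (partition completeness)")
  TRUE
})

setMethod("show", "RingSpectrum", function(object) {
  cat(sprintf("RingSpectrum, %d rings, total |F| = %.4g\n",
              length(object@energies), object@total))
  frac <- if (object@total > 0) object@energies / object@total
          else rep(0, length(object@energies))
  cat("  energy fractions:", paste(formatC(frac, digits = 3, format = "f"),
                                   collapse = " "), "\n")
})

#' DegradationSpec: a named, parameterised image distortion
#'
#' Drives the distortion simulators: decimation--bicubic cycles, Gaussian
#' and disk defocus, and the illumination presets seen in practice at the
#' microscope (under-lit lamp, vignetting when the sample sits off the lens
#' axis, a closed aperture/condenser). Illumination presets are
#' parameterised test-fixture simulators, not calibrated optical models.
#'
#' @slot kind one of \code{bicubic_cycle}, \code{defocus_gaussian},
#'   \code{defocus_disk}, \code{dark_lighting}, \code{vignette},
#'   \code{closed_aperture}.
#' @slot params kind-specific parameter list.
#' @slot seed optional integer seed for stochastic components.
#' @exportClass DegradationSpec
setClass("DegradationSpec",
  representation(kind = "character", params = "list", seed = "integer"))

.degradationKinds <- c("bicubic_cycle", "defocus_gaussian", "defocus_disk",
                       "dark_lighting", "vignette", "closed_aperture")

setValidity("DegradationSpec", function(object) {
  if (!object@kind %in% .degradationKinds)
    return(paste("kind must be one of:",
                 paste(.degradationKinds, collapse = ", ")))
  p <- object@params
  switch(object@kind,
    bicubic_cycle = if (is.null(p$factor) || p$factor < 2)
      return("bicubic_cycle needs integer factor >= 2"),
    defocus_gaussian = if (is.null(p$sigma) || p$sigma <= 0)
      return("defocus_gaussian needs sigma > 0"),
    defocus_disk = if (is.null(p$radius) || p$radius <= 0)
      return("defocus_disk needs radius > 0"))
  TRUE
})

#' Construct a DegradationSpec
#'
#' @param kind distortion name; see \linkS4class{DegradationSpec}.
#' @param ... kind-specific parameters (\code{factor}, \code{sigma},
#'   \code{radius}, \code{gain}, \code{falloff}, \code{contrast}).
#' @param seed optional integer seed.
#' @return A \linkS4class{DegradationSpec}.
#' @examples
#' DegradationSpec("defocus_gaussian", sigma = 2)
#' @export
DegradationSpec <- function(kind, ..., seed = NA_integer_) {
  new("DegradationSpec", kind = kind, params = list(...),
      seed = as.integer(seed))
}

setMethod("show", "DegradationSpec", function(object) {
  pp <- paste(names(object@params), unlist(object@params),
              sep = "=", collapse = ", ")
  cat(sprintf("DegradationSpec '%s' (%s)\n", object@kind, pp))
})

#' GateModel: a calibrated sharp/defocused decision threshold
#'
#' The decision block of a quality-gated enhancement pipeline: a
#' one-dimensional threshold on the frequency-ring sharpness score,
#' calibrated on labelled sharp and defocused images. Images scoring below
#' the threshold are routed to enhancement.
#'
#' @slot cutoffRadius normalised-frequency cutoff the sharpness score uses.
#' @slot nRings ring count the sharpness score uses.
#' @slot threshold decision threshold on the sharpness score.
#' @slot calibrationStats list with balanced accuracy, per-class counts and
#'   the calibration score range.
#' @slot version character version tag.
#' @exportClass GateModel
setClass("GateModel",
  representation(cutoffRadius = "numeric", nRings = "integer",
                 threshold = "numeric", calibrationStats = "list",
                 version = "character"))

setValidity("GateModel", function(object) {
  if (object@cutoffRadius <= 0) return("cutoffRadius must be positive")
  rng <- object@calibrationStats$scoreRange
  if (!is.null(rng) && diff(rng) > 0 &&
      (object@threshold < rng[1L] || object@threshold > rng[2L]))
    return("threshold must lie within the calibration score range")
  TRUE
})

setMethod("show", "GateModel", function(object) {
  cat(sprintf(
    "GateModel v%s: enhance iff sharpnessScore < %.6g (cutoff %.3g, %d rings)\n",
    object@version, object@threshold, object@cutoffRadius, object@nRings))
  st <- object@calibrationStats
  if (!is.null(st$balancedAccuracy))
    cat(sprintf("  calibration: balanced accuracy %.3f on %d sharp / %d blurred\n",
                st$balancedAccuracy, st$nSharp, st$nBlurred))
})

#' InstanceMask: one segmented instance of a scene
#'
#' A boolean raster marking the pixels of a single instance, with a class
#' label and (for predictions) a confidence score. All instances of one
#' scene share the raster shape.
#'
#' @slot mask logical matrix with at least one TRUE pixel.
#' @slot label class identifier.
#' @slot score confidence in [0, 1]; \code{NA} for ground truth.
#' @exportClass InstanceMask
setClass("InstanceMask",
  representation(mask = "matrix", label = "character", score = "numeric"))

setValidity("InstanceMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (!any(object@mask)) return("mask must be non-empty")
  if (!is.na(object@score) && (object@score < 0 || object@score > 1))
    return("score must be in [0, 1] or NA")
  TRUE
})

#' Construct an InstanceMask
#'
#' @param mask logical matrix (or coercible) with at least one TRUE pixel.
#' @param label class label (default \code{"cell"}).
#' @param score prediction confidence in [0, 1]; \code{NA} for ground truth.
#' @return An \linkS4class{InstanceMask}.
#' @export
InstanceMask <- function(mask, label = "cell", score = NA_real_) {
  mode(mask) <- "logical"
  new("InstanceMask", mask = mask, label = as.character(label),
      score = as.numeric(score))
}

setMethod("show", "InstanceMask", function(object) {
  cat(sprintf("InstanceMask '%s', %d px%s\n", object@label,
              sum(object@mask),
              if (is.na(object@score)) " (ground truth)"
              else sprintf(", score %.3f", object@score)))
})

#' APResult: average precision at fixed IoU thresholds
#'
#' COCO-style instance-segmentation evaluation summary: AP at IoU 0.50 and
#' 0.75, the mean over the 0.50:0.05:0.95 grid, per-class values, and an
#' optional percent change against a named baseline variant.
#'
#' @slot apByThreshold named numeric, e.g. \code{c("0.5" = .., "0.75" = ..)}.
#' @slot map5095 mean AP over IoU 0.50:0.05:0.95.
#' @slot perClass list mapping class label to its AP vector.
#' @slot percentChange named numeric percent change vs a baseline, or empty.
#' @exportClass APResult
setClass("APResult",
  representation(apByThreshold = "numeric", map5095 = "numeric",
                 perClass = "list", percentChange = "numeric"))

setValidity("APResult", function(object) {
  vals <- c(object@apByThreshold, object@map5095)
  if (any(vals < 0 | vals > 1)) return("AP values must lie in [0, 1]")
  TRUE
})

setMethod("show", "APResult", function(object) {
  cat("APResult:",
      paste(sprintf("AP@%s = %.3f", names(object@apByThreshold),
                    object@apByThreshold), collapse = ", "),
      sprintf("| mAP[.50:.95] = %.3f\n", object@map5095))
})

#' SceneSpec: parameters of one synthetic cytology scene
#'
#' Describes a stained-cytology-like scene: clustered elliptical cells with
#' darker nuclei on a pale textured background, with additive sensor noise.
#' Generation is fully deterministic given the spec (including its seed).
#'
#' @slot shape integer (rows, cols).
#' @slot nCells number of cells to place (>= 0).
#' @slot axisRange ellipse semi-axis range in pixels, c(lo, hi).
#' @slot palette list with RGB triples \code{background}, \code{cytoplasm},
#'   \code{nucleus}, each in [0, 255].
#' @slot textureAmplitude amplitude of the smooth texture field (intensity
#'   units).
#' @slot noiseSigma standard deviation of per-pixel Gaussian noise.
#' @slot seed integer seed.
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(shape = "integer", nCells = "integer", axisRange = "numeric",
                 palette = "list", textureAmplitude = "numeric",
                 noiseSigma = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (object@nCells < 0L) return("nCells must be >= 0")
  if (length(object@axisRange) != 2L || object@axisRange[1L] <= 0 ||
      object@axisRange[1L] > object@axisRange[2L])
    return("axisRange must be 0 < lo <= hi")
  if (2 * object@axisRange[2L] > min(object@shape))
    return("cell axes must fit inside the scene")
  pal <- object@palette
  if (!all(c("background", "cytoplasm", "nucleus") %in% names(pal)))
    return("palette needs background, cytoplasm and nucleus entries")
  cols <- unlist(pal[c("background", "cytoplasm", "nucleus")])
  if (any(cols < 0 | cols > 255)) return("palette colours must be in [0, 255]")
  TRUE
})

#' Construct a SceneSpec
#'
#' Defaults emulate a Diff-Quik-stained aspirate at moderate magnification:
#' a pale background, purplish cytoplasm and a darker nucleus, mild texture
#' and sensor noise.
#'
#' @param shape scene shape (rows, cols).
#' @param nCells number of cells.
#' @param axisRange ellipse semi-axis range in pixels.
#' @param palette list of RGB triples (background, cytoplasm, nucleus).
#' @param textureAmplitude texture field amplitude (intensity units).
#' @param noiseSigma per-pixel Gaussian noise sd (intensity units).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return A \linkS4class{SceneSpec}.
#' @examples
#' spec <- SceneSpec(shape = c(96, 96), nCells = 5, seed = 7)
#' @export
SceneSpec <- function(shape = c(128L, 128L), nCells = 8L,
                      axisRange = c(6, 14),
                      palette = list(background = c(232, 226, 238),
                                     cytoplasm  = c(168, 148, 200),
                                     nucleus    = c(88, 58, 132)),
                      textureAmplitude = 12, noiseSigma = 4, seed = 1L) {
  new("SceneSpec", shape = as.integer(shape), nCells = as.integer(nCells),
      axisRange = as.numeric(axisRange), palette = palette,
      textureAmplitude = as.numeric(textureAmplitude),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec %d x %d, %d cells, axes [%g, %g] px, seed %d\n",
              object@shape[1L], object@shape[2L], object@nCells,
              object@axisRange[1L], object@axisRange[2L], object@seed))
})

#' SpectrumSpec: the defocus-severity law of a paired dataset
#'
#' Controls how blur severities are drawn when degraded partners are
#' generated for a set of scenes, so that the resulting pairwise-PSNR
#' histogram spans a controllable (narrow or wide) interval.
#'
#' @slot blurKind \code{"gaussian"} or \code{"disk"}.
#' @slot range c(lo, hi) for sigma (gaussian) or radius (disk); lo > 0.
#' @slot drawLaw \code{"uniform"} (draw within range) or \code{"fixed"}
#'   (always lo).
#' @slot seed integer seed for the severity draws.
#' @exportClass SpectrumSpec
setClass("SpectrumSpec",
  representation(blurKind = "character", range = "numeric",
                 drawLaw = "character", seed = "integer"))

setValidity("SpectrumSpec", function(object) {
  if (!object@blurKind %in% c("gaussian", "disk"))
    return("blurKind must be 'gaussian' or 'disk'")
  if (length(object@range) != 2L || object@range[1L] <= 0 ||
      object@range[1L] > object@range[2L])
    return("range must be 0 < lo <= hi")
  if (!object@drawLaw %in% c("uniform", "fixed"))
    return("drawLaw must be 'uniform' or 'fixed'")
  TRUE
})

#' Construct a SpectrumSpec
#'
#' @param blurKind \code{"gaussian"} or \code{"disk"}.
#' @param range severity range c(lo, hi); lo > 0.
#' @param drawLaw \code{"uniform"} or \code{"fixed"}.
#' @param seed integer seed.
#' @return A \linkS4class{SpectrumSpec}.
#' @export
SpectrumSpec <- function(blurKind = "gaussian", range = c(0.5, 6),
                         drawLaw = "uniform", seed = 1L) {
  new("SpectrumSpec", blurKind = blurKind, range = as.numeric(range),
      drawLaw = drawLaw, seed = as.integer(seed))
}
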