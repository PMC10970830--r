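#' @include AllClasses.R AllGenerics.R utils.R image_io.R
NULL

.fftShiftIndex <- function(n) ((seq_len(n) - 1L - n %/% 2L) %% n) + 1L

#' Centred 2-D DFT magnitude of a luminance plane
#'
#' Computes the unnormalised forward 2-D discrete Fourier transform of the
#' plane and shifts the zero-frequency component to the centre of the
#' spectrum: the DC bin sits at index \code{(rows \%/\% 2, cols \%/\% 2)}
#' (0-based). Returned values are the absolute magnitudes |F|. No window
#' or taper is applied.
#'
#' @param plane a GRAY \linkS4class{RasterImage} or a numeric matrix.
#' @return A non-negative numeric matrix of the plane's shape.
#' @examples
#' m <- centeredDFTMagnitude(matrix(7, 8, 8))
#' m[5, 5]          # DC magnitude = 8 * 8 * 7
#' sum(m) - m[5, 5] # all other bins 0
#' @export
centeredDFTMagnitude <- function(plane) {
  m <- asGrayMatrix(plane)
  if (nrow(m) < 1L || ncol(m) < 1L) stop("plane must be non-empty")
  f <- stats::fft(m)
  Mod(f[.fftShiftIndex(nrow(m)), .fftShiftIndex(ncol(m)), drop = FALSE])
}

#' Build ring-shaped frequency masks
#'
#' Partitions the centred frequency plane into \code{nRings} rings of equal
#' radial width. Each bin's radius is \code{sqrt(u^2 + v^2)} with
#' \code{u = (i - rows \%/\% 2)/rows} and \code{v = (j - cols \%/\% 2)/cols}
#' the per-axis normalised frequencies in cycles/pixel (per-axis Nyquist
#' 0.5), so rings are circular in normalised frequency and elliptical in
#' index space for non-square shapes. Ring k covers
#' \code{[edges[k], edges[k+1])}, with the last edge inclusive; ring 1
#' contains the DC bin.
#'
#' @param shape integer (rows, cols), both >= 2.
#' @param nRings number of rings (>= 2, default 10).
#' @return A \linkS4class{RingMaskSet}.
#' @export
buildRingMasks <- function(shape, nRings = 10L) {
  shape <- as.integer(shape)
  nRings <- as.integer(nRings)
  if (nRings < 2L) stop("nRings must be >= 2")
  if (any(shape < 2L)) stop("shape must be at least 2 x 2")
  rows <- shape[1L]; cols <- shape[2L]
  u <- (seq_len(rows) - 1L - rows %/% 2L) / rows
  v <- (seq_len(cols) - 1L - cols %/% 2L) / cols
  r <- sqrt(outer(u^2, v^2, "+"))
  nDistinct <- length(unique(as.vector(r)))
  if (nRings > nDistinct)
    stop(sprintf("nRings = %d exceeds the %d distinct radii on this grid",
                 nRings, nDistinct))
  edges <- seq(0, max(r), length.out = nRings + 1L)
  assignment <- matrix(findInterval(r, edges, rightmost.closed = TRUE),
                       rows, cols)
  new("RingMaskSet", shape = shape, nRings = nRings, edges = edges,
      assignment = assignment)
}

#' Ring spectrum: absolute-magnitude sums over ring masks
#'
#' For an image (or a precomputed magnitude array), sums the absolute DFT
#' magnitudes over each ring of a \linkS4class{RingMaskSet}. Because the
#' rings partition the spectrum, the ring energies always sum to the total
#' magnitude of the plane.
#'
#' @param x a \linkS4class{RasterImage} (its luminance plane is analysed),
#'   a grayscale matrix of pixel intensities, or \code{NULL} when
#'   \code{magnitude} is supplied directly.
#' @param masks a \linkS4class{RingMaskSet}; built on the fly from
#'   \code{nRings} when missing.
#' @param nRings ring count used when \code{masks} is missing.
#' @param magnitude optional precomputed centred |F| array (then \code{x}
#'   is ignored).
#' @return A \linkS4class{RingSpectrum}.
#' @examples
#' img <- RasterImage(matrix(128, 32, 32))
#' sp <- ringSpectrum(img, nRings = 4)
#' ringEnergies(sp)[1]   # all energy in the DC ring for a constant image
#' @export
ringSpectrum <- function(x = NULL, masks = NULL, nRings = 10L,
                         magnitude = NULL) {
  if (is.null(magnitude)) {
    if (is.null(x)) stop("supply an image or a magnitude array")
    magnitude <- centeredDFTMagnitude(x)
  }
  if (is.null(masks))
    masks <- buildRingMasks(dim(magnitude), nRings)
  if (!identical(dim(magnitude), as.integer(masks@shape)))
    stop(sprintf("magnitude shape %s does not match mask shape %s",
                 paste(dim(magnitude), collapse = "x"),
                 paste(masks@shape, collapse = "x")))
  energies <- numeric(masks@nRings)
  sums <- rowsum(as.vector(magnitude), as.vector(masks@assignment))
  energies[as.integer(rownames(sums))] <- sums[, 1L]
  new("RingSpectrum", energies = energies, edges = masks@edges,
      total = sum(magnitude))
}

#' High-frequency sharpness score
#'
#' Scalarises a ring spectrum into the fraction of total spectral energy
#' carried by rings whose lower edge lies at or above \code{cutoffRadius}
#' (default 0.25 cycles/pixel, half-Nyquist). The DC ring is never counted.
#' Defocus removes high-frequency content, so blurrier images score lower.
#' A degenerate spectrum with zero total energy scores 0.
#'
#' @param x a \linkS4class{RingSpectrum}, or anything
#'   \code{\link{ringSpectrum}} accepts.
#' @param cutoffRadius normalised-frequency cutoff, strictly between 0 and
#'   the outermost ring edge.
#' @param nRings ring count used when \code{x} is not already a spectrum.
#' @return A score in [0, 1].
#' @export
sharpnessScore <- function(x, cutoffRadius = 0.25, nRings = 10L) {
  sp <- if (is(x, "RingSpectrum")) x else ringSpectrum(x, nRings = nRings)
  edges <- sp@edges
  nr <- length(sp@energies)
  if (cutoffRadius <= 0 || cutoffRadius >= edges[nr + 1L])
    stop("cutoffRadius must lie strictly between 0 and the outermost edge")
  if (sp@total <= 0) return(0)
  sel <- edges[seq_len(nr)] >= cutoffRadius
  sel[1L] <- FALSE   # DC ring never counted
  sum(sp@energies[sel]) / sp@total
}

#' Bar plot of a ring spectrum
#'
#' Renders one bar per ring (x labelled by the ring's normalised-frequency
#' interval, y the absolute-magnitude sum) to a PNG or SVG file.
#'
#' @param spectrum a \linkS4class{RingSpectrum}.
#' @param out output path (\code{.png} or \code{.svg}).
#' @param log plot energies on a log axis (bar order is unchanged).
#' @return \code{out}, invisibly.
#' @export
spectrumBarplot <- function(spectrum, out, log = FALSE) {
  stopifnot(is(spectrum, "RingSpectrum"))
  ext <- .fileExt(out)
  dev <- switch(ext,
    png = function() grDevices::png(out, width = 800, height = 500),
    svg = function() grDevices::svg(out, width = 8, height = 5),
    stop(sprintf("unsupported plot format '.%s'; use png or svg", ext)))
  ok <- tryCatch({ dev(); TRUE },
                 error = function(e)
                   stop(sprintf("cannot write plot to '%s': %s", out,
                                conditionMessage(e)), call. = FALSE))
  on.exit(grDevices::dev.off())
  n <- length(spectrum@energies)
  labels <- sprintf("[%.2f,%.2f)", spectrum@edges[-(n + 1L)],
                    spectrum@edges[-1L])
  y <- spectrum@energies
  if (log) y <- log10(1 + y)
  graphics::barplot(y, names.arg = labels, las = 2, col = "steelblue",
                    xlab = "normalised frequency ring",
                    ylab = if (log) "log10(1 + sum |F|)" else "sum |F|",
                    main = "Ring spectrum")
  invisible(out)
}
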