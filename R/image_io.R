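#' @include AllClasses.R AllGenerics.R utils.R
NULL

# BT.601 full-range colour matrices (the "YCbCr" mode convention of common
# imaging libraries). Luminance weights sum to 1.
.bt601Forward <- matrix(c(
   0.299,     0.587,     0.114,
  -0.168736, -0.331264,  0.5,
   0.5,      -0.418688, -0.081312), nrow = 3, byrow = TRUE)

.bt601Inverse <- matrix(c(
  1,  0,         1.402,
  1, -0.344136, -0.714136,
  1,  1.772,     0), nrow = 3, byrow = TRUE)

.fileExt <- function(path) tolower(sub(".*\\.", "", basename(path)))

# Minimal reader for uncompressed 8-bit-palette and 24-bit BMP files
# (BITMAPINFOHEADER, bottom-up or top-down rows, 4-byte row padding).
# No installed R package reads BMP.
.readBMP <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL)))
    stop(sprintf("not a BMP file: '%s'", path))
  readBin(con, "integer", 2L, size = 4L)           # file size, reserved
  dataOffset <- readBin(con, "integer", 1L, size = 4L)
  headerSize <- readBin(con, "integer", 1L, size = 4L)
  if (headerSize < 40L)
    stop(sprintf("unsupported BMP header in '%s'", path))
  width  <- readBin(con, "integer", 1L, size = 4L)
  height <- readBin(con, "integer", 1L, size = 4L)
  readBin(con, "integer", 1L, size = 2L)           # planes
  bpp <- readBin(con, "integer", 1L, size = 2L)
  compression <- readBin(con, "integer", 1L, size = 4L)
  if (compression != 0L)
    stop(sprintf("compressed BMP not supported: '%s'", path))
  if (!bpp %in% c(8L, 24L))
    stop(sprintf("unsupported BMP bit depth %d in '%s'", bpp, path))
  palette <- NULL
  if (bpp == 8L) {
    seek(con, 14L + headerSize)
    pal <- readBin(con, "integer", 256L * 4L, size = 1L, signed = FALSE)
    palette <- matrix(pal, ncol = 4L, byrow = TRUE)[, 3:1, drop = FALSE]
  }
  seek(con, dataOffset)
  topDown <- height < 0L
  height <- abs(height)
  bytesPerRow <- ((width * bpp / 8 + 3) %/% 4) * 4
  raw <- readBin(con, "integer", bytesPerRow * height, size = 1L,
                 signed = FALSE)
  if (length(raw) < bytesPerRow * height)
    stop(sprintf("truncated BMP file: '%s'", path))
  rows <- matrix(raw, nrow = bytesPerRow)[seq_len(width * bpp / 8), ,
                                          drop = FALSE]
  rowOrder <- if (topDown) seq_len(height) else rev(seq_len(height))
  if (bpp == 8L) {
    m <- t(rows)[rowOrder, , drop = FALSE]
    px <- array(0, dim = c(height, width, 3L))
    for (k in 1:3) px[, , k] <- matrix(palette[m + 1L, k], height, width)
    if (all(px[, , 1] == px[, , 2]) && all(px[, , 2] == px[, , 3]))
      return(px[, , 1L])
    return(px)
  }
  px <- array(0, dim = c(height, width, 3L))
  for (k in 1:3)   # BMP stores BGR
    px[, , k] <- t(rows[seq.int(4L - k, by = 3L, length.out = width), ,
                        drop = FALSE])[rowOrder, , drop = FALSE]
  px
}

.pngBitDepth <- function(path) {
  hdr <- readBin(path, "raw", 25L)
  if (length(hdr) < 25L) return(8L)
  as.integer(hdr[25L])
}

#' Read a raster image
#'
#' Reads PNG, TIFF (8- or 16-bit), JPEG or BMP files into an 8-bit
#' \linkS4class{RasterImage}. Grayscale files yield \code{GRAY}, colour
#' files \code{RGB}; an alpha channel, when present, is dropped with a
#' warning. 16-bit inputs are down-converted to 8-bit by a right shift
#' (integer division by 256) and the conversion is reported via
#' \code{message()}.
#'
#' @param path path to a PNG/TIFF/JPEG/BMP file.
#' @return A \linkS4class{RasterImage} with \code{bitDepth = 8}.
#' @seealso \code{\link{writeRaster}}
#' @export
readRaster <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: file '%s' does not exist", path))
  ext <- .fileExt(path)
  px <- tryCatch(switch(ext,
    png = {
      x <- png::readPNG(path)
      depth <- .pngBitDepth(path)
      if (depth == 16L) {
        message(sprintf("16-bit PNG '%s' down-converted to 8-bit (>> 8)",
                        path))
        round(x * 65535) %/% 256
      } else round(x * 255)
    },
    tif = , tiff = {
      x <- tiff::readTIFF(path, info = TRUE)   # values scaled to [0, 1]
      bits <- attr(x, "bits.per.sample")
      if (is.null(bits)) bits <- 8L
      if (bits == 16L) {
        message(sprintf("16-bit TIFF '%s' down-converted to 8-bit (>> 8)",
                        path))
        round(x * 65535) %/% 256
      } else if (bits != 8L) {
        stop(sprintf("unsupported TIFF bit depth %d in '%s'", bits, path))
      } else round(x * 255)
    },
    jpg = , jpeg = round(jpeg::readJPEG(path) * 255),
    bmp = .readBMP(path),
    stop(sprintf("unsupported image format '.%s' for '%s'", ext, path))),
    error = function(e)
      stop(sprintf("failed to read image '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  px <- array(as.numeric(px), dim = dim(px))  # strip reader attributes
  if (length(dim(px)) == 3L && dim(px)[3L] == 4L) {
    warning(sprintf("alpha channel of '%s' dropped", path))
    px <- px[, , 1:3, drop = FALSE]
  }
  if (length(dim(px)) == 3L && dim(px)[3L] == 1L) px <- px[, , 1L]
  if (length(dim(px)) == 3L && dim(px)[3L] == 2L) {
    warning(sprintf("alpha channel of '%s' dropped", path))
    px <- px[, , 1L]
  }
  RasterImage(px, colorspace = if (length(dim(px)) == 2L) "GRAY" else "RGB")
}

#' Write a raster image
#'
#' Writes a \linkS4class{RasterImage} as 8-bit PNG or TIFF (both lossless:
#' a write-then-read round trip preserves every pixel).
#'
#' @param img a \linkS4class{RasterImage} (RGB or GRAY; YCBCR images are
#'   converted back to RGB first).
#' @param path output path ending in \code{.png}, \code{.tif} or
#'   \code{.tiff}.
#' @return \code{path}, invisibly.
#' @export
writeRaster <- function(img, path) {
  stopifnot(is(img, "RasterImage"))
  if (img@colorspace == "YCBCR") img <- toRGB(img)
  ext <- .fileExt(path)
  x <- img@pixels / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop(sprintf("unsupported output format '.%s'; use png or tiff", ext)))
  invisible(path)
}

#' Convert RGB to full-range BT.601 YCbCr
#'
#' \code{Y = 0.299 R + 0.587 G + 0.114 B}, with chroma channels offset by
#' 128; every channel is rounded to the nearest integer and clipped to
#' [0, 255]. \code{toRGB} inverts the transform (recovering RGB within
#' +/- 1 per channel, the integer-rounding loss).
#'
#' @param img an RGB \linkS4class{RasterImage}.
#' @return A YCBCR (resp. RGB) \linkS4class{RasterImage}.
#' @examples
#' rgb <- RasterImage(array(128, dim = c(4, 4, 3)))
#' pixels(toYCbCr(rgb))[1, 1, 1]  # Y = 128
#' @export
toYCbCr <- function(img) {
  stopifnot(is(img, "RasterImage"))
  if (img@colorspace != "RGB")
    stop("toYCbCr expects an RGB image")
  d <- dim(img@pixels)
  flat <- matrix(img@pixels, ncol = 3L)
  out <- flat %*% t(.bt601Forward)
  out[, 2:3] <- out[, 2:3] + 128
  RasterImage(array(quantise8(out), dim = d), colorspace = "YCBCR")
}

#' @rdname toYCbCr
#' @export
toRGB <- function(img) {
  stopifnot(is(img, "RasterImage"))
  if (img@colorspace == "RGB") return(img)
  if (img@colorspace != "YCBCR")
    stop("toRGB expects a YCBCR (or RGB) image")
  d <- dim(img@pixels)
  flat <- matrix(img@pixels, ncol = 3L)
  flat[, 2:3] <- flat[, 2:3] - 128
  out <- flat %*% t(.bt601Inverse)
  RasterImage(array(quantise8(out), dim = d), colorspace = "RGB")
}

#' Luminance plane of an image
#'
#' Grayscale images are returned unchanged; RGB images are routed through
#' the BT.601 conversion and the Y channel is extracted; YCBCR images yield
#' their first channel.
#'
#' @param img a \linkS4class{RasterImage}.
#' @return A GRAY \linkS4class{RasterImage}.
#' @export
luminance <- function(img) {
  stopifnot(is(img, "RasterImage"))
  switch(img@colorspace,
    GRAY = img,
    RGB = RasterImage(toYCbCr(img)@pixels[, , 1L], colorspace = "GRAY"),
    YCBCR = RasterImage(img@pixels[, , 1L], colorspace = "GRAY"))
}

#' Load a paired reference/degraded image dataset
#'
#' Walks two mirrored directory trees and pairs files by their relative
#' path without extension. Unmatched files and shape-mismatched pairs are
#' reported with a warning and skipped. The output order is lexicographic
#' in the pair id (byte order), independent of filesystem enumeration.
#'
#' @param refDir directory of reference (sharp) images.
#' @param degDir directory of degraded counterparts.
#' @param cachePsnr compute and cache the pairwise PSNR per pair?
#' @return A list of \linkS4class{PairedSample}s.
#' @export
loadPairedDataset <- function(refDir, degDir, cachePsnr = FALSE) {
  exts <- "\\.(png|tif|tiff|jpg|jpeg|bmp)$"
  listStems <- function(dir) {
    files <- list.files(dir, pattern = exts, recursive = TRUE,
                        ignore.case = TRUE)
    stems <- sub(exts, "", files, ignore.case = TRUE)
    stats::setNames(file.path(dir, files), stems)
  }
  refs <- listStems(refDir)
  degs <- listStems(degDir)
  common <- sort(intersect(names(refs), names(degs)), method = "radix")
  skipped <- c(setdiff(names(refs), names(degs)),
               setdiff(names(degs), names(refs)))
  if (length(skipped))
    warning(sprintf("unmatched files skipped: %s",
                    paste(sort(skipped, method = "radix"), collapse = ", ")))
  if (!length(common))
    stop(sprintf("no matched pairs between '%s' and '%s'", refDir, degDir))
  out <- list()
  for (stem in common) {
    ref <- readRaster(refs[[stem]])
    deg <- readRaster(degs[[stem]])
    if (!identical(dim(ref), dim(deg))) {
      warning(sprintf("pair '%s' rejected: shape mismatch (%s vs %s)", stem,
                      paste(dim(ref), collapse = "x"),
                      paste(dim(deg), collapse = "x")))
      next
    }
    out[[stem]] <- PairedSample(ref, deg, stem,
                                psnrDb = if (cachePsnr) TRUE else NA_real_)
  }
  if (!length(out))
    stop(sprintf("no valid pairs between '%s' and '%s'", refDir, degDir))
  unname(out)
}
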