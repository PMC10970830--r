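#' @include AllClasses.R AllGenerics.R utils.R image_io.R
NULL

#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(peak^2 / MSE)} in dB, with the MSE computed in double
#' precision on the luminance planes of the two images (colour inputs are
#' converted first). Identical images have zero MSE and return the
#' \code{+Inf} sentinel: identical pairs are legitimate inputs, not errors.
#'
#' @param ref,test \linkS4class{RasterImage}s or grayscale matrices of
#'   identical shape.
#' @param peak peak signal value (default 255 for 8-bit data).
#' @return PSNR in dB (possibly \code{+Inf}).
#' @examples
#' a <- matrix(0, 8, 8); b <- matrix(1, 8, 8)
#' psnr(a, b)   # 20 * log10(255) ~= 48.13 dB
#' @export
psnr <- function(ref, test, peak = 255) {
  r <- asGrayMatrix(ref)
  t <- asGrayMatrix(test)
  if (!identical(dim(r), dim(t)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(r), collapse = "x"),
                 paste(dim(t), collapse = "x")))
  mse <- mean((r - t)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# 11 x 11 Gaussian window, sigma 1.5, normalised (the original SSIM window).
.ssimWindow <- local({
  x <- seq.int(-5L, 5L)
  g <- exp(-x^2 / (2 * 1.5^2))
  k <- outer(g, g)
  k / sum(k)
})

#' Structural similarity index
#'
#' Mean local SSIM over the luminance planes with the original constants:
#' 11 x 11 Gaussian window with sigma 1.5, K1 = 0.01, K2 = 0.03, dynamic
#' range 255. Local statistics use valid-window convolution (no padding),
#' as in the reference implementation, so both dimensions must be at least
#' 11.
#'
#' @param ref,test \linkS4class{RasterImage}s or grayscale matrices of
#'   identical shape, min dimension >= 11.
#' @return mean SSIM in [-1, 1]; exactly 1 for identical inputs.
#' @export
ssim <- function(ref, test) {
  x <- asGrayMatrix(ref)
  y <- asGrayMatrix(test)
  if (!identical(dim(x), dim(y)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(x), collapse = "x"),
                 paste(dim(y), collapse = "x")))
  if (min(dim(x)) < 11L)
    stop("image smaller than the 11 x 11 SSIM window; pad the image or use a larger input")
  if (identical(x, y)) return(1)
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  w <- .ssimWindow
  mux  <- convolveValid(x, w)
  muy  <- convolveValid(y, w)
  sxx  <- convolveValid(x * x, w) - mux^2
  syy  <- convolveValid(y * y, w) - muy^2
  sxy  <- convolveValid(x * y, w) - mux * muy
  s <- ((2 * mux * muy + C1) * (2 * sxy + C2)) /
       ((mux^2 + muy^2 + C1) * (sxx + syy + C2))
  mean(s)
}

#' Per-pair quality-metric table
#'
#' Computes PSNR and SSIM for every \linkS4class{PairedSample} and appends
#' a mean row (\code{pair_id = "mean"}). Rows follow the input order.
#'
#' @param pairs non-empty list of \linkS4class{PairedSample}s.
#' @return A data.frame with columns \code{pair_id}, \code{psnr_db},
#'   \code{ssim}.
#' @export
metricTable <- function(pairs) {
  if (!length(pairs)) stop("empty dataset: no pairs to evaluate")
  rows <- lapply(pairs, function(p) {
    stopifnot(is(p, "PairedSample"))
    pd <- if (!is.na(p@psnrDb)) p@psnrDb else psnr(p@reference, p@degraded)
    data.frame(pair_id = p@pairId, psnr_db = pd,
               ssim = ssim(p@reference, p@degraded),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rbind(tab, data.frame(pair_id = "mean", psnr_db = mean(tab$psnr_db),
                        ssim = mean(tab$ssim)))
}

#' Percent change against a baseline
#'
#' \code{((value - baseline) / baseline) * 100}, rounded half away from
#' zero to 2 decimals — the convention of printed benchmark tables.
#' Vectorised over \code{value}.
#'
#' @param value measured value(s).
#' @param baseline reference value, non-zero.
#' @return percent change(s), rounded to 2 decimals.
#' @examples
#' percentChange(0.195, 0.156)  # 25.00
#' @export
percentChange <- function(value, baseline) {
  if (any(baseline == 0))
    stop("percent change is undefined for a zero baseline")
  roundHalfUp((value - baseline) / baseline * 100, 2L)
}
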