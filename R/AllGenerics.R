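#' @include AllClasses.R
NULL

#' Pixel array of an image
#' @param x a \linkS4class{RasterImage}
#' @return the numeric pixel array
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
setMethod("pixels", "RasterImage", function(x) x@pixels)

#' Colour-space tag of an image
#' @param x a \linkS4class{RasterImage}
#' @return one of \code{"RGB"}, \code{"GRAY"}, \code{"YCBCR"}
#' @export
setGeneric("colorspace", function(x) standardGeneric("colorspace"))

#' @rdname colorspace
setMethod("colorspace", "RasterImage", function(x) x@colorspace)

#' Bit depth of an image
#' @param x a \linkS4class{RasterImage}
#' @return integer bit depth
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname bitDepth
setMethod("bitDepth", "RasterImage", function(x) x@bitDepth)

#' Accessors for paired samples
#' @param x a \linkS4class{PairedSample}
#' @return the reference image
#' @export
setGeneric("reference", function(x) standardGeneric("reference"))

#' @rdname reference
setMethod("reference", "PairedSample", function(x) x@reference)

#' @rdname reference
#' @export
setGeneric("degraded", function(x) standardGeneric("degraded"))

#' @rdname reference
setMethod("degraded", "PairedSample", function(x) x@degraded)

#' @rdname reference
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))

#' @rdname reference
setMethod("pairId", "PairedSample", function(x) x@pairId)

#' Cached pairwise PSNR of a sample
#' @param x a \linkS4class{PairedSample}
#' @return PSNR in dB, or \code{NA} when not cached
#' @export
setGeneric("psnrDb", function(x) standardGeneric("psnrDb"))

#' @rdname psnrDb
setMethod("psnrDb", "PairedSample", function(x) x@psnrDb)

#' Ring energies of a spectrum
#' @param x a \linkS4class{RingSpectrum}
#' @return numeric vector of per-ring absolute-magnitude sums
#' @export
setGeneric("ringEnergies", function(x) standardGeneric("ringEnergies"))

#' @rdname ringEnergies
setMethod("ringEnergies", "RingSpectrum", function(x) x@energies)

#' Ring edges (normalised frequency)
#' @param x a \linkS4class{RingSpectrum} or \linkS4class{RingMaskSet}
#' @return numeric vector of ring edges
#' @export
setGeneric("ringEdges", function(x) standardGeneric("ringEdges"))

#' @rdname ringEdges
setMethod("ringEdges", "RingSpectrum", function(x) x@edges)

#' @rdname ringEdges
setMethod("ringEdges", "RingMaskSet", function(x) x@edges)

#' Total spectral magnitude
#' @param x a \linkS4class{RingSpectrum}
#' @return sum of |F| over all bins
#' @export
setGeneric("spectrumTotal", function(x) standardGeneric("spectrumTotal"))

#' @rdname spectrumTotal
setMethod("spectrumTotal", "RingSpectrum", function(x) x@total)

#' Mask, label and score of an instance
#' @param x an \linkS4class{InstanceMask}
#' @return the logical mask matrix
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' @rdname maskPixels
setMethod("maskPixels", "InstanceMask", function(x) x@mask)

#' @rdname maskPixels
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' @rdname maskPixels
setMethod("maskLabel", "InstanceMask", function(x) x@label)

#' @rdname maskPixels
#' @export
setGeneric("maskScore", function(x) standardGeneric("maskScore"))

#' @rdname maskPixels
setMethod("maskScore", "InstanceMask", function(x) x@score)

#' AP values of an evaluation
#' @param x an \linkS4class{APResult}
#' @return named numeric of AP at the fixed IoU thresholds
#' @export
setGeneric("apByThreshold", function(x) standardGeneric("apByThreshold"))

#' @rdname apByThreshold
setMethod("apByThreshold", "APResult", function(x) x@apByThreshold)

#' @rdname apByThreshold
#' @export
setGeneric("map5095", function(x) standardGeneric("map5095"))

#' @rdname apByThreshold
setMethod("map5095", "APResult", function(x) x@map5095)

#' Gate threshold and calibration statistics
#' @param x a \linkS4class{GateModel}
#' @return the decision threshold on the sharpness score
#' @export
setGeneric("gateThreshold", function(x) standardGeneric("gateThreshold"))

#' @rdname gateThreshold
setMethod("gateThreshold", "GateModel", function(x) x@threshold)

#' @rdname gateThreshold
#' @export
setGeneric("calibrationStats", function(x) standardGeneric("calibrationStats"))

#' @rdname gateThreshold
setMethod("calibrationStats", "GateModel", function(x) x@calibrationStats)
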