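#' @include AllClasses.R AllGenerics.R ring_spectrum.R degrade_restore.R
NULL

#' Calibrate the sharp/defocused decision gate
#'
#' Computes the frequency-ring sharpness score for every calibration image
#' and places a decision threshold at the candidate midpoint (between
#' adjacent sorted scores) that maximises balanced accuracy — the mean of
#' per-class recalls, robust to the class imbalance of real QC streams.
#' Images scoring strictly below the threshold are routed to enhancement;
#' ties among candidates are broken toward the higher threshold, favouring
#' enhancement. When the two classes' score distributions overlap at every
#' candidate, the model is still returned and its calibration statistics
#' expose the achievable balanced accuracy.
#'
#' @param sharp,blurred lists of \linkS4class{RasterImage}s (>= 2 each).
#' @param cutoffRadius sharpness-score cutoff (default 0.25).
#' @param nRings ring count for the score (default 10).
#' @return A \linkS4class{GateModel}.
#' @export
calibrateGate <- function(sharp, blurred, cutoffRadius = 0.25,
                          nRings = 10L) {
  if (length(sharp) < 2L || length(blurred) < 2L)
    stop("calibration needs at least 2 images per class")
  score <- function(imgs) vapply(imgs, function(im)
    sharpnessScore(luminance(im), cutoffRadius, nRings), numeric(1L))
  sSharp <- score(sharp)
  sBlur <- score(blurred)
  all <- sort(unique(c(sSharp, sBlur)))
  candidates <- if (length(all) > 1L)
    (all[-length(all)] + all[-1L]) / 2 else all
  balacc <- vapply(candidates, function(thr)
    (mean(sBlur < thr) + mean(sSharp >= thr)) / 2, numeric(1L))
  best <- max(balacc)
  thr <- max(candidates[balacc >= best - 1e-12])  # ties -> higher threshold
  new("GateModel", cutoffRadius = cutoffRadius, nRings = as.integer(nRings),
      threshold = thr,
      calibrationStats = list(
        balancedAccuracy = best,
        sensitivity = mean(sBlur < thr),
        specificity = mean(sSharp >= thr),
        nSharp = length(sSharp), nBlurred = length(sBlur),
        scoreRange = range(c(sSharp, sBlur))),
      version = "1")
}

#' Route an image through the decision gate
#'
#' @param img a \linkS4class{RasterImage}.
#' @param model a calibrated \linkS4class{GateModel}.
#' @return A list with \code{decision} (\code{"enhance"} iff the sharpness
#'   score is below the model threshold, else \code{"pass_through"}) and
#'   the \code{score} itself.
#' @export
routeImage <- function(img, model) {
  stopifnot(is(img, "RasterImage"), is(model, "GateModel"))
  s <- sharpnessScore(luminance(img), model@cutoffRadius, model@nRings)
  list(decision = if (s < model@threshold) "enhance" else "pass_through",
       score = s)
}

#' Quality-gated enhancement pipeline
#'
#' Routes the image through the gate: pass-through returns the input
#' unchanged; enhance applies the enhancer. If an external enhancement hook
#' fails, the original image is returned with the failure flagged in the
#' record rather than lost.
#'
#' @param img a \linkS4class{RasterImage}.
#' @param model a calibrated \linkS4class{GateModel}.
#' @param enhancer a function \code{RasterImage -> RasterImage}, an
#'   external command template with \code{{in}}/\code{{out}} placeholders,
#'   or a classical method name (then: upsample x2 with that method and
#'   resize back, a smoothing re-interpolation).
#' @return A list with \code{image} and a \code{record} list
#'   (\code{score}, \code{decision}, \code{enhancer}, \code{failed}).
#' @export
gatedPipeline <- function(img, model, enhancer = "bicubic") {
  routing <- routeImage(img, model)
  enhancerId <- if (is.function(enhancer)) "function" else enhancer
  record <- list(score = routing$score, decision = routing$decision,
                 enhancer = enhancerId, failed = FALSE)
  if (routing$decision == "pass_through")
    return(list(image = img, record = record))
  out <- tryCatch({
    if (is.function(enhancer)) enhancer(img)
    else if (grepl("{in}", enhancer, fixed = TRUE)) {
      res <- .runHook(img, enhancer)
      if (!identical(dim(res@pixels)[1:2], dim(img@pixels)[1:2]))
        res <- bicubicResize(res, dim(img@pixels)[1:2])
      res
    } else resizeImage(classicalUpsample(img, 2L, enhancer),
                       dim(img@pixels)[1:2], enhancer)
  }, error = function(e) e)
  if (inherits(out, "error")) {
    record$failed <- TRUE
    record$error <- conditionMessage(out)
    return(list(image = img, record = record))
  }
  list(image = out, record = record)
}

#' Persist a gate model as JSON
#'
#' The model is a small plain-text document (threshold, score parameters,
#' calibration statistics) so deployed gates stay auditable.
#'
#' @param model a \linkS4class{GateModel}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeGateModel <- function(model, path) {
  stopifnot(is(model, "GateModel"))
  doc <- list(version = model@version, cutoffRadius = model@cutoffRadius,
              nRings = model@nRings, threshold = model@threshold,
              calibrationStats = model@calibrationStats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGateModel
#' @return \code{readGateModel}: the \linkS4class{GateModel} read back.
#' @export
readGateModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GateModel", cutoffRadius = doc$cutoffRadius,
      nRings = as.integer(doc$nRings), threshold = doc$threshold,
      calibrationStats = as.list(doc$calibrationStats),
      version = as.character(doc$version))
}
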