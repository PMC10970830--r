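#' @include AllClasses.R AllGenerics.R quality_metrics.R
NULL

#' Split a labelled raster into instance masks
#'
#' Each distinct non-zero integer label becomes one
#' \linkS4class{InstanceMask} (class label \code{"cell"} unless remapped).
#'
#' @param raster integer matrix; 0 = background, k > 0 = instance k.
#' @param label class label for all instances.
#' @return A list of \linkS4class{InstanceMask}s, ordered by label value.
#' @export
masksFromLabels <- function(raster, label = "cell") {
  ids <- sort(setdiff(unique(as.vector(raster)), 0))
  lapply(ids, function(k) InstanceMask(raster == k, label = label))
}

#' Intersection-over-union of two masks
#'
#' @param a,b \linkS4class{InstanceMask}s or logical matrices of identical
#'   shape.
#' @return |a intersect b| / |a union b| in [0, 1].
#' @export
maskIoU <- function(a, b) {
  ma <- if (is(a, "InstanceMask")) a@mask else a
  mb <- if (is(b, "InstanceMask")) b@mask else b
  if (!identical(dim(ma), dim(mb)))
    stop("mask shape mismatch")
  inter <- sum(ma & mb)
  union <- sum(ma | mb)
  if (union == 0) return(0)
  inter / union
}

#' Greedy score-ordered instance matching
#'
#' COCO-style matching at one IoU threshold within one class: predictions
#' are sorted by descending score (ties keep input order) and each is
#' greedily assigned to the unmatched ground truth with the highest IoU at
#' or above the threshold.
#'
#' @param preds,gts lists of \linkS4class{InstanceMask}s sharing one raster
#'   shape; matching is per class.
#' @param iouThr IoU threshold in (0, 1].
#' @return A data.frame with one row per prediction (input index, score,
#'   label, matched gt index or NA, achieved IoU), ordered by descending
#'   score, plus attributes \code{nGt} (named per-class ground-truth
#'   counts).
#' @export
matchInstances <- function(preds, gts, iouThr = 0.5) {
  predLabels <- vapply(preds, maskLabel, character(1L))
  gtLabels <- if (length(gts)) vapply(gts, maskLabel, character(1L))
              else character(0L)
  scores <- vapply(preds, maskScore, numeric(1L))
  ord <- order(-scores)   # stable: ties keep input order
  rows <- list()
  gtMatched <- rep(FALSE, length(gts))
  for (i in ord) {
    cls <- predLabels[i]
    cand <- which(gtLabels == cls & !gtMatched)
    bestJ <- NA_integer_; bestIoU <- 0
    for (j in cand) {
      v <- maskIoU(preds[[i]], gts[[j]])
      if (v >= iouThr && v > bestIoU) { bestIoU <- v; bestJ <- j }
    }
    if (!is.na(bestJ)) gtMatched[bestJ] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      pred = i, score = scores[i], label = cls, gt = bestJ,
      iou = if (is.na(bestJ)) NA_real_ else bestIoU)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(pred = integer(0), score = numeric(0),
                         label = character(0), gt = integer(0),
                         iou = numeric(0))
  attr(out, "nGt") <- table(factor(gtLabels,
                                   levels = sort(unique(c(gtLabels,
                                                          predLabels)))))
  out
}

# 101-point interpolated AP from pooled (score, tp) pairs and a GT count.
.ap101 <- function(scores, tp, nGt) {
  ord <- order(-scores)
  tp <- tp[ord]
  cumTp <- cumsum(tp)
  precision <- cumTp / seq_along(tp)
  recall <- cumTp / nGt
  # precision envelope: max precision at recall >= r
  grid <- seq(0, 1, by = 0.01)
  if (!length(tp)) return(0)
  env <- rev(cummax(rev(precision)))
  idx <- findInterval(grid, recall, left.open = TRUE) + 1L
  p <- ifelse(idx <= length(env), env[idx], 0)
  mean(p)
}

#' COCO-style average precision over scenes
#'
#' Pools score-ranked matches across scenes, builds the precision--recall
#' curve per class, applies the precision envelope and averages precision
#' on the 101-point recall grid (0, 0.01, ..., 1); class APs are then
#' averaged.
#'
#' @param scenes list of scenes, each a list with elements \code{preds} and
#'   \code{gts} (lists of \linkS4class{InstanceMask}s).
#' @param iouThr IoU matching threshold.
#' @return AP in [0, 1].
#' @export
averagePrecision <- function(scenes, iouThr = 0.5) {
  classes <- sort(unique(unlist(lapply(scenes, function(sc)
    c(vapply(sc$gts, maskLabel, character(1L)),
      vapply(sc$preds, maskLabel, character(1L)))))))
  nGtTotal <- 0L
  perClass <- vapply(classes, function(cls) {
    scores <- numeric(0); tp <- logical(0); nGt <- 0L
    for (sc in scenes) {
      m <- matchInstances(sc$preds, sc$gts, iouThr)
      keep <- m$label == cls
      scores <- c(scores, m$score[keep])
      tp <- c(tp, !is.na(m$gt[keep]))
      nGt <- nGt + sum(vapply(sc$gts, maskLabel, character(1L)) == cls)
    }
    if (nGt == 0L) return(NA_real_)
    nGtTotal <<- nGtTotal + nGt
    .ap101(scores, tp, nGt)
  }, numeric(1L))
  if (nGtTotal == 0L)
    stop("average precision is undefined without ground-truth instances")
  mean(perClass, na.rm = TRUE)
}

#' Full AP evaluation at the standard thresholds
#'
#' @param scenes as in \code{\link{averagePrecision}}.
#' @param thresholds IoU thresholds reported individually.
#' @param grid IoU grid averaged into \code{map5095}.
#' @return An \linkS4class{APResult}.
#' @export
evaluateScenes <- function(scenes, thresholds = c(0.5, 0.75),
                           grid = seq(0.5, 0.95, by = 0.05)) {
  byThr <- vapply(thresholds, function(t) averagePrecision(scenes, t),
                  numeric(1L))
  names(byThr) <- as.character(thresholds)
  gridAp <- vapply(grid, function(t) averagePrecision(scenes, t),
                   numeric(1L))
  new("APResult", apByThreshold = byThr, map5095 = mean(gridAp),
      perClass = list(), percentChange = numeric(0))
}

#' Percent-change report of pipeline variants against a baseline
#'
#' Builds the benchmark-table-shaped report: for each variant, the percent
#' change of mAP_50 and mAP_75 relative to the named baseline (whose own
#' rows read 0.00). Rows keep the input order.
#'
#' @param variants either a data.frame with columns \code{variant},
#'   \code{map_50}, \code{map_75}, or a named list of
#'   \linkS4class{APResult}s (AP at 0.5 / 0.75 are used).
#' @param baseline name of the baseline variant.
#' @return A data.frame with columns \code{variant}, \code{map_50},
#'   \code{map_75}, \code{map_50_pct_change}, \code{map_75_pct_change}.
#' @examples
#' tab <- data.frame(variant = c("low quality", "enhanced"),
#'                   map_50 = c(0.226, 0.279), map_75 = c(0.156, 0.195))
#' evaluateVariants(tab, baseline = "low quality")
#' @export
evaluateVariants <- function(variants, baseline) {
  if (is.list(variants) && !is.data.frame(variants)) {
    variants <- data.frame(
      variant = names(variants),
      map_50 = vapply(variants, function(r) r@apByThreshold[["0.5"]],
                      numeric(1L)),
      map_75 = vapply(variants, function(r) r@apByThreshold[["0.75"]],
                      numeric(1L)),
      stringsAsFactors = FALSE)
  }
  if (!baseline %in% variants$variant)
    stop(sprintf("baseline '%s' not found; available variants: %s", baseline,
                 paste(variants$variant, collapse = ", ")))
  base <- variants[match(baseline, variants$variant), ]
  variants$map_50_pct_change <- percentChange(variants$map_50, base$map_50)
  variants$map_75_pct_change <- percentChange(variants$map_75, base$map_75)
  rownames(variants) <- NULL
  variants
}

#' Published end-to-end pipeline benchmark table
#'
#' The mAP_50/mAP_75 columns of a published end-to-end benchmark of
#' segmentation quality on a veterinary-cytology dataset, comparing a
#' high-quality dataset, its low-quality (defocused) counterpart, and four
#' enhancement pipelines that combine x2/x4 super-resolution with
#' subsampling in both orders. Shipped so the percent-change accounting can
#' be reproduced from the printed values.
#'
#' @return A data.frame with columns \code{variant}, \code{map_50},
#'   \code{map_75}.
#' @export
pipelineBenchmark <- function() {
  utils::read.csv(system.file("extdata", "pipeline_benchmark.csv",
                              package = "cytofocus"),
                  stringsAsFactors = FALSE)
}
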