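# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately written along different algorithmic paths than
# the package implementation they check.

# Naive O(N^4) centred 2-D DFT magnitude: explicit complex exponential sums
# per output bin, DC moved to (rows %/% 2, cols %/% 2) by direct index
# arithmetic.
naiveCenteredDFT <- function(m) {
  M <- nrow(m); N <- ncol(m)
  out <- matrix(0, M, N)
  for (ui in seq_len(M)) {
    u <- ui - 1L - M %/% 2L          # centred frequency index
    uu <- ((u %% M) + M) %% M        # plain DFT index
    for (vi in seq_len(N)) {
      v <- vi - 1L - N %/% 2L
      vv <- ((v %% N) + N) %% N
      acc <- 0 + 0i
      for (x in seq_len(M) - 1L)
        for (y in seq_len(N) - 1L)
          acc <- acc + m[x + 1L, y + 1L] *
            exp(-2i * pi * (uu * x / M + vv * y / N))
      out[ui, vi] <- Mod(acc)
    }
  }
  out
}

# Brute-force 101-point interpolated AP: naive per-grid-point search for
# the maximum precision at recall >= r over the raw PR points.
bruteAP101 <- function(scores, tp, nGt) {
  if (!length(scores)) return(0)
  ord <- order(-scores)
  tp <- tp[ord]
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / nGt
  vals <- vapply(seq(0, 1, by = 0.01), function(r) {
    ok <- rec >= r
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1L))
  mean(vals)
}

# Brute-force AP over scenes for a single class, re-deriving the TP/FP
# labels with an independent (exhaustive best-first) matcher.
bruteScenesAP <- function(scenes, iouThr) {
  scores <- numeric(0); tp <- logical(0); nGt <- 0L
  for (sc in scenes) {
    nGt <- nGt + length(sc$gts)
    if (!length(sc$preds)) next
    sPred <- vapply(sc$preds, maskScore, numeric(1))
    taken <- rep(FALSE, length(sc$gts))
    for (i in order(-sPred)) {
      ious <- vapply(seq_along(sc$gts), function(j)
        if (taken[j]) -1 else maskIoU(sc$preds[[i]], sc$gts[[j]]),
        numeric(1))
      hit <- length(ious) && max(ious) >= iouThr
      if (hit) taken[which.max(ious)] <- TRUE
      scores <- c(scores, sPred[i])
      tp <- c(tp, hit)
    }
  }
  bruteAP101(scores, tp, nGt)
}

# A reproducible textured grayscale plane (deterministic, no RNG).
texturedPlane <- function(n = 32) {
  ij <- outer(seq_len(n), seq_len(n), function(i, j)
    127 + 60 * sin(2 * pi * i * 5 / n) * cos(2 * pi * j * 3 / n) +
      40 * sin(2 * pi * (i + 2 * j) * 9 / n))
  quantiseTo8 <- function(x) pmin(pmax(round(x), 0), 255)
  quantiseTo8(ij)
}

# Minimal uncompressed 24-bit BMP writer (bottom-up rows), used to build
# read fixtures at test time.
writeBMP24 <- function(px, path) {
  h <- dim(px)[1L]; w <- dim(px)[2L]
  rowBytes <- ((w * 3 + 3) %/% 4) * 4
  dataSize <- rowBytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4D)), con)
  writeBin(as.integer(54 + dataSize), con, size = 4)
  writeBin(0L, con, size = 4)
  writeBin(54L, con, size = 4)
  writeBin(40L, con, size = 4)
  writeBin(as.integer(w), con, size = 4)
  writeBin(as.integer(h), con, size = 4)    # positive: bottom-up
  writeBin(1L, con, size = 2)
  writeBin(24L, con, size = 2)
  writeBin(0L, con, size = 4)               # BI_RGB
  writeBin(as.integer(dataSize), con, size = 4)
  writeBin(c(2835L, 2835L, 0L, 0L), con, size = 4)
  for (r in rev(seq_len(h))) {
    row <- integer(rowBytes)
    for (c in seq_len(w)) {
      base <- (c - 1L) * 3L
      row[base + 1L] <- px[r, c, 3L]        # B
      row[base + 2L] <- px[r, c, 2L]        # G
      row[base + 3L] <- px[r, c, 1L]        # R
    }
    writeBin(as.integer(row), con, size = 1)
  }
  invisible(path)
}

# Seeded prediction masks for AP tests: ground-truth masks shifted by a
# seeded offset (drops some IoU below 1), plus spurious blobs as FPs.
perturbedPredictions <- function(gts, shape, seed) {
  set.seed(seed)
  preds <- list()
  for (g in gts) {
    dy <- sample(-2:2, 1); dx <- sample(-2:2, 1)
    m <- matrix(FALSE, shape[1], shape[2])
    idx <- which(maskPixels(g), arr.ind = TRUE)
    idx[, 1] <- pmin(pmax(idx[, 1] + dy, 1L), shape[1])
    idx[, 2] <- pmin(pmax(idx[, 2] + dx, 1L), shape[2])
    m[idx] <- TRUE
    preds[[length(preds) + 1L]] <-
      InstanceMask(m, "cell", score = stats::runif(1, 0.5, 1))
  }
  nFp <- sample(0:2, 1)
  for (k in seq_len(nFp)) {
    cy <- sample(5:(shape[1] - 5), 1); cx <- sample(5:(shape[2] - 5), 1)
    m <- matrix(FALSE, shape[1], shape[2])
    m[(cy - 2):(cy + 2), (cx - 2):(cx + 2)] <- TRUE
    preds[[length(preds) + 1L]] <-
      InstanceMask(m, "cell", score = stats::runif(1, 0, 0.5))
  }
  preds
}
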