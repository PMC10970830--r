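mk <- function(cells, shape = c(4, 4), label = "cell", score = NA_real_) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (rc in cells) m[rc[1], rc[2]] <- TRUE
  InstanceMask(m, label, score)
}

test_that("mask IoU matches brute-force pixel counting", {
  a <- mk(list(c(1, 1), c(1, 2)))
  b <- mk(list(c(1, 2), c(1, 3)))
  expect_identical(maskIoU(a, a), 1)
  expect_identical(maskIoU(a, mk(list(c(3, 3)))), 0)
  expect_equal(maskIoU(a, b), 1 / 3)
  expect_error(maskIoU(a, InstanceMask(matrix(TRUE, 5, 5))), "mismatch")
})

test_that("greedy matching follows score order and the IoU threshold", {
  gt <- mk(list(c(1, 1), c(1, 2), c(2, 1), c(2, 2)))
  exact <- mk(list(c(1, 1), c(1, 2), c(2, 1), c(2, 2)), score = 0.9)
  m <- matchInstances(list(exact), list(gt), 0.5)
  expect_false(anyNA(m$gt))

  # two predictions on one ground truth: only the higher-scored matches
  lower <- mk(list(c(1, 1), c(1, 2), c(2, 1), c(2, 2)), score = 0.4)
  m2 <- matchInstances(list(lower, exact), list(gt), 0.5)
  expect_identical(m2$pred, c(2L, 1L))      # sorted by descending score
  expect_identical(is.na(m2$gt), c(FALSE, TRUE))

  # IoU below threshold: neither matched
  off <- mk(list(c(1, 1), c(3, 3), c(3, 4), c(4, 3), c(4, 4)), score = 0.8)
  m3 <- matchInstances(list(off), list(gt), 0.5)
  expect_true(is.na(m3$gt[1]))
})

test_that("AP hits its closed-form extremes", {
  gt <- list(mk(list(c(1, 1), c(1, 2))), mk(list(c(3, 3), c(3, 4))))
  perfect <- list(
    mk(list(c(1, 1), c(1, 2)), score = 0.9),
    mk(list(c(3, 3), c(3, 4)), score = 0.8))
  expect_identical(averagePrecision(list(list(preds = perfect, gts = gt)),
                                    0.5), 1)
  expect_identical(averagePrecision(list(list(preds = list(), gts = gt)),
                                    0.5), 0)
  expect_error(averagePrecision(list(list(preds = perfect, gts = list())),
                                0.5), "ground-truth")
})

test_that("AP for a mixed TP/FP ranking matches the exhaustive PR envelope", {
  gts <- list(mk(list(c(1, 1), c(1, 2))), mk(list(c(3, 3), c(3, 4))))
  preds <- list(
    mk(list(c(1, 1), c(1, 2)), score = 0.9),              # TP
    mk(list(c(4, 1), c(4, 2)), score = 0.8),              # FP
    mk(list(c(3, 3), c(3, 4)), score = 0.7))              # TP
  scene <- list(preds = preds, gts = gts)
  got <- averagePrecision(list(scene), 0.5)
  # oracle: ranked (TP, FP, TP) -> precision (1, 1/2, 2/3), recall
  # (.5, .5, 1); envelope 1 on [0, .5], 2/3 on (.5, 1]
  expected <- bruteAP101(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 2)
  expect_equal(got, expected)
  expect_equal(expected, (51 * 1 + 50 * 2 / 3) / 101)
})

test_that("AP equals the brute-force oracle on random small scenes", {
  set.seed(31)
  for (trial in 1:25) {
    nGt <- sample(1:4, 1)
    gts <- lapply(seq_len(nGt), function(k)
      mk(list(c(k, 1), c(k, 2)), shape = c(6, 6)))
    nPred <- sample(0:4, 1)
    preds <- lapply(seq_len(nPred), function(k) {
      r <- sample(1:5, 1)
      mk(list(c(r, 1), c(r, sample(2:3, 1))), shape = c(6, 6),
         score = runif(1))
    })
    scene <- list(preds = preds, gts = gts)
    for (thr in c(0.5, 0.75))
      expect_equal(averagePrecision(list(scene), thr),
                   bruteScenesAP(list(scene), thr), tolerance = 1e-12)
  }
})

test_that("AP agrees with the independent evaluator on 20 seeded scenes", {
  scenes <- lapply(1:20, function(i) {
    sc <- generateScene(SceneSpec(shape = c(64, 64), nCells = 4,
                                  seed = 300 + i))
    list(preds = perturbedPredictions(sc$masks, c(64, 64), seed = 500 + i),
         gts = sc$masks)
  })
  for (thr in c(0.5, 0.75))
    expect_equal(averagePrecision(scenes, thr), bruteScenesAP(scenes, thr),
                 tolerance = 1e-6)
})

test_that("AP depends on score ranks only and degrades with FPs", {
  sc <- generateScene(SceneSpec(shape = c(64, 64), nCells = 4, seed = 321))
  preds <- perturbedPredictions(sc$masks, c(64, 64), seed = 99)
  scene <- list(preds = preds, gts = sc$masks)
  ap0 <- averagePrecision(list(scene), 0.5)

  rescaled <- lapply(preds, function(p)
    InstanceMask(maskPixels(p), maskLabel(p), maskScore(p) * 0.3))
  expect_equal(averagePrecision(list(list(preds = rescaled,
                                          gts = sc$masks)), 0.5), ap0)

  lowFp <- c(preds, list(InstanceMask({
    m <- matrix(FALSE, 64, 64); m[60:63, 60:63] <- TRUE; m
  }, "cell", score = 0.001)))
  expect_lte(averagePrecision(list(list(preds = lowFp, gts = sc$masks)),
                              0.5), ap0)

  tpIdx <- which(!is.na(matchInstances(preds, sc$masks, 0.5)$gt))[1]
  predOrd <- matchInstances(preds, sc$masks, 0.5)$pred
  dropped <- preds[-predOrd[tpIdx]]
  expect_lte(averagePrecision(list(list(preds = dropped, gts = sc$masks)),
                              0.5), ap0)
})

test_that("evaluateScenes summarises the standard thresholds", {
  sc <- generateScene(SceneSpec(shape = c(64, 64), nCells = 4, seed = 77))
  exact <- lapply(sc$masks, function(g)
    InstanceMask(maskPixels(g), maskLabel(g), score = 1))
  res <- evaluateScenes(list(list(preds = exact, gts = sc$masks)))
  expect_identical(unname(apByThreshold(res)), c(1, 1))
  expect_identical(map5095(res), 1)
})

test_that("variant reports reproduce printed percent-change cells", {
  tab <- pipelineBenchmark()
  rep <- evaluateVariants(tab, "low quality dataset")
  expect_identical(rep$map_75_pct_change[rep$variant == "SR x4, subsampling x4"],
                   25)
  expect_identical(rep$map_75_pct_change[rep$variant == "high quality dataset"],
                   63.46)
  expect_identical(rep$map_50_pct_change[rep$variant == "low quality dataset"],
                   0)
  expect_error(evaluateVariants(tab, "nonexistent"), "available variants")
})

test_that("labelled rasters convert to instance masks", {
  lab <- matrix(0L, 4, 4); lab[1, 1:2] <- 1L; lab[3, 3:4] <- 2L
  ms <- masksFromLabels(lab)
  expect_length(ms, 2L)
  expect_identical(sum(maskPixels(ms[[1]])), 2L)
  expect_true(all(vapply(ms, maskLabel, character(1)) == "cell"))
})
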