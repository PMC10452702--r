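test_that("truncated count keeps a gamma slope beyond two cells", {
  expect_equal(truncatedCount(1.5), 1.5)
  expect_equal(truncatedCount(3, gamma = 0.001), 2.003)
  expect_equal(truncatedCount(0), 0)
  ## nondecreasing in Dsum and bounded by 2 + gamma * Dsum
  g <- seq(0, 6, by = 0.01)
  f <- truncatedCount(g, 0.01)
  expect_true(all(diff(f) >= -1e-12))
  expect_true(all(f <= 2 + 0.01 * g + 1e-12))
})

test_that("max regularizer penalizes only density peaks above one", {
  expect_equal(maxRegularizer(1.3), 0.3)
  expect_equal(maxRegularizer(0.8), 0)
  expect_equal(maxRegularizer(1.0), 0)
})

test_that("counting loss combines truncation error and peak penalty", {
  mkD <- function(dsum, dmax, n = 16) {
    stopifnot(dmax <= dsum, (dsum - dmax) / (n^2 - 1) <= dmax)
    D <- matrix((dsum - dmax) / (n^2 - 1), n, n)
    D[1, 1] <- dmax
    D
  }
  ## perfect single-cell prediction
  expect_equal(countingLoss(mkD(1, 0.9), y = 1), 0)
  ## truncated multiple: (2.003 - 2)^2
  expect_equal(countingLoss(mkD(3, 0.95), y = 2, gamma = 0.001), 9e-6,
               tolerance = 1e-12)
  ## squared error and peak penalty add; as numbers (a map with Dsum 0.5
  ## but Dmax 1.2 cannot exist, so the term identity is checked directly)
  expect_equal((truncatedCount(0.5) - 0)^2 + maxRegularizer(1.2), 0.45,
               tolerance = 1e-12)
  ## feasible overshooting-peak case: y = 0, one spike of 1.2
  D <- matrix(0, 8, 8)
  D[2, 2] <- 1.2
  expect_equal(countingLoss(D, y = 0), 1.2^2 + 0.2, tolerance = 1e-12)
  ## zero exactly when f(D) = y and Dmax <= 1
  set.seed(7)
  for (i in 1:10) {
    D <- matrix(runif(64, 0, 0.05), 8, 8)
    y <- sample(0:2, 1)
    L <- countingLoss(D, y)
    isZero <- abs(truncatedCount(sum(D)) - y) < 1e-12 && max(D) <= 1
    expect_equal(L == 0, isZero)
  }
})

test_that("total loss adds the weighted counting branch", {
  expect_equal(totalLoss(0, 0), 0)
  expect_equal(totalLoss(0.7, 0.3, omega = 1), 1.0)
  expect_equal(totalLoss(0.7, 0.3, omega = 0), 0.7)
  expect_error(totalLoss(1, 1, omega = -1))
})

test_that("reclassification splits exactly at 0.5 and 1.5", {
  expect_equal(reclassifyCount(0.3), 0L)
  expect_equal(reclassifyCount(1.4), 1L)
  expect_equal(reclassifyCount(5), 2L)
  ## ties resolve toward the smaller count
  expect_equal(reclassifyCount(0.5), 0L)
  expect_equal(reclassifyCount(1.5), 1L)
  expect_equal(reclassifyCount(c(0.49, 0.51, 1.49, 1.51)), c(0L, 1L, 1L, 2L))
})

test_that("network construction is seeded and compact", {
  n1 <- buildWSCNet(seed = 42)
  n2 <- buildWSCNet(seed = 42)
  expect_identical(n1@weights, n2@weights)
  n3 <- buildWSCNet(seed = 43)
  expect_false(identical(n1@weights, n3@weights))
  ## seven convolutional layers; far below 1/8 of a 34-layer residual
  ## classifier (~21.8M parameters)
  expect_length(n1@weights$convW, 7L)
  expect_lt(nParameters(n1), 21.8e6 / 8)
})

test_that("forward pass emits a full-resolution nonnegative density map", {
  net <- buildWSCNet(seed = 2, patchSize = 32L)
  X <- array(runif(32 * 32 * 3), c(32, 32, 3))
  out <- wscnetForward(net, X)
  expect_equal(dim(out$density), c(32L, 32L, 3L))
  expect_true(all(out$density >= 0))
  expect_equal(dim(out$logits), c(2L, 3L))
  expect_equal(out$dsum, apply(out$density, 3, sum), tolerance = 1e-9)
  expect_equal(out$dmax, apply(out$density, 3, max), tolerance = 1e-12)
  ## single-matrix input works too
  out1 <- wscnetForward(net, X[, , 1])
  expect_equal(out1$dsum, out$dsum[1], tolerance = 1e-9)
})

test_that("analytic gradients agree with finite differences", {
  net <- buildWSCNet(seed = 3, patchSize = 8L,
                     channels = c(3L, 3L, 4L, 4L, 3L, 3L, 1L))
  set.seed(9)
  X <- array(runif(8 * 8 * 3), c(8, 8, 3))
  cls <- c(0L, 1L, 1L)
  y <- c(0, 1, 2)
  g <- dropletScope:::wsc_grad_cpp(net@weights, X, cls, y, 0.001, 1)
  lossAt <- function(w) dropletScope:::evalLoss(w, X, cls, y, 0.001, 1)
  eps <- 1e-6
  for (l in c(1L, 4L, 7L)) {
    for (t in 1:4) {
      i <- sample(length(net@weights$convW[[l]]), 1)
      wp <- net@weights; wp$convW[[l]][i] <- wp$convW[[l]][i] + eps
      wm <- net@weights; wm$convW[[l]][i] <- wm$convW[[l]][i] - eps
      num <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
      expect_equal(g$convW[[l]][i], num, tolerance = 1e-4)
    }
  }
  i <- sample(length(net@weights$fcW), 1)
  wp <- net@weights; wp$fcW[i] <- wp$fcW[i] + eps
  wm <- net@weights; wm$fcW[i] <- wm$fcW[i] - eps
  expect_equal(g$fcW[i], (lossAt(wp) - lossAt(wm)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("training requires all four categories and reduces the loss", {
  data <- makePatchDataset(sceneConfig(cpdLambda = 1, seed = 700L),
                           nPerCategory = 40)
  bad <- data
  drop <- bad$category == "multiple"
  bad$split[drop] <- "test"
  expect_error(trainWSCNet(buildWSCNet(seed = 1), bad,
                           trainConfig(maxEpochs = 1L)),
               "multiple")
  net <- trainWSCNet(buildWSCNet(seed = 1), data,
                     trainConfig(learningRate = 5e-3, batchSize = 64L,
                                 maxEpochs = 6L, seed = 3L))
  h <- net@history$loss
  expect_true(net@trained)
  expect_lt(h$valLoss[nrow(h)], h$valLoss[1])
})

test_that("inference contract: counts, locations and categories cohere", {
  net <- tinyTrainedModel()
  scene <- renderScene(sceneConfig(nDroplets = 25L, cpdLambda = 0.8,
                                   seed = 901L))
  props <- detectDroplets(sceneImage(scene), astmConfig())
  inf <- inferDroplets(net, props, sceneImage(scene))
  det <- inf$detections
  expect_equal(nrow(det), nrow(props))
  drp <- det$isDroplet
  ## count = floor(Dsum + 0.5); one location per counted cell
  expect_equal(det$count[drp], as.integer(floor(det$dsum[drp] + 0.5)))
  for (i in which(drp)) {
    expect_equal(nrow(inf$cellLocations[[i]]),
                 min(det$count[i], nrow(inf$cellLocations[[i]])))
    expect_equal(det$category[i],
                 dropletScope:::categoryName(reclassifyCount(det$dsum[i])))
  }
  expect_true(all(det$category[!drp] == "false_positive"))
  ## proposals outside the frame are rejected
  bad <- data.frame(cx = 1e4, cy = 10, r = 5, score = 1)
  expect_error(inferDroplets(net, bad, sceneImage(scene)))
})

test_that("density peak extraction respects separation and order", {
  D <- matrix(0, 20, 20)
  D[5, 5] <- 1
  D[5, 6] <- 0.9   # within 3 px of the first peak: must be suppressed
  D[15, 12] <- 0.8
  pk <- findDensityPeaks(D, 3, minSep = 3)
  expect_equal(nrow(pk), 2L)
  expect_equal(unname(pk[1, ]), c(5, 5))   # (x, y) of the strongest peak
  expect_equal(unname(pk[2, ]), c(12, 15))
  expect_equal(nrow(findDensityPeaks(matrix(0, 5, 5), 3)), 0L)
})

test_that("checkpoints round-trip with an architecture sidecar", {
  net <- tinyTrainedModel()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "net.rds")
  paths <- saveWSCNet(net, p)
  expect_true(all(file.exists(paths)))
  back <- loadWSCNet(p)
  expect_identical(back@weights, net@weights)
  side <- jsonlite::read_json(paths[["sidecar"]])
  expect_equal(side$patchSize, net@patchSize)
  expect_equal(unlist(side$channels), net@channels, ignore_attr = TRUE)
})
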