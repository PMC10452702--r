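test_that("circle IoU matches analytic and rasterized values", {
  expect_equal(circleIoU(5, 5, 3, 5, 5, 3), 1)
  expect_equal(circleIoU(0, 0, 3, 10, 0, 3), 0)
  expect_equal(circleIoU(0, 0, 5, 6, 8, 5), circleIoU(6, 8, 5, 0, 0, 5))
  ## concentric circles radius r and 2r: exactly 1/4
  expect_equal(circleIoU(7, 7, 4, 7, 7, 8), 0.25, tolerance = 1e-12)
  expect_error(circleIoU(0, 0, 0, 1, 1, 1))
  ## rasterization oracle on random pairs
  set.seed(11)
  for (i in 1:12) {
    c1 <- c(runif(2, 10, 30), runif(1, 3, 9))
    c2 <- c1 + c(runif(2, -8, 8), runif(1, -2, 2))
    a <- circleIoU(c1[1], c1[2], c1[3], c2[1], c2[2], c2[3])
    b <- rasterCircleIoU(c1[1], c1[2], c1[3], c2[1], c2[2], c2[3])
    expect_equal(a, b, tolerance = 0.02)
    expect_true(a >= 0 && a <= 1)
  }
  ## IoU = 1 only for identical circles
  expect_lt(circleIoU(5, 5, 3, 5, 5, 3.0001), 1)
})

test_that("circle matching is one-to-one and threshold-respecting", {
  truth <- data.frame(cx = c(10, 30, 50), cy = c(10, 10, 10), r = c(5, 6, 5))
  m <- matchCircles(truth, truth, theta = 0.5)
  expect_equal(nrow(m$pairs), 3L)
  expect_length(m$unmatchedTruth, 0L)
  expect_length(m$unmatchedPred, 0L)
  expect_true(all(m$pairs$iou >= 0.5))

  m0 <- matchCircles(truth, truth[0, ], theta = 0.5)
  expect_equal(nrow(m0$pairs), 0L)
  expect_equal(m0$unmatchedTruth, 1:3)

  ## two near-duplicate predictions on one truth circle
  pred <- data.frame(cx = c(10, 10.5), cy = c(10, 10), r = c(5, 5))
  m2 <- matchCircles(truth, pred, theta = 0.5)
  expect_equal(nrow(m2$pairs), 1L)
  expect_length(m2$unmatchedPred, 1L)
  expect_length(m2$unmatchedTruth, 2L)
})

test_that("greedy matching is permutation-invariant and near-optimal", {
  set.seed(21)
  for (rep in 1:10) {
    nt <- sample(2:5, 1)
    np <- sample(2:5, 1)
    truth <- data.frame(cx = runif(nt, 0, 40), cy = runif(nt, 0, 40),
                        r = runif(nt, 4, 9))
    pred <- data.frame(cx = truth$cx[sample(nt, np, replace = TRUE)] +
                         rnorm(np, 0, 3),
                       cy = truth$cy[sample(nt, np, replace = TRUE)] +
                         rnorm(np, 0, 3),
                       r = runif(np, 4, 9))
    m <- matchCircles(truth, pred, theta = 0.3)
    perm <- sample(np)
    mp <- matchCircles(truth, pred[perm, , drop = FALSE], theta = 0.3)
    expect_equal(nrow(mp$pairs), nrow(m$pairs))
    ## exhaustive-assignment oracle bounds the greedy matching
    opt <- optimalMatchCount(truth, pred, 0.3)
    expect_lte(nrow(m$pairs), opt)
    expect_gte(nrow(m$pairs), ceiling(opt / 2))
  }
})

test_that("precision/recall/F1 follow the standard definitions", {
  expect_equal(unname(prf1(10, 0, 0)), c(1, 1, 1))
  s <- prf1(12, 3, 8)
  expect_equal(unname(s["precision"]), 0.8)
  expect_equal(unname(s["recall"]), 0.6)
  expect_equal(unname(s["f1"]), 2 * 0.8 * 0.6 / 1.4, tolerance = 1e-12)
  expect_equal(unname(prf1(0, 5, 5)["f1"]), 0)
  ## F1 bound through the weaker of the two rates
  set.seed(2)
  for (i in 1:20) {
    v <- prf1(sample(0:20, 1), sample(0:20, 1), sample(0:20, 1))
    mn <- min(v["precision"], v["recall"])
    expect_lte(v["f1"], 2 * mn / (1 + mn) + 1e-12)
  }
})

test_that("localization scoring uses valid areas with 1:1 matching", {
  truth <- rbind(c(10, 10), c(30, 30))
  expect_equal(localizationScore(truth, rbind(c(10, 10)), 1)$tp, 1L)
  ## outside the valid area
  s <- localizationScore(rbind(c(10, 10)), rbind(c(10, 21)), 10)
  expect_equal(s$tp, 0L)
  expect_equal(s$fp, 1L)
  ## two predictions near one centroid: one TP, one FP
  s2 <- localizationScore(rbind(c(10, 10)), rbind(c(11, 10), c(9, 10)), 5)
  expect_equal(s2$tp, 1L)
  expect_equal(s2$fp, 1L)
  expect_equal(s2$precision, 0.5)
  ## nearest-first greedy: each prediction binds its closest centroid
  s3 <- localizationScore(truth, rbind(c(29, 30), c(11, 10)), 4)
  expect_equal(s3$tp, 2L)
  expect_equal(s3$recall, 1)
})

test_that("counting MRE averages relative errors over positive droplets", {
  expect_equal(as.numeric(countingMRE(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(countingMRE(2, 3)), 0.5)
  mre <- countingMRE(c(1, 2, 4, 0), c(2, 1, 3, 1))
  expect_equal(as.numeric(mre), mean(c(1 / 1, 1 / 2, 1 / 4)))
  expect_equal(attr(mre, "nExcluded"), 1L)
  expect_error(countingMRE(c(0, 0), c(1, 2)))
})

test_that("Poisson fit diagnostics: RSS against the theoretical curves", {
  lam <- c(0.1, 0.3, 0.6, 1)
  exact <- encapsulationRates(lam)$single
  expect_equal(poissonFitRSS(lam, exact, "single")$rss, 0)
  off <- exact
  off[2] <- off[2] + 0.1
  expect_equal(poissonFitRSS(lam, off, "single")$rss, 0.01, tolerance = 1e-12)
  ## chi-squared path: a true Poisson sample should not be rejected
  set.seed(9)
  counts <- rpois(5000, 0.4)
  gof <- poissonFitRSS(0.4, mean(counts == 1), "single",
                       counts = counts, countsLambda = 0.4)
  expect_gt(gof$chisq$p.value, 0.01)
  expect_true(gof$chisq$df >= 1)
})

test_that("recognition F1 decreases as the IoU threshold rises", {
  s <- renderScene(sceneConfig(nDroplets = 80L, seed = 61L))
  props <- detectDroplets(sceneImage(s), astmConfig())
  truth <- sceneCircles(s)
  thetas <- seq(0.5, 0.85, by = 0.05)
  f1 <- vapply(thetas, function(th) {
    m <- matchCircles(truth, props, th)
    tp <- nrow(m$pairs)
    unname(prf1(tp, nrow(props) - tp, nrow(truth) - tp)["f1"])
  }, 0)
  expect_true(all(diff(f1) <= 1e-9))
  expect_gt(f1[1], f1[length(f1)])
})

test_that("category-aware F1 books mismatches on both categories", {
  truth <- data.frame(cx = c(10, 30, 50, 70), cy = 10, r = 5,
                      category = c("empty", "single", "multiple", "single"))
  pred <- data.frame(cx = c(10, 30, 50), cy = 10, r = 5,
                     category = c("empty", "multiple", "multiple"))
  r <- categoryF1(truth, pred, theta = 0.5)
  per <- r$perCategory
  expect_equal(per$tp[per$category == "empty"], 1L)
  ## single predicted as multiple: fn for single, fp for multiple
  expect_equal(per$fn[per$category == "single"], 2L)  # one mismatch + one miss
  expect_equal(per$fp[per$category == "multiple"], 1L)
  expect_equal(per$tp[per$category == "multiple"], 1L)
  expect_true(all(is.finite(per$f1)))
  expect_equal(per$f1[per$category == "empty"], 1)
  ## multiple: tp 1, fp 1 (the mislabeled single), fn 0 -> P 0.5, R 1
  expect_equal(per$f1[per$category == "multiple"], 2 * 0.5 * 1 / 1.5)
  expect_equal(r$meanF1, mean(per$f1))
})
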