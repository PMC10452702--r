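test_that("identical config and seed give bit-identical scenes", {
  cfg <- sceneConfig(nDroplets = 40L, seed = 7L)
  s1 <- renderScene(cfg)
  s2 <- renderScene(cfg)
  expect_identical(sceneImage(s1), sceneImage(s2))
  expect_identical(sceneCircles(s1), sceneCircles(s2))
  expect_identical(sceneCells(s1), sceneCells(s2))
  s3 <- renderScene(sceneConfig(nDroplets = 40L, seed = 8L))
  expect_false(identical(sceneImage(s1), sceneImage(s3)))
})

test_that("empty scene is uniform background with empty truth", {
  cfg <- sceneConfig(nDroplets = 0L, noiseSD = 0, seed = 1L)
  s <- renderScene(cfg)
  expect_equal(nrow(sceneCircles(s)), 0L)
  expect_length(sceneCategories(s), 0L)
  expect_true(all(sceneImage(s) == cfg@backgroundLevel))
})

test_that("lambda 0 forces every droplet to be empty", {
  s <- renderScene(sceneConfig(nDroplets = 50L, cpdLambda = 0, seed = 2L))
  expect_equal(nrow(sceneCircles(s)), 50L)
  expect_true(all(sceneCategories(s) == "empty"))
  expect_true(all(vapply(sceneCells(s), nrow, 0L) == 0L))
})

test_that("scene geometry is consistent: circles in frame, cells in circles", {
  for (seed in c(3L, 13L, 23L)) {
    cfg <- sceneConfig(seed = seed, cpdLambda = 0.8)
    s <- renderScene(cfg)
    circ <- sceneCircles(s)
    expect_true(all(circ$cx - circ$r >= 0.5 &
                    circ$cx + circ$r <= cfg@frameWidth + 0.5))
    expect_true(all(circ$cy - circ$r >= 0.5 &
                    circ$cy + circ$r <= cfg@frameHeight + 0.5))
    for (i in seq_len(nrow(circ))) {
      pts <- sceneCells(s)[[i]]
      if (nrow(pts) == 0) next
      d <- sqrt((pts[, 1] - circ$cx[i])^2 + (pts[, 2] - circ$cy[i])^2)
      expect_true(all(d < circ$r[i]))
    }
    ncell <- vapply(sceneCells(s), nrow, 0L)
    expect_identical(sceneCategories(s),
                     ifelse(ncell == 0, "empty",
                            ifelse(ncell == 1, "single", "multiple")))
    ## center separation respects the adhesion limit
    if (nrow(circ) > 1) {
      dm <- as.matrix(dist(circ[, c("cx", "cy")]))
      rs <- outer(circ$r, circ$r, `+`) * (1 - cfg@maxOverlap)
      diag(dm) <- Inf
      expect_true(all(dm >= rs - 1e-9))
    }
  }
})

test_that("per-droplet cell counts follow the Poisson law", {
  ## ~10,500 droplets across seeded scenes; chi-squared GOF at alpha = 0.01
  counts <- unlist(lapply(1:70, function(i) {
    s <- renderScene(sceneConfig(seed = 4000L + i, cpdLambda = 0.26,
                                 noiseSD = 0))
    vapply(sceneCells(s), nrow, 0L)
  }))
  expect_gte(length(counts), 1e4)
  gof <- poissonFitRSS(0.26, mean(counts == 1), curve = "single",
                       counts = counts, countsLambda = 0.26)
  expect_gt(gof$chisq$p.value, 0.01)

  ## occupied fraction at lambda 0.5 within 3 binomial s.e. of 1 - e^-0.5
  counts5 <- unlist(lapply(1:70, function(i) {
    s <- renderScene(sceneConfig(seed = 6000L + i, cpdLambda = 0.5,
                                 noiseSD = 0))
    vapply(sceneCells(s), nrow, 0L)
  }))
  p <- 1 - exp(-0.5)
  se <- sqrt(p * (1 - p) / length(counts5))
  expect_lt(abs(mean(counts5 >= 1) - p), 3 * se)
})

test_that("patch dataset meets quotas, is seeded, and splits 4:1:1", {
  cfg <- sceneConfig(cpdLambda = 1, seed = 50L)
  d1 <- makePatchDataset(cfg, nPerCategory = 30)
  expect_equal(dim(d1$patches)[3], 120L)
  expect_equal(unname(table(d1$category)[c("background", "empty", "single",
                                           "multiple")]),
               rep(30L, 4), ignore_attr = TRUE)
  d2 <- makePatchDataset(cfg, nPerCategory = 30)
  expect_identical(d1$patches, d2$patches)
  expect_identical(d1$split, d2$split)
  for (ct in unique(d1$category)) {
    sp <- table(factor(d1$split[d1$category == ct],
                       levels = c("train", "validate", "test")))
    expect_equal(unname(sp["train"]), 20L, ignore_attr = TRUE)
    expect_equal(unname(sp["validate"]), 5L, ignore_attr = TRUE)
  }
  expect_true(all(range(d1$patches) >= 0 & range(d1$patches) <= 1))
})

test_that("background patches intersect no truth circle", {
  cfg <- sceneConfig(cpdLambda = 1, seed = 77L)
  d <- makePatchDataset(cfg, nPerCategory = 25)
  bg <- which(d$category == "background")
  hw <- max(4L, as.integer(round(d$cropFactor * cfg@dropletDiameterMean / 4)))
  for (i in bg) {
    sc <- renderScene({
      c2 <- cfg
      c2@seed <- as.integer(d$meta$sceneSeed[i])
      c2
    })
    circ <- sceneCircles(sc)
    ## brute-force: no circle point may fall inside the crop square
    dx <- pmax(0, abs(circ$cx - d$meta$cx[i]) - hw)
    dy <- pmax(0, abs(circ$cy - d$meta$cy[i]) - hw)
    expect_true(all(dx^2 + dy^2 > circ$r^2))
  }
})

test_that("patch/frame coordinate mapping round-trips", {
  img <- matrix(200, 100, 120)
  p <- extractPatch(img, cx = 60.3, cy = 41.7, r = 11, size = 32L)
  pts <- cbind(c(5.5, 16, 30), c(8, 16.5, 2))
  back <- dropletScope:::frameToPatch(patchToFrame(pts, p),
                                      attr(p, "src0"), attr(p, "srcSide"),
                                      32L)
  expect_equal(unname(back), unname(pts), tolerance = 1e-10)
})

test_that("scene writer emits PNG, JSON and 0-based CSV that reload", {
  s <- renderScene(sceneConfig(nDroplets = 12L, seed = 5L))
  dir <- withr::local_tempdir()
  paths <- writeScene(s, dir, id = "f1")
  expect_true(all(file.exists(paths)))
  png <- png::readPNG(paths["png"])
  expect_equal(round(png * 255), unname(sceneImage(s)), ignore_attr = TRUE)
  csv <- read.csv(paths["csv"])
  expect_equal(csv$cx, sceneCircles(s)$cx - 1)
  expect_equal(csv$n_cells, vapply(sceneCells(s), nrow, 0L))
})
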