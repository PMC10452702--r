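## Synthetic brightfield droplet micrographs with full ground truth.
##
## Scenes emulate the statistical and geometric structure that the two-stage
## recognizer sees in real data: a bright oil background, densely packed and
## often adherent circular droplets with a dark 2-px rim and a slightly
## darker interior, and cells drawn per droplet from a Poisson law and
## rendered as small dark Gaussian blobs. Rendering is fully seeded so a
## (config, seed) pair is a reproducible benchmark.

#' Render a synthetic droplet scene
#'
#' Draws droplet diameters from a truncated normal, places droplet centers
#' by rejection sampling so neighboring circles may touch or encroach up to
#' \code{maxOverlap} of their summed radii (emulating adherent monolayers),
#' loads each droplet with \code{Poisson(cpdLambda)} cells placed uniformly
#' in the inner 80\% of its disk (minimum 3 px apart), renders rims, interiors
#' and cells, and adds Gaussian noise. Intensities are rounded to the 8-bit
#' grid so the in-memory frame equals its PNG serialization.
#'
#' If fewer than \code{nDroplets} centers can be placed within the retry
#' budget, the scene is returned with the achieved number and a warning; the
#' truth always matches what was rendered.
#'
#' @param config a [SceneConfig-class].
#' @return A [DropletScene-class] holding the frame and its ground truth.
#' @examples
#' scene <- renderScene(sceneConfig(nDroplets = 30, seed = 3))
#' scene
#' @export
renderScene <- function(config) {
  validObject(config)
  set.seed(config@seed)
  W <- config@frameWidth
  H <- config@frameHeight
  n <- config@nDroplets

  ## droplet diameters: Normal(mean, cv * mean) truncated positive (and not
  ## below a renderable 5 px)
  diam <- numeric(n)
  if (n > 0) {
    sdd <- config@dropletDiameterCV * config@dropletDiameterMean
    for (i in seq_len(n)) {
      d <- rnorm(1, config@dropletDiameterMean, sdd)
      tries <- 0L
      while (d < 5 && tries < 100L) {
        d <- rnorm(1, config@dropletDiameterMean, sdd)
        tries <- tries + 1L
      }
      diam[i] <- max(d, 5)
    }
  }
  rad <- diam / 2

  ## center placement by rejection sampling
  cx <- numeric(0); cy <- numeric(0); rr <- numeric(0)
  if (n > 0) {
    maxTries <- 300L * n
    tries <- 0L
    for (i in seq_len(n)) {
      placed <- FALSE
      while (!placed && tries < maxTries) {
        tries <- tries + 1L
        x <- runif(1, rad[i] + 1.5, W - rad[i] - 0.5)
        y <- runif(1, rad[i] + 1.5, H - rad[i] - 0.5)
        if (length(cx) == 0L ||
            all(sqrt((cx - x)^2 + (cy - y)^2) >=
                (rr + rad[i]) * (1 - config@maxOverlap))) {
          cx <- c(cx, x); cy <- c(cy, y); rr <- c(rr, rad[i])
          placed <- TRUE
        }
      }
      if (!placed) break
    }
    if (length(cx) < n)
      warning(sprintf("placed %d of %d droplets before retry budget ran out",
                      length(cx), n))
  }
  nPlaced <- length(cx)

  ## Poisson cell loading and in-disk placement (min 3 px separation)
  nCells <- if (nPlaced > 0) rpois(nPlaced, config@cpdLambda) else integer(0)
  cells <- vector("list", nPlaced)
  cellDiam <- vector("list", nPlaced)
  for (i in seq_len(nPlaced)) {
    k <- nCells[i]
    pts <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("cx", "cy")))
    dd <- numeric(0)
    if (k > 0) {
      for (j in seq_len(k)) {
        ok <- FALSE
        for (t in seq_len(200L)) {
          a <- runif(1, 0, 2 * pi)
          u <- 0.8 * rr[i] * sqrt(runif(1))
          px <- cx[i] + u * cos(a); py <- cy[i] + u * sin(a)
          if (nrow(pts) == 0L ||
              all(sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2) >= 3)) {
            pts <- rbind(pts, c(px, py))
            dd <- c(dd, runif(1, config@cellDiameterRange[1],
                              config@cellDiameterRange[2]))
            ok <- TRUE
            break
          }
        }
        if (!ok) break  # crowded droplet: drop the unplaceable cell
      }
    }
    cells[[i]] <- pts
    cellDiam[[i]] <- dd
  }

  img <- renderFrame(W, H, cx, cy, rr, cells, cellDiam, config)

  ncell <- vapply(cells, nrow, 0L)
  categories <- if (nPlaced > 0)
    ifelse(ncell == 0L, "empty", ifelse(ncell == 1L, "single", "multiple"))
  else character(0)

  new("DropletScene",
      image = img,
      circles = data.frame(cx = cx, cy = cy, r = rr),
      cells = cells,
      categories = as.character(categories),
      config = config)
}

## Rasterize droplets and cells into an (H, W) intensity matrix.
renderFrame <- function(W, H, cx, cy, rr, cells, cellDiam, config) {
  img <- matrix(config@backgroundLevel, H, W)
  interiorLevel <- config@backgroundLevel - config@interiorContrast
  rimLevel <- config@backgroundLevel - config@rimContrast

  for (i in seq_along(cx)) {
    r <- rr[i]
    rows <- max(1L, floor(cy[i] - r - 1)):min(H, ceiling(cy[i] + r + 1))
    cols <- max(1L, floor(cx[i] - r - 1)):min(W, ceiling(cx[i] + r + 1))
    d2 <- outer((rows - cy[i])^2, (cols - cx[i])^2, `+`)
    sub <- img[rows, cols, drop = FALSE]
    sub[d2 <= (r - 2)^2] <- pmin(sub[d2 <= (r - 2)^2], interiorLevel)
    rim <- d2 > (r - 2)^2 & d2 <= r^2
    sub[rim] <- pmin(sub[rim], rimLevel)
    img[rows, cols] <- sub
  }

  for (i in seq_along(cells)) {
    pts <- cells[[i]]
    for (j in seq_len(nrow(pts))) {
      s <- cellDiam[[i]][j] / 4  # Gaussian sigma: blob FWHM ~ cell diameter
      hw <- ceiling(3 * s)
      rows <- max(1L, floor(pts[j, 2] - hw)):min(H, ceiling(pts[j, 2] + hw))
      cols <- max(1L, floor(pts[j, 1] - hw)):min(W, ceiling(pts[j, 1] + hw))
      d2 <- outer((rows - pts[j, 2])^2, (cols - pts[j, 1])^2, `+`)
      img[rows, cols] <- img[rows, cols] -
        config@cellContrast * exp(-d2 / (2 * s^2))
    }
  }

  if (config@noiseSD > 0)
    img <- img + rnorm(length(img), 0, config@noiseSD)
  round(pmin(pmax(img, 0), 255))
}

#' Extract a fixed-size droplet patch
#'
#' Crops a square window of side \code{cropFactor * r} centered on a circle
#' and resizes it (bilinear) to \code{size} x \code{size}, normalized to
#' [0, 1] with inverted polarity: patch intensity is
#' \code{(255 - pixel) / 255}, so the bright oil background is near 0 and
#' absorbing objects (droplet rims, cells) carry positive signal.
#' Out-of-frame pixels are padded with the median frame intensity.
#' The attached attributes record the crop so patch coordinates can be
#' mapped back to frame coordinates with [patchToFrame()].
#'
#' @param image frame matrix (intensities 0-255).
#' @param cx,cy,r circle center and radius (px, 1-based centers).
#' @param size output patch side (px).
#' @param cropFactor window side as a multiple of the circle radius.
#' @return \code{size} x \code{size} matrix in [0, 1] with attributes
#'   \code{src0} (row, col of the window origin) and \code{srcSide}.
#' @export
extractPatch <- function(image, cx, cy, r, size = 32L, cropFactor = 2.4) {
  H <- nrow(image); W <- ncol(image)
  if (cx < 1 || cx > W || cy < 1 || cy > H)
    stop("proposal center lies outside the frame")
  hw <- max(4L, as.integer(round(cropFactor * r / 2)))
  ri <- as.integer(round(cy)); ci <- as.integer(round(cx))
  rows <- (ri - hw):(ri + hw)
  cols <- (ci - hw):(ci + hw)
  pad <- median(image)
  win <- matrix(pad, length(rows), length(cols))
  rIn <- rows >= 1L & rows <= H
  cIn <- cols >= 1L & cols <= W
  win[rIn, cIn] <- image[rows[rIn], cols[cIn]]
  out <- EBImage::resize(EBImage::Image(1 - win / 255), w = size, h = size)
  patch <- matrix(EBImage::imageData(out), size, size)
  attr(patch, "src0") <- c(row = rows[1], col = cols[1])
  attr(patch, "srcSide") <- length(rows)
  patch
}

#' Map patch coordinates back to frame coordinates
#'
#' @param coords two-column matrix of (x, y) patch pixel coordinates.
#' @param patch a patch from [extractPatch()] (its crop attributes are used).
#' @return Two-column matrix of frame (x, y) coordinates.
#' @export
patchToFrame <- function(coords, patch) {
  src0 <- attr(patch, "src0")
  side <- attr(patch, "srcSide")
  size <- nrow(patch)
  sc <- side / size
  cbind(cx = src0[["col"]] - 0.5 + (coords[, 1] - 0.5) * sc,
        cy = src0[["row"]] - 0.5 + (coords[, 2] - 0.5) * sc)
}

## Inverse of patchToFrame for truth centroids.
frameToPatch <- function(coords, src0, side, size) {
  sc <- size / side
  cbind(x = (coords[, 1] - src0[["col"]] + 0.5) * sc + 0.5,
        y = (coords[, 2] - src0[["row"]] + 0.5) * sc + 0.5)
}

#' Build a labeled patch dataset from synthetic scenes
#'
#' Generates seeded scenes until the requested per-category quota is met and
#' extracts four kinds of fixed-size patches: droplet patches centered on
#' truth circles for the \code{empty}, \code{single} and \code{multiple}
#' categories, and \code{background} patches sampled off-droplet (their crop
#' windows intersect no truth circle). Patches are split 4:1:1 into
#' train/validate/test within each category.
#'
#' @param config a [SceneConfig-class]; its seed starts the scene stream.
#' @param nPerCategory patches required per category.
#' @param size patch side in px.
#' @param cropFactor crop window side as a multiple of the circle radius.
#' @param maxScenes safety cap on the number of scenes generated.
#' @return A list with elements \code{patches} (array size x size x N),
#'   \code{category}, \code{isDroplet}, \code{countLabel} (0/1/2, NA for
#'   background), \code{split}, \code{cells} (per-patch truth centroids in
#'   patch coordinates), and \code{meta} (per-patch provenance).
#' @export
makePatchDataset <- function(config, nPerCategory, size = 32L,
                             cropFactor = 2.4, maxScenes = 2000L) {
  stopifnot(nPerCategory > 0)
  want <- c(background = nPerCategory, empty = nPerCategory,
            single = nPerCategory, multiple = nPerCategory)
  got <- c(background = 0L, empty = 0L, single = 0L, multiple = 0L)
  patches <- vector("list", sum(want))
  category <- character(sum(want))
  countLabel <- integer(sum(want))
  cellList <- vector("list", sum(want))
  meta <- vector("list", sum(want))
  nPat <- 0L

  meanR <- config@dropletDiameterMean / 2
  sceneIdx <- 0L
  while (any(got < want) && sceneIdx < maxScenes) {
    sceneIdx <- sceneIdx + 1L
    cfg <- config
    cfg@seed <- config@seed + sceneIdx - 1L
    scene <- suppressWarnings(renderScene(cfg))
    img <- scene@image
    circ <- scene@circles

    ## droplet patches
    for (i in seq_len(nrow(circ))) {
      cat_i <- scene@categories[i]
      if (got[cat_i] >= want[cat_i]) next
      p <- extractPatch(img, circ$cx[i], circ$cy[i], circ$r[i],
                        size = size, cropFactor = cropFactor)
      nPat <- nPat + 1L
      got[cat_i] <- got[cat_i] + 1L
      patches[[nPat]] <- p
      category[nPat] <- cat_i
      countLabel[nPat] <- min(nrow(scene@cells[[i]]), 2L)
      cellList[[nPat]] <- if (nrow(scene@cells[[i]]) > 0)
        frameToPatch(scene@cells[[i]], attr(p, "src0"),
                     attr(p, "srcSide"), size)
      else matrix(numeric(0), 0, 2)
      meta[[nPat]] <- data.frame(sceneSeed = cfg@seed, droplet = i,
                                 cx = circ$cx[i], cy = circ$cy[i],
                                 r = circ$r[i])
    }

    ## background patches: windows that intersect no truth circle
    nBgWanted <- min(want["background"] - got["background"],
                     max(10L, nrow(circ) %/% 3L))
    hw <- max(4L, as.integer(round(cropFactor * meanR / 2)))
    tries <- 0L
    while (nBgWanted > 0L && tries < 500L) {
      tries <- tries + 1L
      x <- runif(1, hw + 1, config@frameWidth - hw)
      y <- runif(1, hw + 1, config@frameHeight - hw)
      ## circle-square intersection test against every truth circle
      ddx <- pmax(0, abs(circ$cx - x) - hw)
      ddy <- pmax(0, abs(circ$cy - y) - hw)
      if (nrow(circ) == 0L || all(ddx^2 + ddy^2 > circ$r^2)) {
        p <- extractPatch(img, x, y, meanR, size = size,
                          cropFactor = cropFactor)
        nPat <- nPat + 1L
        got["background"] <- got["background"] + 1L
        patches[[nPat]] <- p
        category[nPat] <- "background"
        countLabel[nPat] <- NA_integer_
        cellList[[nPat]] <- matrix(numeric(0), 0, 2)
        meta[[nPat]] <- data.frame(sceneSeed = cfg@seed, droplet = NA_integer_,
                                   cx = x, cy = y, r = meanR)
        nBgWanted <- nBgWanted - 1L
      }
    }
  }
  if (any(got < want))
    stop("patch quota not met after maxScenes scenes; increase maxScenes ",
         "or raise cpdLambda for more occupied droplets")

  X <- array(0, c(size, size, nPat))
  for (i in seq_len(nPat)) X[, , i] <- patches[[i]]
  category <- category[seq_len(nPat)]
  countLabel <- countLabel[seq_len(nPat)]
  cellList <- cellList[seq_len(nPat)]
  metaDf <- do.call(rbind, meta[seq_len(nPat)])

  ## 4:1:1 split, stratified by category, deterministic under the config seed
  split <- character(nPat)
  set.seed(config@seed + 10000L)
  for (cat_i in names(want)) {
    idx <- sample(which(category == cat_i))
    nTr <- floor(length(idx) * 4 / 6)
    nVa <- floor(length(idx) / 6)
    split[idx[seq_len(nTr)]] <- "train"
    split[idx[nTr + seq_len(nVa)]] <- "validate"
    split[idx[(nTr + nVa + 1):length(idx)]] <- "test"
  }

  list(patches = X, category = category,
       isDroplet = category != "background",
       countLabel = countLabel, split = split,
       cells = cellList, meta = metaDf,
       size = size, cropFactor = cropFactor)
}

#' Write a scene and its ground truth to disk
#'
#' Writes an 8-bit grayscale PNG, a JSON truth file (circles, centroids,
#' labels) and a flat CSV (one row per droplet). File coordinates are
#' 0-based pixel indices, x along columns and y along rows.
#'
#' @param scene a [DropletScene-class].
#' @param dir output directory (created if missing).
#' @param id frame identifier used in file names.
#' @return Invisibly, the paths written.
#' @export
writeScene <- function(scene, dir, id = "frame0000") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pngPath <- file.path(dir, paste0(id, ".png"))
  png::writePNG(scene@image / 255, pngPath)

  truth <- list(
    frame = id,
    coordinate_convention = "0-based pixel centers, x = column, y = row",
    circles = data.frame(cx = scene@circles$cx - 1,
                         cy = scene@circles$cy - 1,
                         r = scene@circles$r),
    cells = lapply(scene@cells, function(m)
      if (nrow(m)) data.frame(cx = m[, 1] - 1, cy = m[, 2] - 1)
      else data.frame(cx = numeric(0), cy = numeric(0))),
    category = scene@categories)
  jsonPath <- file.path(dir, paste0(id, "_truth.json"))
  jsonlite::write_json(truth, jsonPath, auto_unbox = TRUE, digits = NA)

  csvPath <- file.path(dir, paste0(id, "_truth.csv"))
  df <- data.frame(frame_id = id,
                   cx = scene@circles$cx - 1, cy = scene@circles$cy - 1,
                   r = scene@circles$r,
                   n_cells = vapply(scene@cells, nrow, 0L),
                   category = scene@categories)
  write.csv(df, csvPath, row.names = FALSE)
  invisible(c(png = pngPath, json = jsonPath, csv = csvPath))
}
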