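## Orchestration and I/O: reading micrographs, the end-to-end recognize
## pipeline (frame -> proposals -> counting network -> per-droplet table ->
## encapsulation summary), colored overlays and result writers.
##
## File coordinate convention: all CSV/JSON outputs are 0-based pixel
## indices (x along columns, y along rows); in-memory objects are 1-based.

#' Read grayscale frames from a file or directory
#'
#' Accepts PNG and TIFF. Color images are converted to grayscale by
#' luminance (Rec. 709 weights); intensities are rescaled to [0, 255]
#' regardless of bit depth. Directories are read in lexicographic name
#' order; unreadable files are skipped with a warning.
#'
#' @param path image file or directory.
#' @return Named list of intensity matrices (rows = image height).
#' @export
readImages <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no images found in ", path)
  } else if (file.exists(path)) {
    files <- path
  } else stop("path does not exist: ", path)

  out <- list()
  for (f in files) {
    img <- tryCatch(EBImage::readImage(f), error = function(e) {
      warning("skipping unreadable image ", f, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(img)) next
    d <- EBImage::imageData(img)
    if (length(dim(d)) == 3L) {
      nc <- dim(d)[3]
      d <- if (nc >= 3)
        0.2126 * d[, , 1] + 0.7152 * d[, , 2] + 0.0722 * d[, , 3]
      else d[, , 1]
    }
    ## EBImage stores (x, y): transpose to (row = y, col = x)
    m <- t(d) * 255
    out[[basename(f)]] <- m
  }
  if (!length(out)) stop("all images failed to read under ", path)
  out
}

#' Draw a colored detection overlay
#'
#' Circles are colored by category following the standard scheme: empty
#' red, single-cell blue, multicell green, false-positive proposals yellow;
#' predicted cell locations are marked as red points.
#'
#' @param image grayscale frame matrix (0-255).
#' @param detections detection data.frame from [inferDroplets()] (or any
#'   data.frame with \code{cx}, \code{cy}, \code{r} and optionally
#'   \code{category}).
#' @param cellLocations optional list of per-detection cell coordinate
#'   matrices.
#' @param path optional PNG output path.
#' @return Invisibly, the RGB array (H x W x 3, values in [0, 1]).
#' @export
drawOverlay <- function(image, detections, cellLocations = NULL,
                        path = NULL) {
  H <- nrow(image); W <- ncol(image)
  rgb <- array(rep(image / 255, 3), c(H, W, 3))
  cols <- list(empty = c(1, 0, 0), single = c(0, 0.3, 1),
               multiple = c(0, 0.8, 0), false_positive = c(1, 0.9, 0))
  setPx <- function(rgb, rows, cols_, colr) {
    ok <- rows >= 1 & rows <= H & cols_ >= 1 & cols_ <= W
    for (ch in 1:3) rgb[cbind(rows[ok], cols_[ok], ch)] <- colr[ch]
    rgb
  }
  for (i in seq_len(nrow(detections))) {
    cat_i <- if ("category" %in% names(detections))
      detections$category[i] else "single"
    colr <- cols[[cat_i]]
    if (is.null(colr)) colr <- c(1, 0, 1)
    th <- seq(0, 2 * pi, length.out = max(16, round(2 * pi * detections$r[i])))
    rows <- round(detections$cy[i] + detections$r[i] * sin(th))
    cols_ <- round(detections$cx[i] + detections$r[i] * cos(th))
    rgb <- setPx(rgb, rows, cols_, colr)
  }
  if (!is.null(cellLocations)) {
    for (pts in cellLocations) {
      for (j in seq_len(nrow(pts))) {
        rows <- round(pts[j, 2]) + rep(-1:1, each = 3)
        cols_ <- round(pts[j, 1]) + rep(-1:1, times = 3)
        rgb <- setPx(rgb, rows, cols_, c(1, 0, 0))
      }
    }
  }
  if (!is.null(path)) png::writePNG(rgb, path)
  invisible(rgb)
}

#' End-to-end recognition of cell-encapsulated droplets
#'
#' For every frame: Otsu binarization and adaptive-scale template matching
#' produce droplet proposals; the counting network filters false positives,
#' counts encapsulated cells and localizes them; per-droplet rows are
#' accumulated and the batch is summarized into encapsulation statistics
#' (category rates, single-cell rate, estimated cells per droplet).
#'
#' @param images named list of frame matrices (see [readImages()]) or a
#'   single matrix.
#' @param model a trained [WSCNet-class].
#' @param astmCfg an [AstmConfig-class].
#' @param outDir optional output directory; when given, writes
#'   \code{droplets.csv} (per-droplet table, 0-based coordinates),
#'   \code{summary.json}, \code{manifest.json} and per-frame overlay PNGs.
#' @param cropFactor patch crop factor (must match training).
#' @param overlay write overlay PNGs (only with \code{outDir}).
#' @return List with \code{droplets} (data.frame over all frames),
#'   \code{summary} (an [EncapsulationSummary-class]), and
#'   \code{cellLocations}.
#' @export
recognize <- function(images, model, astmCfg = astmConfig(), outDir = NULL,
                      cropFactor = 2.4, overlay = !is.null(outDir)) {
  if (is.matrix(images)) images <- list(frame = images)
  if (is.null(names(images)))
    names(images) <- sprintf("frame%04d", seq_along(images))
  rows <- list()
  allLocs <- list()
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  for (nm in names(images)) {
    frame <- images[[nm]]
    props <- detectDroplets(frame, astmCfg)
    inf <- inferDroplets(model, props, frame, cropFactor = cropFactor)
    det <- inf$detections
    if (nrow(det)) det <- cbind(data.frame(frame_id = nm), det)
    rows[[nm]] <- det
    allLocs[[nm]] <- inf$cellLocations
    if (!is.null(outDir) && overlay)
      drawOverlay(frame, inf$detections, inf$cellLocations,
                  file.path(outDir, paste0(sub("\\.[^.]+$", "", nm),
                                           "_overlay.png")))
  }
  droplets <- do.call(rbind, rows[vapply(rows, nrow, 0L) > 0])
  if (is.null(droplets))
    droplets <- data.frame(frame_id = character(0), cx = numeric(0),
                           cy = numeric(0), r = numeric(0),
                           score = numeric(0), isDroplet = logical(0),
                           probDroplet = numeric(0), dsum = numeric(0),
                           count = integer(0), category = character(0))
  rownames(droplets) <- NULL
  counts <- droplets$count[droplets$isDroplet]
  summary <- summarizeEncapsulation(counts)

  if (!is.null(outDir)) {
    writeDetections(droplets, file.path(outDir, "droplets.csv"))
    writeSummary(summary, file.path(outDir, "summary.json"))
    manifest <- list(
      package = "dropletScope",
      version = as.character(utils::packageVersion("dropletScope")),
      frames = names(images),
      astm = list(sigma = astmCfg@sigma, rInit = astmCfg@rInit,
                  rMin = astmCfg@rMin, minShrink = astmCfg@minShrink,
                  nmsIou = astmCfg@nmsIou),
      model = list(patchSize = model@patchSize,
                   channels = model@channels, seed = model@seed),
      cropFactor = cropFactor,
      coordinate_convention = "0-based in files, x = column, y = row")
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(droplets = droplets, summary = summary, cellLocations = allLocs)
}

#' Write a per-droplet detection table
#'
#' Coordinates are converted to the 0-based file convention; a leading
#' comment line states it.
#'
#' @param droplets detection data.frame (1-based, in-memory convention).
#' @param path CSV output path.
#' @export
writeDetections <- function(droplets, path) {
  out <- droplets
  for (cc in intersect(c("cx", "cy"), names(out))) out[[cc]] <- out[[cc]] - 1
  con <- file(path, "w")
  writeLines("# coordinates are 0-based pixel indices; x = column, y = row",
             con)
  write.csv(out, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write an encapsulation summary as JSON
#'
#' @param summary an [EncapsulationSummary-class].
#' @param path JSON output path.
#' @export
writeSummary <- function(summary, path) {
  jsonlite::write_json(list(
    n_droplets = summary@nDroplets,
    m_positive = summary@nPositive,
    counts_by_k = as.list(summary@countsByK),
    rates = as.list(summary@rates),
    single_cell_rate = summary@singleCellRate,
    lambda_hat = summary@lambdaHat),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Theoretical rate curves for a lambda grid
#'
#' Convenience table for plotting observed encapsulation rates against the
#' Poisson curves.
#'
#' @param lambdaGrid vector of CPD values.
#' @param path optional CSV output path.
#' @return The rates data.frame (invisibly when written to file).
#' @export
ratesTable <- function(lambdaGrid = seq(0, 3, by = 0.05), path = NULL) {
  tab <- encapsulationRates(lambdaGrid)
  if (!is.null(path)) {
    write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
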