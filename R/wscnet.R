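## Stage 2: the weakly supervised counting network.
##
## Seven 3x3 convolutional layers in total: a shared trunk (4 layers) feeds
## both a counting head (3 layers ending in a single-channel, ReLU-clamped
## density map at input resolution) and a classification head (global
## average pooling + a linear 2-class readout, which is not a convolution).
## Training uses only droplet-level labels: background vs droplet for the
## classifier, and a weak count y in {0, 1, 2} ("2" meaning at least two)
## for the counting branch. The counting loss truncates the density-map
## integral at 2 with a small residual slope gamma and penalizes density
## values above 1 so a single cell cannot be represented by one spike of
## mass > 1; at inference the integral counts cells and the leading maxima
## localize them.

#' Build an untrained counting network
#'
#' @param seed integer seed for He-initialized weights (two builds with the
#'   same seed are identical).
#' @param patchSize input patch side in px.
#' @param channels widths of the seven convolutional layers, trunk then
#'   counting head; the last must be 1 (the density map).
#' @return An untrained [WSCNet-class].
#' @examples
#' net <- buildWSCNet(seed = 1)
#' net
#' @export
buildWSCNet <- function(seed = 1L, patchSize = 32L,
                        channels = c(8L, 8L, 16L, 16L, 8L, 8L, 1L)) {
  stopifnot(length(channels) == 7L, channels[7] == 1L, all(channels >= 1L))
  set.seed(seed)
  cin <- c(1L, channels[-7])
  convW <- convB <- vector("list", 7L)
  for (l in 1:7) {
    fanIn <- cin[l] * 9L
    convW[[l]] <- matrix(rnorm(channels[l] * fanIn, 0, sqrt(2 / fanIn)),
                         channels[l], fanIn)
    convB[[l]] <- rep(0, channels[l])
  }
  fcW <- matrix(rnorm(2 * channels[4], 0, sqrt(2 / channels[4])),
                2, channels[4])
  new("WSCNet",
      weights = list(convW = convW, convB = convB, fcW = fcW, fcb = rep(0, 2)),
      patchSize = as.integer(patchSize),
      channels = as.integer(channels),
      seed = as.integer(seed), trained = FALSE, history = list())
}

#' Truncated count prediction from a density map
#'
#' The raw count estimate is the density-map integral \eqn{D_{sum}}. Because
#' the weak "multiple" label only asserts "at least two", the prediction is
#' truncated at 2, keeping a small slope \code{gamma} so the gradient never
#' vanishes: \eqn{f(D) = D_{sum}} if \eqn{D_{sum} < 2}, else
#' \eqn{2 + \gamma D_{sum}}.
#'
#' @param dsum density-map integral(s).
#' @param gamma small positive slope constant.
#' @return Truncated count prediction(s).
#' @export
truncatedCount <- function(dsum, gamma = 0.001) {
  stopifnot(gamma > 0)
  ifelse(dsum < 2, dsum, 2 + gamma * dsum)
}

#' Density-peak regularizer
#'
#' Penalizes the density maximum above 1: \eqn{\psi(D) = D_{max} - 1} when
#' \eqn{D_{max} > 1}, else 0. Without it the truncation would let the net
#' concentrate unbounded mass on one pixel for "multiple" droplets,
#' destroying the correspondence between local maxima and individual cells.
#'
#' @param dmax density-map maximum (vectorized).
#' @return Penalty value(s).
#' @export
maxRegularizer <- function(dmax) {
  pmax(dmax - 1, 0)
}

#' Weakly supervised counting loss
#'
#' Squared error between the truncated count prediction and the weak label
#' plus the density-peak regularizer:
#' \eqn{L_{count} = (f(D) - y)^2 + \psi(D)}. Zero exactly when the
#' truncated prediction equals the label and no density value exceeds 1.
#'
#' @param density nonnegative density-map matrix.
#' @param y weak count label in {0, 1, 2}.
#' @param gamma truncation slope constant.
#' @return Scalar loss.
#' @export
countingLoss <- function(density, y, gamma = 0.001) {
  stopifnot(y %in% 0:2, all(density >= 0))
  (truncatedCount(sum(density), gamma) - y)^2 + maxRegularizer(max(density))
}

#' Total two-branch loss
#'
#' \eqn{L = L_{class} + \omega L_{count}}: the cross-entropy of the
#' droplet/background classifier plus the weighted counting loss, so both
#' branches contribute a training signal for any \eqn{\omega > 0}.
#'
#' @param classLoss classification cross-entropy.
#' @param countLoss counting loss.
#' @param omega counting-branch weight, >= 0.
#' @return Scalar total loss.
#' @export
totalLoss <- function(classLoss, countLoss, omega = 1) {
  stopifnot(omega >= 0)
  classLoss + omega * countLoss
}

#' Reclassify a droplet from its density-map integral
#'
#' Nearest count category \eqn{\arg\min_{k \in \{0,1,2\}} (D_{sum}-k)^2};
#' boundary ties (0.5, 1.5) resolve toward the smaller count.
#'
#' @param dsum density-map integral(s).
#' @return Integer category id(s): 0 empty, 1 single, 2 multicell.
#' @export
reclassifyCount <- function(dsum) {
  stopifnot(all(dsum >= 0))
  ifelse(dsum <= 0.5, 0L, ifelse(dsum <= 1.5, 1L, 2L))
}

categoryName <- function(id) c("empty", "single", "multiple")[id + 1L]

#' Forward pass of the counting network
#'
#' @param model a [WSCNet-class].
#' @param patches a single patch matrix or an array (size, size, N), values
#'   in [0, 1].
#' @return List with \code{density} (array size x size x N, all values
#'   >= 0), \code{logits} (2 x N), \code{probDroplet}, \code{dsum},
#'   \code{dmax}.
#' @export
wscnetForward <- function(model, patches) {
  stopifnot(is(model, "WSCNet"))
  if (is.matrix(patches))
    patches <- array(patches, c(nrow(patches), ncol(patches), 1L))
  stopifnot(dim(patches)[1] == model@patchSize,
            dim(patches)[2] == model@patchSize)
  out <- wsc_forward_cpp(model@weights, patches)
  e <- exp(sweep(out$logits, 2, apply(out$logits, 2, max)))
  p <- sweep(e, 2, colSums(e), "/")
  list(density = out$density, logits = out$logits,
       probDroplet = p[2, ], dsum = as.numeric(out$dsum),
       dmax = as.numeric(out$dmax))
}

## Mean total loss of a labeled patch set under the current weights.
evalLoss <- function(weights, X, cls, y, gamma, omega) {
  out <- wsc_forward_cpp(weights, X)
  e <- exp(sweep(out$logits, 2, apply(out$logits, 2, max)))
  p <- sweep(e, 2, colSums(e), "/")
  picked <- p[cbind(cls + 1L, seq_along(cls))]
  lclass <- mean(-log(pmax(picked, 1e-12)))
  drop <- cls == 1L
  lcount <- if (any(drop)) {
    f <- truncatedCount(out$dsum[drop], gamma)
    sum((f - y[drop])^2 + maxRegularizer(out$dmax[drop])) / length(cls)
  } else 0
  lclass + omega * lcount
}

#' Train the counting network on a labeled patch set
#'
#' Seeded mini-batch Adam training of both branches: cross-entropy on
#' background vs droplet for every patch, the truncated counting loss on
#' droplet patches only. After each epoch the total loss on the validation
#' split is evaluated; when it fails to improve for \code{patience} epochs
#' the learning rate is halved. The returned model carries the weights of
#' the best validation epoch and the full loss history.
#'
#' @param model an untrained (or previously trained) [WSCNet-class].
#' @param data a patch dataset from [makePatchDataset()]; all four
#'   categories must be present in the training split.
#' @param cfg a [TrainConfig-class].
#' @param verbose print per-epoch losses.
#' @return The trained [WSCNet-class] with \code{history} filled in.
#' @export
trainWSCNet <- function(model, data, cfg = trainConfig(), verbose = FALSE) {
  stopifnot(is(model, "WSCNet"), is(cfg, "TrainConfig"))
  validObject(cfg)
  trainIdx <- which(data$split == "train")
  valIdx <- which(data$split == "validate")
  present <- unique(data$category[trainIdx])
  missing <- setdiff(c("background", "empty", "single", "multiple"), present)
  if (length(missing))
    stop("training split lacks category: ", paste(missing, collapse = ", "))

  toCls <- function(idx) as.integer(data$isDroplet[idx])
  toY <- function(idx) ifelse(is.na(data$countLabel[idx]), 0,
                              data$countLabel[idx])
  Xtr <- data$patches[, , trainIdx, drop = FALSE]
  clsTr <- toCls(trainIdx); yTr <- toY(trainIdx)
  Xva <- data$patches[, , valIdx, drop = FALSE]
  clsVa <- toCls(valIdx); yVa <- toY(valIdx)

  w <- model@weights
  adamM <- rapply(w, function(x) x * 0, how = "replace")
  adamV <- rapply(w, function(x) x * 0, how = "replace")
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  tAdam <- 0L
  lr <- cfg@learningRate

  bestVal <- Inf; bestW <- w; badEpochs <- 0L
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valLoss = numeric(0), lr = numeric(0))
  set.seed(cfg@seed)
  nTr <- length(trainIdx)

  for (epoch in seq_len(cfg@maxEpochs)) {
    ord <- sample(nTr)
    epochLoss <- 0; nBatch <- 0L
    for (b in seq(1, nTr, by = cfg@batchSize)) {
      idx <- ord[b:min(b + cfg@batchSize - 1L, nTr)]
      g <- wsc_grad_cpp(w, Xtr[, , idx, drop = FALSE],
                        clsTr[idx], yTr[idx], cfg@gamma, cfg@omega)
      epochLoss <- epochLoss + g$loss; nBatch <- nBatch + 1L
      tAdam <- tAdam + 1L
      corr1 <- 1 - beta1^tAdam; corr2 <- 1 - beta2^tAdam
      for (part in c("convW", "convB")) {
        for (l in 1:7) {
          adamM[[part]][[l]] <- beta1 * adamM[[part]][[l]] +
            (1 - beta1) * g[[part]][[l]]
          adamV[[part]][[l]] <- beta2 * adamV[[part]][[l]] +
            (1 - beta2) * g[[part]][[l]]^2
          w[[part]][[l]] <- w[[part]][[l]] - lr * (adamM[[part]][[l]] / corr1) /
            (sqrt(adamV[[part]][[l]] / corr2) + eps)
        }
      }
      for (part in c("fcW", "fcb")) {
        adamM[[part]] <- beta1 * adamM[[part]] + (1 - beta1) * g[[part]]
        adamV[[part]] <- beta2 * adamV[[part]] + (1 - beta2) * g[[part]]^2
        w[[part]] <- w[[part]] - lr * (adamM[[part]] / corr1) /
          (sqrt(adamV[[part]] / corr2) + eps)
      }
    }
    valLoss <- if (length(valIdx))
      evalLoss(w, Xva, clsVa, yVa, cfg@gamma, cfg@omega)
    else epochLoss / nBatch
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   trainLoss = epochLoss / nBatch,
                                   valLoss = valLoss, lr = lr))
    if (verbose)
      message(sprintf("epoch %2d  train %.4f  val %.4f  lr %.2g",
                      epoch, epochLoss / nBatch, valLoss, lr))
    if (valLoss < bestVal - 1e-6) {
      bestVal <- valLoss; bestW <- w; badEpochs <- 0L
    } else {
      badEpochs <- badEpochs + 1L
      if (badEpochs >= cfg@patience) {
        lr <- lr / 2
        badEpochs <- 0L
      }
    }
  }

  model@weights <- bestW
  model@trained <- TRUE
  model@history <- list(loss = hist, bestValLoss = bestVal,
                        config = cfg)
  model
}

#' Greedy density-map peak extraction
#'
#' Picks up to \code{k} maxima in decreasing density order, suppressing a
#' disk of radius \code{minSep} px around each accepted peak so two peaks
#' cannot sit on the same cell.
#'
#' @param density density-map matrix.
#' @param k number of peaks to extract.
#' @param minSep minimum separation between peaks, px.
#' @return Two-column matrix of (x, y) peak coordinates (patch pixels).
#' @export
findDensityPeaks <- function(density, k, minSep = 3) {
  pts <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  if (k <= 0) return(pts)
  D <- density
  for (i in seq_len(k)) {
    m <- which.max(D)
    if (D[m] <= 0) break
    row <- ((m - 1) %% nrow(D)) + 1
    col <- ((m - 1) %/% nrow(D)) + 1
    pts <- rbind(pts, c(col, row))
    rows <- max(1, row - minSep):min(nrow(D), row + minSep)
    cols <- max(1, col - minSep):min(ncol(D), col + minSep)
    d2 <- outer((rows - row)^2, (cols - col)^2, `+`)
    sub <- D[rows, cols, drop = FALSE]
    sub[d2 <= minSep^2] <- 0
    D[rows, cols] <- sub
  }
  pts
}

#' Classify, count and localize cells in droplet proposals
#'
#' Runs the trained network on the patch of every proposal. A proposal
#' classified as background is flagged a false positive and carries no
#' count or locations. For droplets, the predicted count is
#' \eqn{\lfloor D_{sum} + 0.5 \rfloor}; that many leading density maxima
#' (minimum separation \code{minSep} px) are mapped back through the
#' crop/resize transform to frame coordinates, and the droplet is
#' categorized as empty / single / multiple from \eqn{D_{sum}}.
#'
#' @param model a trained [WSCNet-class].
#' @param proposals data.frame of circle proposals (\code{cx}, \code{cy},
#'   \code{r}, \code{score}).
#' @param frame grayscale frame matrix (0-255).
#' @param cropFactor crop window side as a multiple of the circle radius
#'   (must match training).
#' @param minSep peak separation in patch px.
#' @return List with \code{detections} (data.frame: proposal columns plus
#'   \code{isDroplet}, \code{probDroplet}, \code{dsum}, \code{count},
#'   \code{category}) and \code{cellLocations} (per-detection matrices of
#'   frame coordinates).
#' @export
inferDroplets <- function(model, proposals, frame, cropFactor = 2.4,
                          minSep = 3) {
  stopifnot(is(model, "WSCNet"))
  if (!model@trained)
    warning("model has not been trained; predictions will be arbitrary")
  n <- nrow(proposals)
  locs <- vector("list", n)
  if (n == 0L)
    return(list(detections = cbind(proposals,
                                   data.frame(isDroplet = logical(0),
                                              probDroplet = numeric(0),
                                              dsum = numeric(0),
                                              count = integer(0),
                                              category = character(0))),
                cellLocations = locs))
  size <- model@patchSize
  X <- array(0, c(size, size, n))
  patchAttr <- vector("list", n)
  for (i in seq_len(n)) {
    p <- extractPatch(frame, proposals$cx[i], proposals$cy[i],
                      proposals$r[i], size = size, cropFactor = cropFactor)
    X[, , i] <- p
    patchAttr[[i]] <- p
  }
  out <- wscnetForward(model, X)
  isDroplet <- out$logits[2, ] > out$logits[1, ]
  count <- ifelse(isDroplet, floor(out$dsum + 0.5), NA_integer_)
  category <- ifelse(isDroplet, categoryName(reclassifyCount(out$dsum)),
                     "false_positive")
  for (i in seq_len(n)) {
    if (isDroplet[i] && count[i] > 0) {
      peaks <- findDensityPeaks(out$density[, , i], count[i], minSep)
      locs[[i]] <- patchToFrame(peaks, patchAttr[[i]])
    } else {
      locs[[i]] <- matrix(numeric(0), 0, 2,
                          dimnames = list(NULL, c("cx", "cy")))
    }
  }
  det <- cbind(proposals,
               data.frame(isDroplet = isDroplet,
                          probDroplet = out$probDroplet,
                          dsum = out$dsum,
                          count = as.integer(count),
                          category = category))
  rownames(det) <- NULL
  list(detections = det, cellLocations = locs)
}

#' Save / load a counting network
#'
#' The weights are serialized with R's native RDS format next to a sidecar
#' JSON recording the architecture (patch size, channel widths), the
#' initialization seed and the training configuration, enough to verify a
#' checkpoint matches the code that loads it.
#'
#' @param model a [WSCNet-class].
#' @param path output path (\code{.rds}); the sidecar gets \code{.json}.
#' @return \code{saveWSCNet}: invisibly, the two paths.
#' @export
saveWSCNet <- function(model, path) {
  stopifnot(is(model, "WSCNet"))
  saveRDS(model, path)
  side <- sub("\\.rds$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  cfg <- model@history$config
  jsonlite::write_json(list(
    class = "WSCNet",
    patchSize = model@patchSize,
    channels = model@channels,
    seed = model@seed,
    trained = model@trained,
    nParameters = nParameters(model),
    train = if (!is.null(cfg)) list(gamma = cfg@gamma, omega = cfg@omega,
                                    learningRate = cfg@learningRate,
                                    batchSize = cfg@batchSize,
                                    maxEpochs = cfg@maxEpochs,
                                    seed = cfg@seed)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(model = path, sidecar = side))
}

#' @rdname saveWSCNet
#' @return \code{loadWSCNet}: the restored [WSCNet-class].
#' @export
loadWSCNet <- function(path) {
  model <- readRDS(path)
  if (!is(model, "WSCNet")) stop("not a WSCNet checkpoint: ", path)
  validObject(model)
  model
}
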