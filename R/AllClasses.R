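## Central S4 containers: scene configuration and rendered scenes with
## ground truth, detector and training configurations, the counting network,
## and per-batch encapsulation summaries.

#' Configuration of a synthetic droplet scene
#'
#' Describes one brightfield frame of cell-encapsulated droplets: frame
#' geometry, droplet-size distribution, Poisson cell loading, rendering
#' contrasts and noise. A scene rendered twice from the same configuration
#' (including \code{seed}) is bit-identical.
#'
#' @slot frameWidth,frameHeight frame size in pixels.
#' @slot nDroplets number of droplets requested.
#' @slot dropletDiameterMean mean droplet diameter (px).
#' @slot dropletDiameterCV coefficient of variation of droplet diameter.
#' @slot cpdLambda mean number of cells per droplet (CPD, the Poisson
#'   parameter lambda).
#' @slot cellDiameterRange length-2 interval of rendered cell diameters (px).
#' @slot maxOverlap fraction of the summed radii by which two droplet
#'   centers may encroach; centers are kept at distance
#'   \eqn{\ge (r_1+r_2)(1-\mathrm{maxOverlap})}.
#' @slot backgroundLevel oil background intensity (0-255).
#' @slot interiorContrast intensity drop of the droplet interior below the
#'   background.
#' @slot rimContrast intensity drop of the 2-px dark droplet rim below the
#'   background.
#' @slot cellContrast peak intensity drop of a rendered cell blob.
#' @slot noiseSD standard deviation of additive Gaussian pixel noise.
#' @slot seed integer seed; all scene randomness flows from it.
#' @seealso [sceneConfig()], [renderScene()]
#' @export
setClass("SceneConfig", representation(
  frameWidth = "integer", frameHeight = "integer",
  nDroplets = "integer",
  dropletDiameterMean = "numeric", dropletDiameterCV = "numeric",
  cpdLambda = "numeric",
  cellDiameterRange = "numeric",
  maxOverlap = "numeric",
  backgroundLevel = "numeric", interiorContrast = "numeric",
  rimContrast = "numeric", cellContrast = "numeric",
  noiseSD = "numeric",
  seed = "integer"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@frameWidth < 1L || object@frameHeight < 1L)
    msg <- c(msg, "frame dimensions must be positive")
  if (object@nDroplets < 0L)
    msg <- c(msg, "nDroplets must be >= 0")
  if (object@dropletDiameterMean <= 0)
    msg <- c(msg, "dropletDiameterMean must be positive")
  if (object@dropletDiameterCV < 0)
    msg <- c(msg, "dropletDiameterCV must be >= 0")
  if (object@cpdLambda < 0)
    msg <- c(msg, "cpdLambda must be >= 0")
  if (length(object@cellDiameterRange) != 2L ||
      any(object@cellDiameterRange <= 0) ||
      diff(object@cellDiameterRange) < 0)
    msg <- c(msg, "cellDiameterRange must be a nondecreasing positive pair")
  if (object@maxOverlap < 0 || object@maxOverlap >= 1)
    msg <- c(msg, "maxOverlap must lie in [0, 1)")
  if (object@noiseSD < 0)
    msg <- c(msg, "noiseSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic scene configuration
#'
#' Defaults emulate a 640 x 480 brightfield frame densely packed with ~150
#' adherent droplets of mean diameter 22 px (CV 8\%) loaded at a cell-per-
#' droplet mean of 0.26, the regime in which single-cell encapsulation
#' exceeds 20\% while multicell encapsulation stays below 3\%.
#'
#' @param frameWidth,frameHeight frame size in pixels.
#' @param nDroplets number of droplets to place.
#' @param dropletDiameterMean,dropletDiameterCV droplet diameter
#'   distribution (truncated normal), px and fraction.
#' @param cpdLambda mean cells per droplet (Poisson lambda).
#' @param cellDiameterRange rendered cell diameter interval, px.
#' @param maxOverlap maximum fractional encroachment of two droplet centers.
#' @param backgroundLevel,interiorContrast,rimContrast,cellContrast
#'   rendering intensities (8-bit scale).
#' @param noiseSD additive Gaussian noise SD.
#' @param seed integer seed.
#' @return A [SceneConfig-class] object.
#' @examples
#' cfg <- sceneConfig(nDroplets = 20, seed = 7)
#' scene <- renderScene(cfg)
#' @export
sceneConfig <- function(frameWidth = 640L, frameHeight = 480L,
                        nDroplets = 150L,
                        dropletDiameterMean = 22, dropletDiameterCV = 0.08,
                        cpdLambda = 0.26,
                        cellDiameterRange = c(4, 8),
                        maxOverlap = 0.15,
                        backgroundLevel = 200, interiorContrast = 30,
                        rimContrast = 110, cellContrast = 120,
                        noiseSD = 4,
                        seed = 1L) {
  new("SceneConfig",
      frameWidth = as.integer(frameWidth), frameHeight = as.integer(frameHeight),
      nDroplets = as.integer(nDroplets),
      dropletDiameterMean = as.numeric(dropletDiameterMean),
      dropletDiameterCV = as.numeric(dropletDiameterCV),
      cpdLambda = as.numeric(cpdLambda),
      cellDiameterRange = as.numeric(cellDiameterRange),
      maxOverlap = as.numeric(maxOverlap),
      backgroundLevel = as.numeric(backgroundLevel),
      interiorContrast = as.numeric(interiorContrast),
      rimContrast = as.numeric(rimContrast),
      cellContrast = as.numeric(cellContrast),
      noiseSD = as.numeric(noiseSD),
      seed = as.integer(seed))
}

#' A rendered synthetic scene with ground truth
#'
#' Holds the rendered 8-bit grayscale frame together with its complete
#' ground truth: droplet bounding circles, per-droplet cell centroids, and
#' the droplet-level category labels (\code{"empty"}, \code{"single"},
#' \code{"multiple"}).
#'
#' Coordinates are in-memory 1-based pixel centers, \code{cx} along image
#' columns (x) and \code{cy} along rows (y); file writers emit 0-based
#' coordinates.
#'
#' @slot image numeric matrix (rows = height) with intensities in [0, 255].
#' @slot circles data.frame with columns \code{cx}, \code{cy}, \code{r}.
#' @slot cells list (one element per droplet) of two-column matrices of
#'   cell centroids.
#' @slot categories character vector of per-droplet labels.
#' @slot config the [SceneConfig-class] the scene was rendered from.
#' @seealso [renderScene()], [sceneImage()], [sceneCircles()]
#' @export
setClass("DropletScene", representation(
  image = "matrix",
  circles = "data.frame",
  cells = "list",
  categories = "character",
  config = "SceneConfig"
))

setValidity("DropletScene", function(object) {
  n <- nrow(object@circles)
  msg <- character()
  if (length(object@cells) != n || length(object@categories) != n)
    msg <- c(msg, "circles, cells and categories must have equal length")
  if (n > 0) {
    ncell <- vapply(object@cells, nrow, 0L)
    lab <- ifelse(ncell == 0L, "empty", ifelse(ncell == 1L, "single", "multiple"))
    if (!identical(lab, object@categories))
      msg <- c(msg, "categories must match cell counts (0/1/>=2)")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration for the adaptive-scale template-matching detector
#'
#' @slot sigma matching response threshold in (0, 1]; a pixel whose disk
#'   response reaches \code{sigma} becomes a droplet proposal center.
#' @slot rInit initial template diameter (px); must exceed the largest
#'   droplet diameter expected in the frame.
#' @slot rMin smallest admissible template diameter (px).
#' @slot minShrink upper bound on the per-step scale ratio
#'   \eqn{r_{next}/r_{cur}} so the scale sequence always contracts.
#' @slot nmsIou circle-IoU threshold above which a lower-scoring proposal is
#'   suppressed.
#' @seealso [astmConfig()], [greedyPropose()]
#' @export
setClass("AstmConfig", representation(
  sigma = "numeric", rInit = "numeric", rMin = "numeric",
  minShrink = "numeric", nmsIou = "numeric"
))

setValidity("AstmConfig", function(object) {
  msg <- character()
  if (object@sigma <= 0 || object@sigma > 1)
    msg <- c(msg, "sigma must lie in (0, 1]")
  if (object@rMin >= object@rInit)
    msg <- c(msg, "rMin must be smaller than rInit")
  if (object@minShrink <= 0 || object@minShrink >= 1)
    msg <- c(msg, "minShrink must lie in (0, 1)")
  if (object@nmsIou < 0 || object@nmsIou > 1)
    msg <- c(msg, "nmsIou must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create an ASTM detector configuration
#'
#' The default response threshold is 0.98: a circular template is accepted
#' where at least 98\% of its area lies on droplet foreground. The default
#' initial template diameter (40 px) is about 1.5 times the largest droplet
#' diameter of the default scene model; set it from your own optics as
#' roughly 1.5 x the maximum expected droplet diameter.
#'
#' @param sigma response threshold.
#' @param rInit initial template diameter, px.
#' @param rMin minimum template diameter, px.
#' @param minShrink maximum allowed shrink ratio per scale step.
#' @param nmsIou non-maximum-suppression circle-IoU threshold.
#' @return An [AstmConfig-class] object.
#' @export
astmConfig <- function(sigma = 0.98, rInit = 40, rMin = 8,
                       minShrink = 0.95, nmsIou = 0.3) {
  new("AstmConfig", sigma = sigma, rInit = rInit, rMin = rMin,
      minShrink = minShrink, nmsIou = nmsIou)
}

#' Training configuration for the counting network
#'
#' @slot gamma small positive slope applied to the count prediction once the
#'   density-map integral exceeds 2, so the "at least two" label keeps a
#'   gradient without growing unbounded.
#' @slot omega weight of the counting loss in the total loss.
#' @slot learningRate initial Adam learning rate.
#' @slot batchSize mini-batch size.
#' @slot maxEpochs maximum training epochs.
#' @slot patience epochs without validation improvement before the learning
#'   rate is halved.
#' @slot seed integer seed controlling initialization and shuffling.
#' @seealso [trainConfig()], [trainWSCNet()]
#' @export
setClass("TrainConfig", representation(
  gamma = "numeric", omega = "numeric", learningRate = "numeric",
  batchSize = "integer", maxEpochs = "integer", patience = "integer",
  seed = "integer"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
  if (object@omega < 0) msg <- c(msg, "omega must be >= 0")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a training configuration
#'
#' @param gamma truncation slope constant (default 0.001).
#' @param omega counting-branch weight (default 1).
#' @param learningRate initial learning rate (default 1e-4).
#' @param batchSize mini-batch size (default 1024; reduce for desk-scale
#'   training).
#' @param maxEpochs maximum epochs.
#' @param patience plateau patience before halving the learning rate.
#' @param seed integer seed.
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(gamma = 0.001, omega = 1, learningRate = 1e-4,
                        batchSize = 1024L, maxEpochs = 30L, patience = 3L,
                        seed = 1L) {
  new("TrainConfig", gamma = gamma, omega = omega,
      learningRate = learningRate, batchSize = as.integer(batchSize),
      maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
      seed = as.integer(seed))
}

#' The weakly supervised counting network
#'
#' A compact two-branch convolutional network with exactly seven 3x3
#' convolutional layers: a shared four-layer trunk, a three-layer counting
#' head ending in a single-channel non-negative density map at input
#' resolution, and a classification head (global average pooling plus a
#' linear layer, not counted among the convolutions) separating droplets
#' from false-positive proposals.
#'
#' @slot weights list of convolution weight matrices/biases and the linear
#'   classifier parameters.
#' @slot patchSize side length (px) of the square input patch.
#' @slot channels integer vector of channel widths for the seven conv
#'   layers.
#' @slot seed seed the weights were initialized from.
#' @slot trained logical; TRUE after [trainWSCNet()].
#' @slot history per-epoch training/validation losses.
#' @seealso [buildWSCNet()], [trainWSCNet()], [inferDroplets()]
#' @export
setClass("WSCNet", representation(
  weights = "list",
  patchSize = "integer",
  channels = "integer",
  seed = "integer",
  trained = "logical",
  history = "list"
))

#' Encapsulation summary of a droplet batch
#'
#' Aggregates per-droplet cell counts into the quantities used to judge
#' single-cell encapsulation performance: the number of detected droplets
#' \eqn{N^d}, positive droplets \eqn{M^d} (at least one cell), the count
#' histogram, category rates, the conditional single-cell rate
#' \eqn{\rho_1/(1-\rho_0)}, and the cells-per-droplet estimate
#' \eqn{\hat\lambda = -\ln(1 - M^d/N^d)}.
#'
#' @slot nDroplets detected droplet count \eqn{N^d}.
#' @slot nPositive droplets with at least one cell \eqn{M^d}.
#' @slot countsByK named integer vector, histogram of per-droplet counts.
#' @slot rates named numeric: \code{empty}, \code{single}, \code{multiple}.
#' @slot singleCellRate conditional single-cell rate (NA when no droplet
#'   holds a cell).
#' @slot lambdaHat estimated cells per droplet.
#' @seealso [summarizeEncapsulation()]
#' @export
setClass("EncapsulationSummary", representation(
  nDroplets = "integer", nPositive = "integer",
  countsByK = "integer", rates = "numeric",
  singleCellRate = "numeric", lambdaHat = "numeric"
))

setValidity("EncapsulationSummary", function(object) {
  msg <- character()
  if (object@nPositive > object@nDroplets)
    msg <- c(msg, "nPositive cannot exceed nDroplets")
  if (object@nDroplets > 0 &&
      abs(sum(object@rates) - 1) > 1e-8)
    msg <- c(msg, "category rates must sum to 1")
  if (length(msg)) msg else TRUE
})
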