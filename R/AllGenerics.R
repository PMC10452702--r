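## Accessors and show methods.

#' @rdname DropletScene-class
#' @param object,x a \code{DropletScene}.
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))

#' @rdname DropletScene-class
#' @export
setGeneric("sceneCircles", function(x) standardGeneric("sceneCircles"))

#' @rdname DropletScene-class
#' @export
setGeneric("sceneCells", function(x) standardGeneric("sceneCells"))

#' @rdname DropletScene-class
#' @export
setGeneric("sceneCategories", function(x) standardGeneric("sceneCategories"))

#' @rdname DropletScene-class
#' @export
setGeneric("sceneConfigOf", function(x) standardGeneric("sceneConfigOf"))

#' @rdname DropletScene-class
#' @export
setMethod("sceneImage", "DropletScene", function(x) x@image)

#' @rdname DropletScene-class
#' @export
setMethod("sceneCircles", "DropletScene", function(x) x@circles)

#' @rdname DropletScene-class
#' @export
setMethod("sceneCells", "DropletScene", function(x) x@cells)

#' @rdname DropletScene-class
#' @export
setMethod("sceneCategories", "DropletScene", function(x) x@categories)

#' @rdname DropletScene-class
#' @export
setMethod("sceneConfigOf", "DropletScene", function(x) x@config)

setMethod("show", "DropletScene", function(object) {
  n <- nrow(object@circles)
  cat(sprintf("DropletScene: %d x %d px, %d droplets\n",
              ncol(object@image), nrow(object@image), n))
  if (n > 0) {
    tab <- table(factor(object@categories,
                        levels = c("empty", "single", "multiple")))
    cat(sprintf("  categories: empty %d, single %d, multiple %d\n",
                tab["empty"], tab["single"], tab["multiple"]))
    cat(sprintf("  diameter: mean %.1f px (range %.1f-%.1f)\n",
                mean(2 * object@circles$r), min(2 * object@circles$r),
                max(2 * object@circles$r)))
  }
  invisible(NULL)
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %d x %d px, %d droplets (diameter %.1f px, CV %.2f)\n",
    object@frameWidth, object@frameHeight, object@nDroplets,
    object@dropletDiameterMean, object@dropletDiameterCV))
  cat(sprintf("  cells/droplet lambda = %.3g, seed = %d\n",
              object@cpdLambda, object@seed))
  invisible(NULL)
})

setMethod("show", "AstmConfig", function(object) {
  cat(sprintf(
    "AstmConfig: sigma %.3g, template %.4g -> %.4g px (shrink cap %.3g), NMS IoU %.3g\n",
    object@sigma, object@rInit, object@rMin, object@minShrink, object@nmsIou))
  invisible(NULL)
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: gamma %.4g, omega %.3g, lr %.3g, batch %d, <=%d epochs, seed %d\n",
    object@gamma, object@omega, object@learningRate, object@batchSize,
    object@maxEpochs, object@seed))
  invisible(NULL)
})

#' Number of trainable parameters of a counting network
#'
#' @param model a [WSCNet-class] object.
#' @return Integer parameter count (convolutions plus linear classifier).
#' @export
nParameters <- function(model) {
  stopifnot(is(model, "WSCNet"))
  w <- model@weights
  sum(vapply(w$convW, length, 0L)) + sum(vapply(w$convB, length, 0L)) +
    length(w$fcW) + length(w$fcb)
}

setMethod("show", "WSCNet", function(object) {
  cat(sprintf("WSCNet: 7 conv layers (3x3), patch %d x %d\n",
              object@patchSize, object@patchSize))
  cat(sprintf("  trunk channels %s | counting head %s -> density map\n",
              paste(object@channels[1:4], collapse = "-"),
              paste(object@channels[5:7], collapse = "-")))
  cat(sprintf("  classification head: GAP(%d) -> 2 classes\n",
              object@channels[4]))
  cat(sprintf("  parameters: %d | %s\n", nParameters(object),
              if (object@trained) "trained" else "untrained"))
  invisible(NULL)
})

setMethod("show", "EncapsulationSummary", function(object) {
  cat(sprintf("EncapsulationSummary: N = %d droplets, M = %d positive\n",
              object@nDroplets, object@nPositive))
  cat(sprintf("  rates: empty %.3f, single %.3f, multiple %.3f\n",
              object@rates["empty"], object@rates["single"],
              object@rates["multiple"]))
  cat(sprintf("  single-cell rate %.3f | lambda-hat %.4g\n",
              object@singleCellRate, object@lambdaHat))
  invisible(NULL)
})
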